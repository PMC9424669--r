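# Species-pair trait covariates and the area-interacting driver regressions
# for spatial (Gaussian identity-link) and temporal (beta regression)
# co-occurrence.

#' Diet overlap between two species
#'
#' Number of shared food-resource categories divided by the total number of
#' unique categories used by the pair (Jaccard ratio of the diet sets).
#'
#' @param diet_a,diet_b non-empty character vectors of food categories.
#' @return value in [0, 1].
#' @examples
#' dietOverlap(c("a", "b"), c("b", "c"))  # 1/3
#' @export
dietOverlap <- function(diet_a, diet_b) {
  if (length(diet_a) == 0 || length(diet_b) == 0)
    stop("diet sets must be non-empty")
  length(intersect(diet_a, diet_b)) / length(union(diet_a, diet_b))
}

#' Body-mass ratio of a species pair
#'
#' Ratio of the larger to the smaller mass (>= 1), the one-sided scale on
#' which an intermediate-ratio (quadratic) hypothesis is expressible.
#'
#' @param m_a,m_b positive masses (kg).
#' @return ratio >= 1.
#' @export
bodyMassRatio <- function(m_a, m_b) {
  if (any(c(m_a, m_b) <= 0)) stop("masses must be positive")
  pmax(m_a, m_b) / pmin(m_a, m_b)
}

.pair_key <- function(a, b)
  paste(pmin(a, b), pmax(a, b), sep = "|")

# every unordered rank pairing that can occur (Apex|Apex impossible: one apex)
.rank_pairings <- c("Apex|Large", "Apex|Medium", "Apex|Small",
                    "Large|Medium", "Large|Small", "Medium|Small",
                    "Large|Large", "Medium|Medium", "Small|Small")

.dom_col <- function(pairing) paste0("dom_", gsub("\\|", "_", pairing))

#' Build the species-pair covariate table
#'
#' One row per unordered species pair per area where both species occur,
#' carrying the two co-occurrence responses and all trait covariates:
#' dominance rank-pairing dummies (one per possible rank combination, plus
#' the broad \code{dom_Apex_Any} / \code{dom_Large_Any} contrasts),
#' same-rank dummies, a same-family dummy, diet overlap, the body-mass
#' ratio and its square.  Rank-pairing dummies that cannot occur in an area
#' (e.g. apex pairings where no apex predator is present) are all-zero;
#' these structural zeros are recorded in
#' \code{attr(, "structural_zeros")}.
#'
#' @param traits trait table as from [defaultTraitTable()] (columns
#'   species, body_mass, rank, family, diet).
#' @param assemblages named list of species vectors per area.
#' @param spatial_summaries data.frame from [summarizeCorrelations()]
#'   (rbind over areas) with columns species_a, species_b, area, mean; may
#'   be NULL.
#' @param overlap_table data.frame from [pairwiseOverlap()]\code{$overlaps}
#'   with columns species_a, species_b, area, overlap; may be NULL.
#' @return PairTable data.frame; rows = sum over areas of C(n_area, 2).
#' @export
buildPairTable <- function(traits, assemblages, spatial_summaries = NULL,
                           overlap_table = NULL) {
  rows <- list()
  for (a in names(assemblages)) {
    sp <- assemblages[[a]]
    missing_tr <- setdiff(sp, traits$species)
    if (length(missing_tr))
      stop("species missing from the trait table: ",
           paste(missing_tr, collapse = ", "))
    pr <- .pairs_of(sp)
    if (!nrow(pr)) next
    pr$area <- a
    rows[[a]] <- pr
  }
  pt <- do.call(rbind, c(rows, make.row.names = FALSE))
  ti <- match(pt$species_a, traits$species)
  tj <- match(pt$species_b, traits$species)
  pt$pair_id <- .pair_key(pt$species_a, pt$species_b)
  rk_a <- traits$rank[ti]; rk_b <- traits$rank[tj]
  pairing <- paste(pmin(rk_a, rk_b), pmax(rk_a, rk_b), sep = "|")
  # rank factor order: Apex < Large < Medium < Small alphabetically already
  for (p in .rank_pairings) pt[[.dom_col(p)]] <- as.integer(pairing == p)
  pt$dom_Apex_Any <- as.integer(rk_a == "Apex" | rk_b == "Apex")
  pt$dom_Large_Any <- as.integer(xor(rk_a == "Large", rk_b == "Large") &
                                   rk_a != "Apex" & rk_b != "Apex")
  pt$same_rank_Large <- pt$dom_Large_Large
  pt$same_rank_Medium <- pt$dom_Medium_Medium
  pt$same_rank_Small <- pt$dom_Small_Small
  pt$same_family <- as.integer(traits$family[ti] == traits$family[tj])
  pt$diet_overlap <- mapply(function(i, j)
    dietOverlap(traits$diet[[i]], traits$diet[[j]]), ti, tj)
  pt$body_mass_ratio <- bodyMassRatio(traits$body_mass[ti],
                                      traits$body_mass[tj])
  pt$body_mass_ratio2 <- pt$body_mass_ratio^2
  pt$response_spatial <- NA_real_
  pt$response_temporal <- NA_real_
  if (!is.null(spatial_summaries)) {
    key <- paste(.pair_key(spatial_summaries$species_a,
                           spatial_summaries$species_b),
                 spatial_summaries$area)
    m <- match(paste(pt$pair_id, pt$area), key)
    pt$response_spatial <- spatial_summaries$mean[m]
  }
  if (!is.null(overlap_table)) {
    key <- paste(.pair_key(overlap_table$species_a,
                           overlap_table$species_b), overlap_table$area)
    m <- match(paste(pt$pair_id, pt$area), key)
    pt$response_temporal <- overlap_table$overlap[m]
  }
  sz <- list()
  for (a in names(assemblages)) {
    cols <- vapply(.rank_pairings, function(p)
      sum(pt[[.dom_col(p)]][pt$area == a]) == 0, logical(1))
    sz[[a]] <- .dom_col(.rank_pairings[cols])
  }
  attr(pt, "structural_zeros") <- sz
  pt
}

#' Screen covariate pairs for collinearity
#'
#' For every covariate pair with |Pearson r| at or above the threshold, the
#' member whose single-covariate model attains the higher R-squared for the
#' response is retained and the other dropped (ties keep the first-named
#' covariate, deterministically).
#'
#' @param pair_table PairTable data.frame.
#' @param covariates character vector of numeric covariate columns.
#' @param response response column name (e.g. "response_spatial").
#' @param r_threshold absolute correlation threshold (default 0.7).
#' @return list: \code{retained}, \code{dropped}, and a \code{report}
#'   data.frame with r and the two R-squared values per flagged pair.
#' @export
collinearityScreen <- function(pair_table, covariates,
                               response = "response_spatial",
                               r_threshold = 0.7) {
  d <- pair_table[complete.cases(pair_table[, c(covariates, response)]), ]
  r2 <- vapply(covariates, function(v)
    summary(lm(d[[response]] ~ d[[v]]))$r.squared, numeric(1))
  dropped <- character(); report <- list()
  cmb <- utils::combn(covariates, 2)
  for (q in seq_len(ncol(cmb))) {
    v1 <- cmb[1, q]; v2 <- cmb[2, q]
    r <- cor(d[[v1]], d[[v2]])
    if (is.na(r) || abs(r) < r_threshold) next
    loser <- if (r2[v2] > r2[v1]) v1 else v2
    dropped <- union(dropped, loser)
    report[[length(report) + 1]] <-
      data.frame(cov_a = v1, cov_b = v2, r = r,
                 r2_a = r2[[v1]], r2_b = r2[[v2]], dropped = loser)
  }
  list(retained = setdiff(covariates, dropped), dropped = dropped,
       report = if (length(report)) do.call(rbind, report) else
         data.frame())
}

# per-area blocks: intercepts per area plus covariate-by-area slopes, no
# pooled main effects
.driver_formula <- function(response, covariates) {
  stats::as.formula(paste(response, "~ 0 + area +",
                          paste(sprintf("area:%s", covariates),
                                collapse = " + ")))
}

#' Preselect the dominance-hierarchy covariate
#'
#' Fits, for each candidate dominance dummy, a model with only that
#' candidate interacting with area (response family matching the
#' co-occurrence dimension) and returns the candidate minimizing the
#' information criterion together with the full ranking.
#'
#' @param pair_table PairTable data.frame.
#' @param response "spatial" or "temporal".
#' @param candidates candidate dummy columns; defaults to every dominance
#'   pairing dummy that is not structurally zero everywhere.
#' @param criterion "AIC" (default) or "BIC".
#' @return list: \code{best} (column name), \code{ranking} (data.frame).
#' @export
preselectDominance <- function(pair_table,
                               response = c("spatial", "temporal"),
                               candidates = NULL, criterion = c("AIC", "BIC")) {
  response <- match.arg(response)
  criterion <- match.arg(criterion)
  resp_col <- paste0("response_", response)
  if (is.null(candidates)) {
    candidates <- c(vapply(.rank_pairings, .dom_col, character(1)),
                    "dom_Apex_Any", "dom_Large_Any")
    candidates <- candidates[vapply(candidates, function(v)
      sum(pair_table[[v]], na.rm = TRUE) > 0, logical(1))]
  }
  if (length(candidates) == 0)
    stop("all candidate dominance covariates are structurally zero")
  d <- pair_table[!is.na(pair_table[[resp_col]]), ]
  ic <- function(ll, npar) {
    if (criterion == "AIC") 2 * npar - 2 * ll
    else log(nrow(d)) * npar - 2 * ll
  }
  rows <- lapply(candidates, function(v) {
    f <- .driver_formula(resp_col, v)
    if (response == "spatial") {
      fit <- fitSpatialGLM(d, f)
      np <- nrow(fit@coefficients) + 1  # + error variance
    } else {
      fit <- fitBetaRegression(d, f)
      np <- nrow(fit@coefficients) + 1  # + precision
    }
    data.frame(candidate = v, logLik = fit@logLik,
               criterion = ic(fit@logLik, np))
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$criterion), ]
  rownames(ranking) <- NULL
  list(best = ranking$candidate[1], ranking = ranking)
}

#' Gaussian identity-link driver regression (spatial co-occurrence)
#'
#' Ordinary least squares on the full area-interaction design.  Covariate
#' columns that are structurally zero (all zeros after building the design
#' matrix) are dropped before fitting; any remaining rank deficiency is an
#' error naming the aliased columns.
#'
#' @param pair_table PairTable data.frame (rows with NA response dropped).
#' @param formula model formula; see [preselectDominance()] for the
#'   per-area block construction.
#' @return a \linkS4class{FitResult} (family "gaussian").
#' @export
fitSpatialGLM <- function(pair_table, formula) {
  mf <- stats::model.frame(formula, pair_table, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  zero <- colSums(X != 0) == 0
  if (any(zero)) X <- X[, !zero, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y); p <- ncol(X)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  ll <- -0.5 * n * (log(2 * pi) + log(sum(res^2) / n) + 1)
  vc <- XtXinv * sigma2
  dimnames(vc) <- list(colnames(X), colnames(X))
  new("FitResult",
      coefficients = data.frame(term = colnames(X), estimate = unname(est),
                                se = se, statistic = unname(tval),
                                p.value = unname(pval)),
      family = "gaussian", r.squared = r2, logLik = ll, n = as.integer(n),
      phi = NA_real_, score = NA_real_, vcov = vc)
}

# beta log-likelihood, score in (coefs, log phi); y strictly inside (0,1)
.beta_ll <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p]); mu <- plogis(eta); phi <- exp(par[p + 1])
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

.beta_score <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p]); mu <- plogis(eta); phi <- exp(par[p + 1])
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- sum(mu * (ystar - mustar) + log1p(-y) -
                digamma((1 - mu) * phi) + digamma(phi))
  c(gb, gphi * phi)  # chain rule for log phi
}

#' Beta regression for the temporal-overlap driver model
#'
#' Maximum-likelihood beta regression with a logit mean link and constant
#' precision phi.  Responses are first compressed away from the boundary
#' by \eqn{y' = (y (n - 1) + 0.5) / n} (so exact 0/1 overlaps are
#' admissible); interior observations move by less than 1/(2n).
#' Optimization is BFGS on (coefficients, log phi) with the analytic score;
#' standard errors come from the inverse observed information.
#'
#' @param pair_table PairTable data.frame.
#' @param formula model formula for the mean (logit scale).
#' @param max_iter BFGS iteration cap.
#' @return a \linkS4class{FitResult} (family "beta"); \code{@phi} is the
#'   precision, \code{@r.squared} the Ferrari--Cribari-Neto pseudo-R^2
#'   (squared correlation between linear predictor and link-transformed
#'   response), \code{@score} the max absolute score component at the
#'   optimum.
#' @export
fitBetaRegression <- function(pair_table, formula, max_iter = 500) {
  mf <- stats::model.frame(formula, pair_table, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (any(y < 0 | y > 1)) stop("beta-regression response must lie in [0, 1]")
  X <- stats::model.matrix(formula, mf)
  zero <- colSums(X != 0) == 0
  if (any(zero)) X <- X[, !zero, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n <- length(y)
  yc <- (y * (n - 1) + 0.5) / n
  start_b <- stats::lm.fit(X, qlogis(yc))$coefficients
  mu0 <- plogis(drop(X %*% start_b))
  v0 <- var(qlogis(yc) - drop(X %*% start_b))
  phi0 <- max(mean(mu0 * (1 - mu0)) * (1 + 1 / max(v0, 1e-3)), 2)
  par0 <- c(start_b, log(phi0))
  opt <- optim(par0, fn = .beta_ll, gr = .beta_score, X = X, y = yc,
               method = "BFGS", hessian = TRUE,
               control = list(fnscale = -1, maxit = max_iter,
                              reltol = 1e-12))
  if (opt$convergence != 0)
    stop("beta regression did not converge (optim code ", opt$convergence,
         "): ", paste(opt$message, collapse = " "))
  p <- ncol(X)
  est <- opt$par[1:p]
  info <- -opt$hessian
  vc_full <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix in beta regression"))
  se <- sqrt(pmax(diag(vc_full)[1:p], 0))
  se[!is.finite(se) | se <= 0] <- NA_real_  # ill-conditioned information
  zval <- est / se
  pval <- 2 * pnorm(-abs(zval))
  eta <- drop(X %*% est)
  r2 <- if (sd(eta) > 0) cor(eta, qlogis(yc))^2 else 0
  sc <- .beta_score(opt$par, X, yc)
  vc <- vc_full[1:p, 1:p, drop = FALSE]
  dimnames(vc) <- list(colnames(X), colnames(X))
  new("FitResult",
      coefficients = data.frame(term = colnames(X), estimate = unname(est),
                                se = se, statistic = unname(zval),
                                p.value = unname(pval)),
      family = "beta", r.squared = unname(r2), logLik = opt$value,
      n = as.integer(n), phi = exp(opt$par[p + 1]),
      score = max(abs(sc)), vcov = vc)
}

#' Context-dependency report for pairs shared across areas
#'
#' For every species pair present in at least two areas: whether the
#' residual-correlation signs agree across areas (contrasting signs =
#' context-dependency), the per-area sign-probability evidence classes, and
#' the maximum pairwise absolute difference in activity overlap.
#' Aggregates the percentage of contrasting-sign pairs and the percentage
#' of pairs whose overlap differs by at most 0.1 between any two areas.
#'
#' @param spatial_summaries data.frame from [summarizeCorrelations()]
#'   (rbind over areas).
#' @param overlap_table data.frame with species_a, species_b, area,
#'   overlap.
#' @return list: \code{pairs} (per-pair data.frame) and \code{summary}
#'   (pct_contrasting_sign, pct_overlap_within_0.1, n_shared_pairs).
#' @export
compareContexts <- function(spatial_summaries, overlap_table = NULL) {
  ss <- spatial_summaries
  ss$key <- .pair_key(ss$species_a, ss$species_b)
  shared <- names(which(table(unique(ss[, c("key", "area")])$key) >= 2))
  pairs <- lapply(shared, function(kk) {
    d <- ss[ss$key == kk, ]
    contrasting <- length(unique(sign(d$mean))) > 1
    row <- data.frame(pair_id = kk, n_areas = nrow(d),
                      contrasting_sign = contrasting,
                      evidence = paste(d$evidence, collapse = "/"),
                      max_overlap_diff = NA_real_)
    if (!is.null(overlap_table)) {
      ov <- overlap_table[.pair_key(overlap_table$species_a,
                                    overlap_table$species_b) == kk, ]
      if (nrow(ov) >= 2)
        row$max_overlap_diff <- max(dist(ov$overlap))
    }
    row
  })
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair_id = character(), n_areas = integer(),
               contrasting_sign = logical(), evidence = character(),
               max_overlap_diff = numeric())
  od <- pairs$max_overlap_diff[!is.na(pairs$max_overlap_diff)]
  list(pairs = pairs,
       summary = list(
         n_shared_pairs = nrow(pairs),
         pct_contrasting_sign = if (nrow(pairs)) 100 *
           mean(pairs$contrasting_sign) else NA_real_,
         pct_overlap_within_0.1 = if (length(od)) 100 *
           mean(od <= 0.1) else NA_real_))
}
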