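# Latent-variable multispecies occupancy model: MCMC fitting and
# residual-correlation summaries.

#' Default latent-factor count
#'
#' About n/2 latent variables suffice to approximate an n-species residual
#' correlation matrix; the default rule is ceiling(n/2), overridable per
#' area in the fit configuration.
#'
#' @param n_species number of species (>= 2).
#' @return integer factor count.
#' @examples
#' defaultFactorCount(13)  # 7
#' @export
defaultFactorCount <- function(n_species) {
  n_species <- .assert_count(n_species, "n_species", min = 2L)
  as.integer(ceiling(n_species / 2))
}

#' Configuration for the occupancy JSDM sampler
#'
#' @param T latent-factor count; NULL selects [defaultFactorCount()] at fit
#'   time.
#' @param n_chains number of MCMC chains (>= 1; >= 2 for convergence
#'   diagnostics).
#' @param n_iter retained iterations per chain, after burn-in.
#' @param n_burn burn-in iterations (step sizes adapt only here).
#' @param thin thinning interval applied at storage time, so thinning never
#'   alters the underlying chain trajectory.
#' @param seed master seed; each chain consumes substream ("jsdm", chain).
#' @param mu_prior_var prior variance of the community means (normal,
#'   mean 0).
#' @param sd_prior_scale scale of the half-normal prior on community SDs.
#' @param theta_prior_sd prior SD of the free factor loadings (subject to
#'   the unit-ball constraint).
#' @param rhat_threshold convergence warning threshold for the potential
#'   scale reduction factor.
#' @return list of class "JSDMConfig".
#' @export
jsdmConfig <- function(T = NULL, n_chains = 3, n_iter = 30000,
                       n_burn = 10000, thin = 10, seed = 1L,
                       mu_prior_var = 2.25, sd_prior_scale = 1,
                       theta_prior_sd = 1, rhat_threshold = 1.1) {
  if (n_iter <= n_burn)
    stop("n_iter (post-burn-in iterations) must exceed n_burn")
  if (thin < 1) stop("thin must be >= 1")
  if (!is.null(T) && T < 1) stop("T must be >= 1")
  structure(list(T = T, n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 mu_prior_var = mu_prior_var,
                 sd_prior_scale = sd_prior_scale,
                 theta_prior_sd = theta_prior_sd,
                 rhat_threshold = rhat_threshold),
            class = "JSDMConfig")
}

.check_standardized <- function(x, name, tol = 1e-6) {
  if (any(!is.finite(x))) stop("non-finite covariate: ", name)
  if (abs(mean(x)) > tol || abs(sd(x) - 1) > tol)
    stop("covariate ", name, " is not standardized (mean 0, SD 1); ",
         "call restandardize() after any subsetting")
}

#' Fit the latent-factor multispecies occupancy model by MCMC
#'
#' Samples the posterior of the probit-occupancy / binomial-detection JSDM
#' with T latent spatial factors and community random effects on the
#' occupancy and detection coefficients, using a purpose-built
#' Metropolis-within-Gibbs sampler (see the package vignette for the update
#' scheme).  The latent occupancy state is fixed at 1 wherever y_ij > 0.
#' Species never detected in the area are dropped with a message before
#' fitting.  Convergence is checked with the potential scale reduction
#' factor over all occupancy/detection coefficients and off-diagonal
#' residual correlations; exceedances are attached as a warning to the
#' result, never silently dropped.
#'
#' @param data a \linkS4class{DetectionData}.
#' @param config a [jsdmConfig()].
#' @return a \linkS4class{PosteriorSamples}.
#' @export
fitJSDM <- function(data, config = jsdmConfig()) {
  stopifnot(is(data, "DetectionData"))
  y <- detections(data)
  k <- effort(data)
  cov <- siteCovariates(data)
  for (v in names(cov)) .check_standardized(cov[[v]], v)
  zero <- rowSums(y) == 0
  if (any(zero)) {
    message("dropping species with zero detections: ",
            paste(rownames(y)[zero], collapse = ", "))
    y <- y[!zero, , drop = FALSE]
  }
  n <- nrow(y)
  if (n < 2) stop("need at least 2 detected species")
  T <- if (is.null(config$T)) defaultFactorCount(n) else as.integer(config$T)
  if (T > n) stop("T must not exceed the number of species")
  storage.mode(y) <- "integer"

  per_chain <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(substreamSeed(config$seed, "jsdm", index = ch))
    per_chain[[ch]] <- .jsdm_mcmc(
      y, k, cov$TREE, cov$TRAIL_W, cov$VEG_D, T,
      config$n_burn, config$n_iter, config$thin,
      config$mu_prior_var, config$sd_prior_scale, config$theta_prior_sd,
      TRUE)
  }
  nk <- per_chain[[1]]$n_kept
  nd <- nk * config$n_chains
  S <- ncol(y)
  bind3 <- function(field, d3)
    array(aperm(simplify2array(lapply(per_chain, `[[`, field)),
                c(1, 4, 2, 3)),
          dim = c(nd, n, d3))
  beta <- bind3("beta", 2); gamma <- bind3("gamma", 3)
  theta <- bind3("theta", T)
  sigma2 <- do.call(rbind, lapply(per_chain, `[[`, "sigma2"))
  zarr <- bind3("z", S)
  larr <- array(aperm(simplify2array(lapply(per_chain, `[[`, "l")),
                      c(1, 4, 2, 3)), dim = c(nd, S, T))
  R <- array(NA_real_, c(nd, n, n))
  for (d in seq_len(nd)) {
    th <- matrix(theta[d, , ], n, T)
    R[d, , ] <- tcrossprod(th) + diag(pmax(sigma2[d, ], 0), n)
  }
  ps <- new("PosteriorSamples",
            species = rownames(y), area = areaName(data),
            chain = rep(seq_len(config$n_chains), each = nk),
            draw = rep(seq_len(nk), config$n_chains),
            beta = beta, gamma = gamma, theta = theta,
            sigma2 = sigma2, R = R, z = zarr, l = larr,
            y = y, effort = as.numeric(k), warnings = character())
  rh <- gelmanRubin(ps)
  if (any(rh > config$rhat_threshold, na.rm = TRUE)) {
    w <- sprintf("convergence: %d/%d monitored scalars have Rhat > %.2f (max %.3f)",
                 sum(rh > config$rhat_threshold, na.rm = TRUE), length(rh),
                 config$rhat_threshold, max(rh, na.rm = TRUE))
    warning(w)
    ps@warnings <- w
  }
  ps
}

#' Residual correlation matrix from one posterior draw
#'
#' Evaluates \eqn{R = \theta\theta^\top + \mathrm{diag}(\sigma^2)} for a
#' loading matrix and residual variances from a single draw.
#'
#' @param theta_draw n x T loading matrix.
#' @param sigma2_draw residual variances; defaults to the identity-implied
#'   \code{1 - rowSums(theta^2)}.
#' @return symmetric unit-diagonal matrix.
#' @export
residualCorrelation <- function(theta_draw, sigma2_draw = NULL) {
  theta_draw <- as.matrix(theta_draw)
  ss <- rowSums(theta_draw^2)
  if (any(ss > 1 + 1e-9)) stop("sum_t theta^2 > 1 for some species")
  if (is.null(sigma2_draw)) sigma2_draw <- pmax(1 - ss, 0)
  R <- tcrossprod(theta_draw) + diag(sigma2_draw, nrow(theta_draw))
  if (max(abs(diag(R) - 1)) > 1e-6)
    stop("sigma2 inconsistent with loadings: diagonal of R is not 1")
  if (!is.null(rownames(theta_draw)))
    dimnames(R) <- list(rownames(theta_draw), rownames(theta_draw))
  R
}

# PSRF for one scalar: x is a draws x chains matrix
.psrf <- function(x) {
  m <- ncol(x); nn <- nrow(x)
  if (m < 2) stop("need >= 2 chains for the Gelman-Rubin statistic")
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt((nn - 1) / nn + B_over_n / W)
}

#' Brooks--Gelman--Rubin convergence diagnostic
#'
#' Potential scale reduction factor \eqn{\sqrt{\hat{V}/W}} with
#' \eqn{\hat{V} = (n-1)/n\, W + B/n}, computed per monitored scalar from
#' the between- and within-chain variances.  For a
#' \linkS4class{PosteriorSamples} the monitored scalars are all occupancy
#' and detection coefficients and all off-diagonal entries of R.
#'
#' @param samples a \linkS4class{PosteriorSamples}, or a draws x chains
#'   numeric matrix for a single scalar.
#' @return named numeric vector of PSRF values (or a scalar for a matrix).
#' @export
gelmanRubin <- function(samples) {
  if (is.matrix(samples)) return(.psrf(samples))
  stopifnot(is(samples, "PosteriorSamples"))
  chains <- sort(unique(samples@chain))
  if (length(chains) < 2)
    stop("need >= 2 chains for the Gelman-Rubin statistic")
  n <- length(samples@species)
  as_mat <- function(v) vapply(chains, function(ch) v[samples@chain == ch],
                               numeric(sum(samples@chain == chains[1])))
  out <- c()
  for (p in 1:2) for (i in 1:n) {
    out[sprintf("beta%d[%s]", p - 1, samples@species[i])] <-
      .psrf(as_mat(samples@beta[, i, p]))
  }
  for (p in 1:3) for (i in 1:n) {
    out[sprintf("gamma%d[%s]", p - 1, samples@species[i])] <-
      .psrf(as_mat(samples@gamma[, i, p]))
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      out[sprintf("R[%s,%s]", samples@species[i], samples@species[j])] <-
        .psrf(as_mat(samples@R[, i, j]))
    }
  }
  out
}

#' Summarize pairwise residual occupancy correlations
#'
#' Per unordered species pair: posterior mean, central 95\% credible
#' interval, the sign probability (share of draws sharing the sign of the
#' posterior mean), and an evidence class — "strong" above
#' \code{sign_threshold} (default 0.9), otherwise "moderate" above the
#' secondary 0.7 level, otherwise "none".
#'
#' @param samples a \linkS4class{PosteriorSamples}.
#' @param sign_threshold strong-evidence cut on the sign probability.
#' @return data.frame: species_a, species_b, area, mean, lower, upper,
#'   sign_prob, evidence.
#' @export
summarizeCorrelations <- function(samples, sign_threshold = 0.9) {
  stopifnot(is(samples, "PosteriorSamples"))
  sp <- samples@species
  pr <- .pairs_of(sp)
  out <- cbind(pr, area = samples@area, mean = NA_real_, lower = NA_real_,
               upper = NA_real_, sign_prob = NA_real_,
               evidence = NA_character_)
  for (r in seq_len(nrow(pr))) {
    i <- match(pr$species_a[r], sp); j <- match(pr$species_b[r], sp)
    d <- samples@R[, i, j]
    m <- mean(d)
    ci <- unname(quantile(d, c(0.025, 0.975)))
    sgn <- if (m >= 0) mean(d >= 0) else mean(d < 0)
    out$mean[r] <- m; out$lower[r] <- ci[1]; out$upper[r] <- ci[2]
    out$sign_prob[r] <- sgn
    out$evidence[r] <- if (sgn > sign_threshold) "strong"
      else if (sgn > 0.7) "moderate" else "none"
  }
  out
}

#' Assemblage-level descriptive summary of pair co-occurrence values
#'
#' Per area: mean, SD, percent positive, median and the 33/66\% quantiles
#' of a pairwise co-occurrence measure.
#'
#' @param pair_values data.frame with columns \code{area} and \code{value}
#'   (e.g. the \code{mean} column of [summarizeCorrelations()] output, or
#'   activity overlaps).
#' @return data.frame, one row per area.
#' @export
assemblageSummary <- function(pair_values) {
  stopifnot(all(c("area", "value") %in% names(pair_values)))
  do.call(rbind, lapply(split(pair_values, pair_values$area), function(d) {
    v <- d$value
    data.frame(area = d$area[1], n_pairs = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               pct_positive = 100 * mean(v > 0),
               median = unname(quantile(v, 0.5, type = 7)),
               q33 = unname(quantile(v, 0.33, type = 7)),
               q66 = unname(quantile(v, 0.66, type = 7)))
  }))
}
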