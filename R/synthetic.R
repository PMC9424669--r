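# Synthetic camera-trap landscapes with known ground truth: three adjacent
# survey areas, community-distributed occupancy/detection coefficients,
# latent spatial factors inducing residual co-occurrence, and species-specific
# circular activity densities.

#' Simulate a table of camera-trap sites for one survey area
#'
#' Draws site covariates (tree cover TREE for occupancy; trail width TRAIL_W
#' and vegetation density VEG_D for detection) and standardizes them to mean
#' 0 / SD 1 within the area, and draws survey effort per site from a
#' truncated normal (floor 1 day) rounded to whole trap-days.
#'
#' @param n_sites number of camera stations (>= 2, so standardization is
#'   defined).
#' @param area area label, e.g. "PA", "PR" or "GR".
#' @param mean_effort,sd_effort mean and SD of trap-days per site; the
#'   default emulates surveys of about 75 +/- 15 trap-days.
#' @param seed integer seed (substream "sites").
#' @param start_date first deployment day (late dry season by default).
#' @param longitude site longitude in degrees east, used for solar time.
#' @return data.frame with columns site_id, area, TREE, TRAIL_W, VEG_D,
#'   effort, longitude, deploy_start, deploy_end.
#' @examples
#' s <- simulateSites(20, "PA", seed = 1)
#' round(c(mean(s$TREE), sd(s$TREE)), 10)
#' @export
simulateSites <- function(n_sites, area = "PA", mean_effort = 75,
                          sd_effort = 15, seed = 1L,
                          start_date = "2017-08-01", longitude = 32.2) {
  n_sites <- .assert_count(n_sites, "n_sites", min = 2L)
  if (sd_effort < 0) stop("sd_effort must be >= 0")
  set.seed(substreamSeed(seed, "sites"))
  # raw covariate draws; distributional family is a config choice, the model
  # only ever sees the standardized versions
  tree <- rnorm(n_sites)
  trailw <- rnorm(n_sites)
  vegd <- rnorm(n_sites)
  k <- round(mean_effort + sd_effort * rnorm(n_sites))
  k <- pmax(k, 1)
  start <- as.Date(start_date)
  data.frame(
    site_id = sprintf("%s_%03d", area, seq_len(n_sites)),
    area = area,
    TREE = .standardize(tree),
    TRAIL_W = .standardize(trailw),
    VEG_D = .standardize(vegd),
    effort = as.integer(k),
    longitude = longitude,
    deploy_start = start,
    deploy_end = start + as.integer(k) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Default community-level hyperparameters
#'
#' Community means and SDs for each coefficient family of the occupancy
#' (probit) and detection (logit) layers, plus the scale of the raw
#' latent-factor loadings.  Defaults emulate a moderately detectable guild:
#' marginal occupancy around 0.3--0.5 and daily detection probability
#' around 0.1 at an average site.
#'
#' @return named list with elements mu (length-5), sigma (length-5), both
#'   named beta0, beta1, gamma0, gamma1, gamma2, and theta_scale.
#' @export
defaultHyperparams <- function() {
  list(
    mu = c(beta0 = -0.3, beta1 = 0.4, gamma0 = -2.2, gamma1 = 0.4,
           gamma2 = -0.3),
    sigma = c(beta0 = 0.7, beta1 = 0.4, gamma0 = 0.5, gamma1 = 0.3,
              gamma2 = 0.3),
    theta_scale = 0.5
  )
}

#' Simulate community-distributed species parameters
#'
#' Draws per-species occupancy coefficients (probit scale), detection
#' coefficients (logit scale) and latent-factor loadings from community-level
#' normal distributions.  Loading rows whose sum of squares would exceed 1
#' are shrunk back into the unit ball (to sum 0.95) so the residual-variance
#' identity \eqn{\sigma_i^2 = 1 - \sum_t \theta_{it}^2} stays valid; shrunk
#' species are flagged in \code{@rescaled}.
#'
#' @param n_species number of species.
#' @param T number of latent factors, 1 <= T <= n_species.
#' @param hyperparams list as from [defaultHyperparams()].
#' @param seed integer seed (substream "community").
#' @param species optional species labels.
#' @return a \linkS4class{CommunityParams}.
#' @export
simulateCommunity <- function(n_species, T, hyperparams = defaultHyperparams(),
                              seed = 1L, species = NULL) {
  n_species <- .assert_count(n_species, "n_species")
  T <- .assert_count(T, "T")
  if (T > n_species) stop("T must satisfy 1 <= T <= n_species")
  if (any(hyperparams$sigma < 0)) stop("community SDs must be >= 0")
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(n_species))
  set.seed(substreamSeed(seed, "community"))
  mu <- hyperparams$mu; s <- hyperparams$sigma
  beta <- cbind(rnorm(n_species, mu["beta0"], s["beta0"]),
                rnorm(n_species, mu["beta1"], s["beta1"]))
  gamma <- cbind(rnorm(n_species, mu["gamma0"], s["gamma0"]),
                 rnorm(n_species, mu["gamma1"], s["gamma1"]),
                 rnorm(n_species, mu["gamma2"], s["gamma2"]))
  theta <- matrix(rnorm(n_species * T, 0, hyperparams$theta_scale),
                  n_species, T)
  ss <- rowSums(theta^2)
  rescaled <- ss > 1
  if (any(rescaled))
    theta[rescaled, ] <- theta[rescaled, , drop = FALSE] *
      sqrt(0.95 / ss[rescaled])
  dimnames(beta) <- list(species, c("beta0", "beta1"))
  dimnames(gamma) <- list(species, c("gamma0", "gamma1", "gamma2"))
  rownames(theta) <- species
  new("CommunityParams", species = species, beta = beta, gamma = gamma,
      theta = theta, hyper = hyperparams, rescaled = rescaled)
}

#' True residual occupancy correlation matrix of a simulated community
#'
#' Evaluates \eqn{R = \theta\theta^\top + \mathrm{diag}(\sigma_1^2 \ldots
#' \sigma_n^2)} with \eqn{\sigma_i^2 = 1 - \sum_t \theta_{it}^2}: the
#' correlation among the species' latent occupancy propensities that remains
#' after the covariate effects.
#'
#' @param params a \linkS4class{CommunityParams}, or a loading matrix.
#' @return symmetric unit-diagonal correlation matrix.
#' @examples
#' trueResidualCorrelation(matrix(c(0.6, 0.8), 2, 1))[1, 2]  # 0.48
#' @export
trueResidualCorrelation <- function(params) {
  theta <- if (is(params, "CommunityParams")) params@theta else as.matrix(params)
  ss <- rowSums(theta^2)
  if (any(ss > 1 + 1e-9)) stop("invalid loadings: sum_t theta^2 > 1")
  R <- tcrossprod(theta) + diag(pmax(1 - ss, 0), nrow(theta))
  if (!is.null(rownames(theta)))
    dimnames(R) <- list(rownames(theta), rownames(theta))
  R
}

#' Simulate detection data with known occupancy ground truth
#'
#' Implements the generative model of the latent-factor occupancy JSDM:
#' site factor scores l ~ N(0, I_T); latent propensity
#' u_ij = beta0_i + beta1_i TREE_j + l_j . theta_i + eps_ij with
#' eps_ij ~ N(0, 1 - sum theta_i^2); occupancy z_ij = 1(u_ij > 0); and
#' detection-day counts y_ij ~ Binomial(k_j, z_ij * p_ij) with
#' logit p_ij = gamma0_i + gamma1_i TRAIL_W_j + gamma2_i VEG_D_j.
#'
#' @param params a \linkS4class{CommunityParams}.
#' @param sites site table from [simulateSites()] (one area).
#' @param seed integer seed (substream "occupancy").
#' @return list with elements \code{data} (a \linkS4class{DetectionData})
#'   and \code{truth} (list: z, u, l, p, R — the generating values).
#' @export
simulateDetectionData <- function(params, sites, seed = 1L) {
  stopifnot(is(params, "CommunityParams"))
  n <- nSpecies(params)
  S <- nrow(sites)
  theta <- params@theta
  sigma2 <- 1 - rowSums(theta^2)
  if (any(sigma2 < -1e-9))
    stop("invariant breach: sigma_i^2 = 1 - sum theta^2 is negative")
  sigma2 <- pmax(sigma2, 0)
  set.seed(substreamSeed(seed, "occupancy"))
  l <- matrix(rnorm(S * ncol(theta)), S, ncol(theta))
  eps <- matrix(rnorm(n * S, 0, sqrt(sigma2)), n, S)
  u <- params@beta[, 1] + outer(params@beta[, 2], sites$TREE) +
    theta %*% t(l) + eps
  z <- (u > 0) * 1L
  p <- plogis(params@gamma[, 1] + outer(params@gamma[, 2], sites$TRAIL_W) +
                outer(params@gamma[, 3], sites$VEG_D))
  k <- sites$effort
  y <- matrix(rbinom(n * S, rep(k, each = n), as.vector(z * p)), n, S)
  dimnames(y) <- list(params@species, sites$site_id)
  dd <- .makeDetectionData(y, sites)
  list(data = dd,
       truth = list(z = z, u = u, l = l, p = p,
                    R = trueResidualCorrelation(params)))
}

.makeDetectionData <- function(y, sites) {
  cd <- S4Vectors::DataFrame(sites, row.names = sites$site_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(detections = y), colData = cd)
  new("DetectionData", se)
}

# Best & Fisher (1979) von Mises sampler; kappa = 0 falls back to uniform
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- .wrap_angle(mu + sign(u3 - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

# draw from a von Mises mixture given data.frame(mu, kappa, w)
.rvm_mixture <- function(n, comp) {
  w <- comp$w / sum(comp$w)
  j <- sample.int(nrow(comp), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (cc in unique(j)) {
    idx <- which(j == cc)
    out[idx] <- .rvonmises(length(idx), comp$mu[cc], comp$kappa[cc])
  }
  out
}

#' Default diel-activity specifications
#'
#' Ground-truth circular densities (von Mises mixtures) for a set of
#' species: nocturnal (antipodal-of-noon mode), diurnal (noon mode),
#' crepuscular (dawn + dusk bimodal) or cathemeral (near uniform).  The
#' profile is a deterministic function of the species name, so a species
#' keeps the same diel activity in every area it occurs in (activity as an
#' endogenous species property).
#'
#' @param species character vector of species labels.
#' @return named list; each element a data.frame with columns mu, kappa, w.
#' @export
defaultActivitySpec <- function(species) {
  profiles <- list(
    nocturnal  = data.frame(mu = 0, kappa = 2.5, w = 1),
    diurnal    = data.frame(mu = pi, kappa = 2.5, w = 1),
    crepuscular = data.frame(mu = c(pi / 2, 3 * pi / 2), kappa = c(6, 6),
                             w = c(0.5, 0.5)),
    cathemeral = data.frame(mu = 0, kappa = 0.3, w = 1)
  )
  idx <- vapply(species, function(s)
    (sum(utf8ToInt(s)) %% 4L) + 1L, integer(1))
  out <- profiles[idx]
  names(out) <- species
  out
}

#' Simulate a timestamped record table from circular activity densities
#'
#' Draws, for every species, \code{n_records} detections: a site uniformly
#' at random, a day uniformly within that site's deployment window, and a
#' time of day drawn from the species' circular density (angle 0 =
#' midnight, pi = noon).  A fraction \code{cluster_frac} of records then
#' receives a follow-up record at the same site less than one hour later,
#' deliberately violating independence so the downstream filter has work to
#' do.
#'
#' @param spec named list of von Mises mixture specs as from
#'   [defaultActivitySpec()].
#' @param n_records records per species (>= 1).
#' @param sites site table from [simulateSites()].
#' @param seed integer seed (substream "records").
#' @param cluster_frac fraction of records duplicated within < 1 h.
#' @return data.frame with columns species, site_id, timestamp (POSIXct,
#'   UTC), ordered by time.
#' @export
simulateRecords <- function(spec, n_records, sites, seed = 1L,
                            cluster_frac = 0.2) {
  if (length(spec) == 0) stop("empty activity spec")
  n_records <- .assert_count(n_records, "n_records")
  if (cluster_frac < 0 || cluster_frac > 1) stop("cluster_frac must be in [0,1]")
  set.seed(substreamSeed(seed, "records"))
  rows <- list()
  for (sp in names(spec)) {
    ang <- .rvm_mixture(n_records, spec[[sp]])
    j <- sample.int(nrow(sites), n_records, replace = TRUE)
    day <- sites$deploy_start[j] +
      floor(runif(n_records) * as.integer(sites$effort[j]))
    secs <- ang / (2 * pi) * 86400
    ts <- as.POSIXct(day, tz = "UTC") + secs
    base <- data.frame(species = sp, site_id = sites$site_id[j],
                       timestamp = ts, stringsAsFactors = FALSE)
    n_cl <- round(cluster_frac * n_records)
    if (n_cl > 0) {
      pick <- sample.int(n_records, n_cl, replace = TRUE)
      extra <- base[pick, ]
      extra$timestamp <- extra$timestamp + runif(n_cl, 300, 3300)
      base <- rbind(base, extra)
    }
    rows[[sp]] <- base
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$timestamp, out$species, out$site_id), ]
  rownames(out) <- NULL
  out
}

#' Built-in carnivore trait table
#'
#' Reference traits for a 13-species South African carnivore guild: body
#' mass (kg), size-based dominance rank (Apex = lion; Large > 20 kg; Medium
#' 5--20 kg; Small < 5 kg), taxonomic family, and a coarse diet described as
#' a set of food-category labels.  Masses are round literature values; the
#' diet sets are illustrative and only used through the pairwise
#' shared/unique category ratio.
#'
#' @return data.frame with columns species, body_mass, rank, family, diet
#'   (diet is a list-column of character vectors).
#' @export
defaultTraitTable <- function() {
  d <- function(...) list(c(...))
  tr <- rbind(
    data.frame(species = "lion", body_mass = 190, family = "Felidae",
               diet = I(d("large_ungulates", "medium_ungulates", "carrion"))),
    data.frame(species = "spotted_hyaena", body_mass = 60, family = "Hyaenidae",
               diet = I(d("large_ungulates", "medium_ungulates", "carrion",
                          "small_mammals"))),
    data.frame(species = "leopard", body_mass = 55, family = "Felidae",
               diet = I(d("medium_ungulates", "small_mammals", "birds"))),
    data.frame(species = "wild_dog", body_mass = 25, family = "Canidae",
               diet = I(d("medium_ungulates", "small_mammals"))),
    data.frame(species = "caracal", body_mass = 12, family = "Felidae",
               diet = I(d("small_mammals", "birds"))),
    data.frame(species = "serval", body_mass = 11, family = "Felidae",
               diet = I(d("small_mammals", "birds", "reptiles"))),
    data.frame(species = "african_civet", body_mass = 12, family = "Viverridae",
               diet = I(d("small_mammals", "invertebrates", "fruit", "carrion"))),
    data.frame(species = "honey_badger", body_mass = 9, family = "Mustelidae",
               diet = I(d("small_mammals", "invertebrates", "reptiles"))),
    data.frame(species = "black_backed_jackal", body_mass = 8, family = "Canidae",
               diet = I(d("small_mammals", "carrion", "invertebrates", "fruit"))),
    data.frame(species = "white_tailed_mongoose", body_mass = 3.5,
               family = "Herpestidae",
               diet = I(d("invertebrates", "small_mammals"))),
    data.frame(species = "large_spotted_genet", body_mass = 1.8,
               family = "Viverridae",
               diet = I(d("small_mammals", "invertebrates", "birds", "fruit"))),
    data.frame(species = "banded_mongoose", body_mass = 1.5,
               family = "Herpestidae",
               diet = I(d("invertebrates", "reptiles"))),
    data.frame(species = "slender_mongoose", body_mass = 0.6,
               family = "Herpestidae",
               diet = I(d("invertebrates", "small_mammals", "reptiles")))
  )
  tr$rank <- assignRank(tr$body_mass, apex = tr$species == "lion")
  tr[, c("species", "body_mass", "rank", "family", "diet")]
}

#' Assign size-based dominance ranks
#'
#' Apex is an explicit designation (the apex predator of the system); other
#' species are classed by mass: Large > 20 kg, Medium 5--20 kg, Small < 5 kg.
#'
#' @param body_mass numeric, kg.
#' @param apex logical vector flagging the apex predator(s).
#' @return character vector of ranks.
#' @export
assignRank <- function(body_mass, apex = rep(FALSE, length(body_mass))) {
  r <- ifelse(body_mass > 20, "Large",
              ifelse(body_mass >= 5, "Medium", "Small"))
  r[apex] <- "Apex"
  r
}

#' Default area assemblages
#'
#' Species lists per area for the built-in synthetic landscape: the full
#' 13-species guild in the protected area (PA), 11 species in the private
#' reserve (PR), and a large-carnivore-depauperate 8-species set in the
#' game ranches (GR).
#'
#' @return named list of character vectors.
#' @export
defaultAssemblages <- function() {
  all13 <- defaultTraitTable()$species
  list(
    PA = all13,
    PR = setdiff(all13, c("wild_dog", "banded_mongoose")),
    GR = c("spotted_hyaena", "leopard", "caracal", "black_backed_jackal",
           "honey_badger", "white_tailed_mongoose", "large_spotted_genet",
           "slender_mongoose")
  )
}
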