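#' @import methods
#' @importFrom stats sd var cor qnorm pnorm plogis qlogis rnorm runif rbinom
#'   quantile lm coef vcov logLik AIC pt dbeta optim dbinom setNames
#'   complete.cases aggregate pchisq
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib coocc, .registration = TRUE
NULL

#' Community-level parameters of the latent-factor occupancy model
#'
#' Holds the species-specific coefficients and latent-factor loadings that
#' define one simulated (or estimated) community: probit-scale occupancy
#' intercepts and tree-cover slopes, logit-scale detection coefficients, the
#' species x factor loading matrix theta, and the community-level
#' (hyper-)distribution each coefficient family was drawn from.
#'
#' The residual occupancy variance of species i is \eqn{\sigma_i^2 = 1 -
#' \sum_t \theta_{it}^2}, so every row of \code{theta} must lie inside the
#' unit ball; the validity method enforces this.
#'
#' @slot species character vector of species labels.
#' @slot beta numeric matrix (n x 2): occupancy intercept and TREE slope.
#' @slot gamma numeric matrix (n x 3): detection intercept, TRAIL_W and
#'   VEG_D slopes.
#' @slot theta numeric matrix (n x T) of latent-factor loadings.
#' @slot hyper list of community-level means and SDs per coefficient family.
#' @slot rescaled logical vector: was each species' loading row shrunk to
#'   the unit ball at simulation time?
#'
#' @seealso [simulateCommunity()], [trueResidualCorrelation()]
#' @export
setClass("CommunityParams",
  representation(
    species = "character",
    beta = "matrix",
    gamma = "matrix",
    theta = "matrix",
    hyper = "list",
    rescaled = "logical"
  )
)

setValidity("CommunityParams", function(object) {
  n <- length(object@species)
  msg <- character()
  if (nrow(object@beta) != n || ncol(object@beta) != 2)
    msg <- c(msg, "beta must be n_species x 2")
  if (nrow(object@gamma) != n || ncol(object@gamma) != 3)
    msg <- c(msg, "gamma must be n_species x 3")
  if (nrow(object@theta) != n)
    msg <- c(msg, "theta must have one row per species")
  ss <- rowSums(object@theta^2)
  if (any(ss > 1 + 1e-9))
    msg <- c(msg, "sum_t theta[i,t]^2 must be <= 1 for every species")
  if (length(msg)) msg else TRUE
})

#' Site x species detection data for one survey area
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' \code{"detections"} holds the species x site matrix of detection-day
#' counts \eqn{y_{ij}} (number of distinct active days on which species i
#' was recorded at site j).  Column (site) metadata carries the survey
#' effort \code{effort} (trap-days, the binomial number of trials), the
#' standardized site covariates \code{TREE}, \code{TRAIL_W}, \code{VEG_D},
#' and the area label.
#'
#' @seealso [buildDetectionData()], [simulateDetectionData()], [fitJSDM()]
#' @export
setClass("DetectionData", contains = "SummarizedExperiment")

setValidity("DetectionData", function(object) {
  msg <- character()
  if (!"detections" %in% SummarizedExperiment::assayNames(object))
    return("assay 'detections' is required")
  y <- SummarizedExperiment::assay(object, "detections")
  cd <- SummarizedExperiment::colData(object)
  need <- c("effort", "TREE", "TRAIL_W", "VEG_D", "area")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  k <- cd$effort
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    msg <- c(msg, "detection counts must be non-negative integers")
  if (any(sweep(y, 2, k) > 1e-8))
    msg <- c(msg, "detection counts cannot exceed site effort")
  if (any(k < 1)) msg <- c(msg, "effort must be >= 1 trap-day")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the latent-variable multispecies occupancy model
#'
#' Container for the retained MCMC draws of every monitored quantity of the
#' joint species distribution model: occupancy coefficients (probit scale),
#' detection coefficients (logit scale), factor loadings theta, residual
#' variances sigma2 (= 1 - rowSums(theta^2), per draw), the latent occupancy
#' states z, the site-level factor scores l, and the per-draw residual
#' correlation matrix R = theta theta' + diag(sigma2).
#'
#' Arrays are indexed draws x species (x factor / site) with chain and
#' within-chain draw indices in parallel vectors.
#'
#' @slot species character, species labels.
#' @slot area character scalar, area label.
#' @slot chain integer vector, chain id per retained draw.
#' @slot draw integer vector, post-burn-in iteration number per draw.
#' @slot beta array draws x species x 2.
#' @slot gamma array draws x species x 3.
#' @slot theta array draws x species x T.
#' @slot sigma2 matrix draws x species.
#' @slot R array draws x species x species.
#' @slot z array draws x species x sites (0/1).
#' @slot l array draws x sites x T.
#' @slot y matrix species x sites, the data the model conditioned on.
#' @slot effort numeric, trap-days per site.
#' @slot warnings character, convergence warnings attached by [fitJSDM()].
#' @export
setClass("PosteriorSamples",
  representation(
    species = "character", area = "character",
    chain = "integer", draw = "integer",
    beta = "array", gamma = "array", theta = "array",
    sigma2 = "matrix", R = "array", z = "array", l = "array",
    y = "matrix", effort = "numeric", warnings = "character"
  )
)

setValidity("PosteriorSamples", function(object) {
  nd <- length(object@chain)
  if (length(object@draw) != nd) return("chain/draw index length mismatch")
  if (dim(object@beta)[1] != nd) return("beta draws mismatch")
  s2 <- 1 - apply(object@theta^2, c(1, 2), sum)
  if (max(abs(s2 - object@sigma2)) > 1e-6)
    return("sigma2 must equal 1 - rowSums(theta^2) in every draw")
  if (any(object@sigma2 < -1e-9)) return("negative residual variance")
  dg <- apply(object@R, 1, function(m) max(abs(diag(m) - 1)))
  if (any(dg > 1e-6)) return("per-draw R must have unit diagonal")
  TRUE
})

#' Circular (diel) activity density on an angular grid
#'
#' Von Mises kernel density estimate of a species' activity over the 24-h
#' cycle, represented on a uniform grid over [0, 2*pi) in solar-time
#' radians (solar noon at pi).  The density integrates to 1 over the circle.
#'
#' @slot grid numeric, grid angles in [0, 2*pi).
#' @slot density numeric, non-negative density values at the grid angles.
#' @slot kappa numeric scalar, the von Mises smoothing bandwidth used.
#' @slot n integer, number of records the estimate is based on.
#' @slot species character scalar label (may be empty).
#' @seealso [circularKDE()], [activityOverlap()], [modalRegion()]
#' @export
setClass("ActivityDensity",
  representation(grid = "numeric", density = "numeric", kappa = "numeric",
                 n = "integer", species = "character")
)

setValidity("ActivityDensity", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid/density length mismatch")
  if (any(object@density < -1e-12)) return("density must be non-negative")
  mass <- sum(object@density) * (2 * pi / length(object@grid))
  if (abs(mass - 1) > 1e-6) return("density must integrate to 1 over the circle")
  if (object@kappa <= 0) return("kappa must be positive")
  TRUE
})

#' Highest-density activity region (isopleth)
#'
#' The smallest set of angular arcs containing a given share (typically
#' 95\%) of an activity density: all angles whose density exceeds the
#' reported threshold.
#'
#' @slot level numeric, nominal coverage level in (0, 1).
#' @slot threshold numeric, density cut defining the region.
#' @slot arcs matrix with columns \code{start}, \code{end} (radians); arcs
#'   wrapping through 0 are split at 0.
#' @slot coverage numeric, density mass actually contained in the arcs.
#' @seealso [modalRegion()]
#' @export
setClass("Isopleth",
  representation(level = "numeric", threshold = "numeric", arcs = "matrix",
                 coverage = "numeric")
)

#' Fitted species-pair driver regression
#'
#' Result of a Gaussian identity-link model ([fitSpatialGLM()]) or a beta
#' regression ([fitBetaRegression()]) relating a co-occurrence response to
#' species-pair trait covariates with per-area coefficient blocks.
#'
#' @slot coefficients data.frame with columns term, estimate, se, statistic,
#'   p.value.
#' @slot family character, "gaussian" or "beta".
#' @slot r.squared numeric; ordinary R^2 (gaussian) or Ferrari--Cribari-Neto
#'   pseudo-R^2 (beta).
#' @slot logLik numeric, maximised log-likelihood.
#' @slot n integer, number of pair rows used.
#' @slot phi numeric, beta-regression precision (NA for gaussian).
#' @slot score numeric, max absolute score component at the optimum (beta
#'   only; NA for gaussian).
#' @slot vcov matrix, coefficient covariance.
#' @export
setClass("FitResult",
  representation(coefficients = "data.frame", family = "character",
                 r.squared = "numeric", logLik = "numeric", n = "integer",
                 phi = "numeric", score = "numeric", vcov = "matrix")
)

setValidity("FitResult", function(object) {
  if (!object@family %in% c("gaussian", "beta"))
    return("family must be 'gaussian' or 'beta'")
  if (any(object@coefficients$se <= 0, na.rm = TRUE))
    return("standard errors must be positive")
  TRUE
})
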