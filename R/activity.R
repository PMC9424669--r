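# Diel activity: von Mises circular kernel density estimation, bandwidth
# selection, highest-density activity isopleths, and pairwise overlap.

# ML von Mises concentration: solve I1(k)/I0(k) = Rbar (scaled Bessels keep
# large k finite)
.vm_mle_kappa <- function(rbar) {
  if (rbar <= 1e-8) return(0)
  if (rbar >= 1 - 1e-12) return(1e6)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - rbar
  stats::uniroot(A, c(1e-10, 2000), tol = 1e-12)$root
}

#' Select the circular kernel bandwidth for a sample of angles
#'
#' Plug-in von Mises rule: the concentration \eqn{\hat\kappa} is estimated
#' by maximum likelihood from the mean resultant length, then the smoothing
#' bandwidth is
#' \deqn{\kappa = \left[\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
#'   {4\sqrt{\pi} I_1(\hat\kappa)^2}\right]^{2/5}.}
#'
#' @param sample angles in radians, n >= 5.
#' @return positive bandwidth.  A sample with (numerically) zero resultant
#'   length carries no directional signal; the smallest positive bandwidth
#'   0.01 is returned with a warning.
#' @export
selectBandwidth <- function(sample) {
  n <- length(sample)
  if (n < 5) stop("need at least 5 records to select a bandwidth")
  C <- mean(cos(sample)); S <- mean(sin(sample))
  rbar <- sqrt(C^2 + S^2)
  if (rbar <= 1e-8) {
    warning("zero resultant length: returning smallest positive bandwidth")
    return(0.01)
  }
  kap <- .vm_mle_kappa(rbar)
  # scaled Bessel ratio: I2(2k)/I1(k)^2 = I2s(2k)/I1s(k)^2 (exp factors cancel)
  ratio <- besselI(2 * kap, 2, expon.scaled = TRUE) /
    besselI(kap, 1, expon.scaled = TRUE)^2
  bw <- (3 * n * kap^2 * ratio / (4 * sqrt(pi)))^(2 / 5)
  max(bw, 0.01)
}

#' Shared bandwidth for comparing two activity patterns
#'
#' When comparing two species' activity densities the higher of the two
#' species-specific bandwidths is maintained.
#'
#' @param kappa_a,kappa_b positive bandwidths.
#' @return \code{max(kappa_a, kappa_b)}.
#' @export
sharedBandwidth <- function(kappa_a, kappa_b) {
  if (kappa_a <= 0 || kappa_b <= 0) stop("bandwidths must be positive")
  max(kappa_a, kappa_b)
}

#' Circular kernel density estimate of a diel activity pattern
#'
#' Von Mises kernel density on a uniform angular grid,
#' \deqn{\hat f(\theta) = \frac{1}{n}\sum_r
#'   \frac{e^{\kappa\cos(\theta - x_r)}}{2\pi I_0(\kappa)},}
#' renormalized on the grid so it integrates to exactly 1 over the circle.
#'
#' @param sample angles in radians (non-empty).
#' @param kappa positive smoothing bandwidth (von Mises concentration).
#' @param grid_size number of grid angles (default 512).
#' @param species optional label.
#' @return an \linkS4class{ActivityDensity}.
#' @export
circularKDE <- function(sample, kappa, grid_size = 512, species = "") {
  if (length(sample) == 0) stop("empty sample")
  if (kappa <= 0) stop("kappa must be positive")
  g <- seq(0, 2 * pi, length.out = grid_size + 1)[seq_len(grid_size)]
  # kernel evaluated via exp(kappa*(cos-1)) and scaled I0 so large kappa
  # cannot overflow
  lI0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  d <- vapply(g, function(a)
    mean(exp(kappa * cos(a - sample) - lI0)) / (2 * pi), numeric(1))
  d <- d / (sum(d) * 2 * pi / grid_size)
  new("ActivityDensity", grid = g, density = d, kappa = kappa,
      n = length(sample), species = as.character(species))
}

#' Highest-density activity region (isopleth)
#'
#' Finds the smallest density threshold c such that the grid mass of
#' \{density >= c\} reaches \code{level}, and reports the region as angular
#' arcs.  Coverage can exceed the level by at most one grid cell's mass.
#'
#' @param density an \linkS4class{ActivityDensity}.
#' @param level coverage level in (0, 1); default 0.95.
#' @return an \linkS4class{Isopleth}.
#' @export
modalRegion <- function(density, level = 0.95) {
  stopifnot(is(density, "ActivityDensity"))
  if (level <= 0 || level >= 1) stop("level must be inside (0, 1)")
  G <- length(density@grid)
  dx <- 2 * pi / G
  ord <- order(density@density, decreasing = TRUE)
  cum <- cumsum(density@density[ord] * dx)
  m <- which(cum >= level)[1]
  if (is.na(m)) m <- G
  thr <- density@density[ord[m]]
  inreg <- density@density >= thr
  cov <- sum(density@density[inreg]) * dx
  # contiguous runs of grid cells -> arcs (cell i spans [g_i, g_i + dx))
  idx <- which(inreg)
  arcs <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (length(idx)) {
    brk <- c(0, which(diff(idx) > 1), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      run <- idx[(brk[b] + 1):brk[b + 1]]
      arcs <- rbind(arcs, c(density@grid[run[1]],
                            density@grid[run[length(run)]] + dx))
    }
  }
  new("Isopleth", level = level, threshold = thr, arcs = arcs,
      coverage = cov)
}

#' Activity-overlap coefficient between two diel densities
#'
#' Primary estimator: total-variation overlap
#' \eqn{\Delta = 1 - \frac{1}{2}\oint |f - g|\,d\theta}, 0 for perfectly
#' dissimilar activity and 1 for identical densities.  The alternative
#' \code{"conditional"} estimator is the mass of \code{f} inside
#' \code{g}'s \code{level}-isopleth divided by \code{level} (capped at 1);
#' it is directional in its arguments.
#'
#' @param f,g \linkS4class{ActivityDensity} objects on the same grid,
#'   computed with a shared bandwidth (see [sharedBandwidth()]).
#' @param estimator "tv" (default) or "conditional".
#' @param level isopleth level for the conditional estimator.
#' @return overlap coefficient in [0, 1].
#' @export
activityOverlap <- function(f, g, estimator = c("tv", "conditional"),
                            level = 0.95) {
  estimator <- match.arg(estimator)
  if (length(f@grid) != length(g@grid) || max(abs(f@grid - g@grid)) > 1e-12)
    stop("densities must share the same grid")
  dx <- 2 * pi / length(f@grid)
  if (estimator == "tv") {
    d <- 1 - 0.5 * sum(abs(f@density - g@density)) * dx
    return(min(max(d, 0), 1))
  }
  iso <- modalRegion(g, level)
  inreg <- g@density >= iso@threshold
  min(sum(f@density[inreg]) * dx / level, 1)
}

#' Pairwise diel activity overlap within areas
#'
#' For every area in a record table: selects each species' bandwidth,
#' excludes (with a message) species with fewer than \code{min_records}
#' independent records, and computes every unordered within-area pair's
#' overlap using the shared (larger) bandwidth, plus each species'
#' 95\% activity isopleth.
#'
#' @param records data.frame with columns species, solar_time, and
#'   optionally area (single area assumed if absent) and independent
#'   (only TRUE rows are used if present).
#' @param min_records minimum records per species (default 10).
#' @param grid_size KDE grid size.
#' @param estimator "tv", "conditional" or "both".
#' @param level isopleth level.
#' @return list with elements \code{overlaps} (data.frame: area, species_a,
#'   species_b, kappa, overlap, and the conditional columns when
#'   requested), \code{isopleths} (nested list by area then species),
#'   \code{excluded} (data.frame of species left out and why).
#' @export
pairwiseOverlap <- function(records, min_records = 10, grid_size = 512,
                            estimator = c("tv", "conditional", "both"),
                            level = 0.95) {
  estimator <- match.arg(estimator)
  if (!"area" %in% names(records)) records$area <- "all"
  if ("independent" %in% names(records))
    records <- records[records$independent, ]
  stopifnot("solar_time" %in% names(records))
  overlaps <- list(); isopleths <- list(); excluded <- list()
  for (a in unique(records$area)) {
    ra <- records[records$area == a, ]
    counts <- table(ra$species)
    drop <- names(counts)[counts < min_records]
    if (length(drop)) {
      message("area ", a, ": excluding species with < ", min_records,
              " records: ", paste(drop, collapse = ", "))
      excluded[[a]] <- data.frame(area = a, species = drop,
                                  n_records = as.integer(counts[drop]))
    }
    keep <- setdiff(names(counts), drop)
    if (length(keep) < 1) next
    samp <- lapply(keep, function(s) ra$solar_time[ra$species == s])
    names(samp) <- keep
    kap <- vapply(samp, selectBandwidth, numeric(1))
    dens_own <- lapply(keep, function(s)
      circularKDE(samp[[s]], kap[[s]], grid_size, species = s))
    names(dens_own) <- keep
    isopleths[[a]] <- lapply(dens_own, modalRegion, level = level)
    pr <- .pairs_of(keep)
    if (nrow(pr)) {
      pr$area <- a
      pr$kappa <- NA_real_; pr$overlap <- NA_real_
      if (estimator != "tv") {
        pr$overlap_cond_ab <- NA_real_; pr$overlap_cond_ba <- NA_real_
      }
      for (r in seq_len(nrow(pr))) {
        sa <- pr$species_a[r]; sb <- pr$species_b[r]
        kk <- sharedBandwidth(kap[[sa]], kap[[sb]])
        fa <- circularKDE(samp[[sa]], kk, grid_size, species = sa)
        fb <- circularKDE(samp[[sb]], kk, grid_size, species = sb)
        pr$kappa[r] <- kk
        if (estimator %in% c("tv", "both"))
          pr$overlap[r] <- activityOverlap(fa, fb, "tv")
        if (estimator != "tv") {
          pr$overlap_cond_ab[r] <- activityOverlap(fa, fb, "conditional",
                                                   level = level)
          pr$overlap_cond_ba[r] <- activityOverlap(fb, fa, "conditional",
                                                   level = level)
          if (estimator == "conditional")
            pr$overlap[r] <- pr$overlap_cond_ab[r]
        }
      }
      overlaps[[a]] <- pr[, c("area", setdiff(names(pr), "area"))]
    }
  }
  list(overlaps = if (length(overlaps)) do.call(rbind, c(overlaps,
         make.row.names = FALSE)) else NULL,
       isopleths = isopleths,
       excluded = if (length(excluded)) do.call(rbind, c(excluded,
         make.row.names = FALSE)) else NULL)
}
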