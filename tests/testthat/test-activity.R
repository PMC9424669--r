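test_that("bandwidth selection is monotone and matches its oracles", {
  set.seed(121)
  tight <- coocc:::.rvonmises(100, pi, 8)
  loose <- coocc:::.rvonmises(100, pi, 0.5)
  expect_gt(selectBandwidth(tight), selectBandwidth(loose))

  # duplicating every point doubles n and increases smoothing kappa
  expect_gt(selectBandwidth(c(tight, tight)), selectBandwidth(tight))

  expect_error(selectBandwidth(runif(4, 0, 2 * pi)), "at least 5")
  expect_warning(bw0 <- selectBandwidth(c(0, pi / 2, pi, 3 * pi / 2)
                                        [c(1, 2, 3, 4, 1, 2, 3, 4)]),
                 "resultant")
  expect_gt(bw0, 0)

  # cross-validation oracle: same order of magnitude for a vM(pi, 2) sample
  set.seed(2024)
  x <- coocc:::.rvonmises(200, pi, 2)
  bw <- selectBandwidth(x)
  kern <- function(d, kap) exp(kap * cos(d)) / (2 * pi * besselI(kap, 0,
                                                expon.scaled = TRUE) *
                                                  exp(kap))
  cv <- function(kap) {
    G <- 1024
    g <- seq(0, 2 * pi, length.out = G + 1)[1:G]
    f <- vapply(g, function(a) mean(kern(a - x, kap)), numeric(1))
    loo <- vapply(seq_along(x), function(i)
      mean(kern(x[i] - x[-i], kap)), numeric(1))
    sum(f^2) * 2 * pi / G - 2 * mean(loo)
  }
  k_cv <- optimize(cv, c(0.2, 100))$minimum
  expect_lt(abs(log10(bw / k_cv)), 1)
  # regression lock of the plug-in rule's exact value on this sample
  expect_equal(bw, 12.736769, tolerance = 1e-6)
})

test_that("shared bandwidth keeps the higher value", {
  expect_equal(sharedBandwidth(2, 5), 5)
  expect_equal(sharedBandwidth(3, 3), 3)
  expect_equal(sharedBandwidth(5, 2), sharedBandwidth(2, 5))
  expect_error(sharedBandwidth(0, 1), "positive")
})

test_that("circular KDE integrates to one and respects rotation", {
  x <- c(0.3, 1.2, 4.0)
  f <- circularKDE(x, kappa = 3)
  expect_equal(sum(f@density) * 2 * pi / length(f@grid), 1, tolerance = 1e-9)

  # a single observation puts the mode at the observation
  f1 <- circularKDE(2.1, kappa = 5, grid_size = 512)
  expect_lt(abs(f1@grid[which.max(f1@density)] - 2.1), 2 * pi / 512)

  # rotation equivariance (shift by a whole number of grid cells)
  shift_cells <- 32
  c0 <- 2 * pi * shift_cells / 512
  f_rot <- circularKDE(coocc:::.wrap_angle(x + c0), kappa = 3)
  expect_equal(f_rot@density,
               f@density[((seq_len(512) - 1 - shift_cells) %% 512) + 1],
               tolerance = 1e-10)

  # large-n consistency against the generating von Mises density
  set.seed(131)
  xs <- coocc:::.rvonmises(5000, 2, 3)
  fs <- circularKDE(xs, selectBandwidth(xs))
  expect_lt(max(abs(fs@density - vmDensity(fs@grid, 2, 3))), 0.05)

  expect_error(circularKDE(numeric(0), 1), "empty")
  expect_error(circularKDE(1, 0), "kappa")
})

test_that("modal regions are valid highest-density isopleths", {
  # exactly uniform density: the region must cover >= 95% of the circle
  g <- seq(0, 2 * pi, length.out = 513)[1:512]
  unif <- new("ActivityDensity", grid = g, density = rep(1 / (2 * pi), 512),
              kappa = 1, n = 10L, species = "")
  iso_u <- modalRegion(unif, 0.95)
  expect_gte(sum(iso_u@arcs[, 2] - iso_u@arcs[, 1]), 0.95 * 2 * pi - 1e-9)

  # unimodal von Mises: a single arc containing the mean direction
  f <- new("ActivityDensity", grid = g, density = vmDensity(g, pi, 4) /
             (sum(vmDensity(g, pi, 4)) * 2 * pi / 512),
           kappa = 4, n = 100L, species = "")
  iso <- modalRegion(f, 0.95)
  expect_equal(nrow(iso@arcs), 1)
  expect_true(iso@arcs[1, 1] <= pi && pi <= iso@arcs[1, 2])
  # coverage within one grid cell's mass of the level
  cell <- max(f@density) * 2 * pi / 512
  expect_gte(iso@coverage, 0.95)
  expect_lte(iso@coverage, 0.95 + cell)

  # antipodal bimodal mixture: two arcs against a fine-grid oracle
  dens <- 0.5 * vmDensity(g, 0.5, 8) + 0.5 * vmDensity(g, 0.5 + pi, 8)
  dens <- dens / (sum(dens) * 2 * pi / 512)
  fb <- new("ActivityDensity", grid = g, density = dens, kappa = 8,
            n = 100L, species = "")
  isob <- modalRegion(fb, 0.95)
  # arcs may be split at the 0 wrap; merge wrapped pieces when counting
  n_arcs <- nrow(isob@arcs)
  wraps <- isob@arcs[1, 1] < 1e-9 && abs(isob@arcs[n_arcs, 2] - 2 * pi) < 1e-9
  expect_equal(n_arcs - as.integer(wraps), 2)
  cellb <- max(fb@density) * 2 * pi / 512
  expect_lt(abs(isob@coverage - 0.95), cellb)

  expect_error(modalRegion(f, 1.2), "level")
})

test_that("overlap coefficient matches identities and quadrature", {
  set.seed(141)
  x <- coocc:::.rvonmises(300, 1, 3)
  f <- circularKDE(x, 10)
  expect_equal(activityOverlap(f, f), 1, tolerance = 1e-12)

  # near-disjoint supports
  a <- circularKDE(coocc:::.rvonmises(300, 0.5, 500), 400)
  b <- circularKDE(coocc:::.rvonmises(300, 0.5 + pi, 500), 400)
  expect_lt(activityOverlap(a, b), 1e-4)

  # symmetry and joint-rotation invariance
  y2 <- coocc:::.rvonmises(300, 2.5, 2)
  g2 <- circularKDE(y2, 10)
  expect_equal(activityOverlap(f, g2), activityOverlap(g2, f))
  c0 <- 2 * pi * 17 / 512
  f_r <- circularKDE(coocc:::.wrap_angle(x + c0), 10)
  g_r <- circularKDE(coocc:::.wrap_angle(y2 + c0), 10)
  expect_equal(activityOverlap(f_r, g_r), activityOverlap(f, g2),
               tolerance = 1e-10)

  # quadrature oracle on exact antipodal von Mises densities
  G <- 512
  gr <- seq(0, 2 * pi, length.out = G + 1)[1:G]
  d1 <- vmDensity(gr, 0, 4); d1 <- d1 / (sum(d1) * 2 * pi / G)
  d2 <- vmDensity(gr, pi, 4); d2 <- d2 / (sum(d2) * 2 * pi / G)
  f1 <- new("ActivityDensity", grid = gr, density = d1, kappa = 4,
            n = 1L, species = "")
  f2 <- new("ActivityDensity", grid = gr, density = d2, kappa = 4,
            n = 1L, species = "")
  got <- activityOverlap(f1, f2)
  fine <- seq(0, 2 * pi, length.out = 2^17 + 1)[1:2^17]
  oracle <- 1 - 0.5 * sum(abs(vmDensity(fine, 0, 4) -
                                vmDensity(fine, pi, 4))) *
    2 * pi / 2^17
  expect_lt(abs(got - oracle), 1e-4)

  # separation monotonicity at fixed concentration
  seps <- seq(0.2, pi, length.out = 6)
  ovs <- vapply(seps, function(s) {
    da <- vmDensity(gr, 0, 4); da <- da / (sum(da) * 2 * pi / G)
    db <- vmDensity(gr, s, 4); db <- db / (sum(db) * 2 * pi / G)
    activityOverlap(new("ActivityDensity", grid = gr, density = da,
                        kappa = 4, n = 1L, species = ""),
                    new("ActivityDensity", grid = gr, density = db,
                        kappa = 4, n = 1L, species = ""))
  }, numeric(1))
  expect_true(all(diff(ovs) < 0))

  # conditional estimator: self-overlap is exactly 1 by normalization
  expect_equal(activityOverlap(f, f, "conditional"), 1)
  expect_error(activityOverlap(f, circularKDE(x, 10, grid_size = 256)),
               "grid")
})

test_that("pairwise overlap enumerates within-area pairs with exclusions", {
  set.seed(151)
  mk <- function(n_sp, n_rec, area) {
    do.call(rbind, lapply(seq_len(n_sp), function(i)
      data.frame(species = sprintf("%s_sp%02d", area, i), area = area,
                 solar_time = coocc:::.rvonmises(n_rec, i %% 3, 2))))
  }
  r3 <- mk(3, 30, "A")
  out3 <- pairwiseOverlap(r3, min_records = 10)
  expect_equal(nrow(out3$overlaps), 3)
  expect_true(all(out3$overlaps$overlap >= 0 & out3$overlaps$overlap <= 1))

  r13 <- mk(13, 12, "B")
  expect_equal(nrow(pairwiseOverlap(r13, min_records = 10)$overlaps), 78)

  # one of nine species under the record minimum -> C(8,2) pairs
  r9 <- mk(9, 20, "C")
  r9 <- r9[-which(r9$species == "C_sp09")[1:15], ]
  expect_message(out9 <- pairwiseOverlap(r9, min_records = 10), "C_sp09")
  expect_equal(nrow(out9$overlaps), 28)
  expect_equal(out9$excluded$species, "C_sp09")
  # per-species isopleths accompany the pair table
  expect_equal(length(out9$isopleths$C), 8)
})
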