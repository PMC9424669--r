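test_that("simulated sites are standardized per area with truncated effort", {
  s <- simulateSites(100, "PA", mean_effort = 75, sd_effort = 15, seed = 1)
  expect_equal(nrow(s), 100)
  for (v in c("TREE", "TRAIL_W", "VEG_D")) {
    expect_lt(abs(mean(s[[v]])), 1e-9)
    expect_lt(abs(sd(s[[v]]) - 1), 1e-9)
  }
  expect_true(all(s$effort >= 1))
  expect_true(all(s$effort == round(s$effort)))
  expect_equal(as.numeric(s$deploy_end - s$deploy_start) + 1, s$effort)

  # degenerate noise: every site gets exactly the mean effort
  s0 <- simulateSites(10, "GR", mean_effort = 10, sd_effort = 0, seed = 2)
  expect_true(all(s0$effort == 10))

  # determinism contract
  expect_identical(simulateSites(50, "PR", seed = 7),
                   simulateSites(50, "PR", seed = 7))
  expect_error(simulateSites(1, "PA", seed = 1), "n_sites")
})

test_that("community coefficients respect the loading unit ball", {
  comm <- simulateCommunity(13, 7, seed = 3)
  expect_equal(dim(loadings(comm)), c(13, 7))
  expect_true(all(rowSums(loadings(comm)^2) <= 1 + 1e-12))

  # degenerate community: zero SDs collapse all species onto the means
  hp <- defaultHyperparams()
  hp$sigma[] <- 0
  hp$theta_scale <- 0
  c0 <- simulateCommunity(5, 2, hyperparams = hp, seed = 1)
  expect_true(all(apply(c0@beta, 2, sd) == 0))
  expect_true(all(apply(c0@gamma, 2, sd) == 0))

  expect_error(simulateCommunity(5, 0, seed = 1), "T")
  expect_error(simulateCommunity(5, 6, seed = 1), "T")
})

test_that("true residual correlation follows the loading identity", {
  expect_equal(trueResidualCorrelation(matrix(0, 4, 2)), diag(4))
  R <- trueResidualCorrelation(matrix(c(0.6, 0.8), 2, 1))
  expect_equal(R[1, 2], 0.48)
  expect_equal(diag(R), c(1, 1))
  # perfect dependence: both loadings at the ball boundary
  expect_equal(trueResidualCorrelation(matrix(c(1, 1), 2, 1))[1, 2], 1)
  # property: symmetric, unit diagonal, PSD for arbitrary communities
  for (s in 1:5) {
    comm <- simulateCommunity(sample(3:10, 1), sample(1:3, 1), seed = s)
    R <- trueResidualCorrelation(comm)
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, nrow(R)))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("detection generator honours the occupancy/detection layers", {
  sites <- simulateSites(60, "PA", mean_effort = 20, sd_effort = 0, seed = 2)
  comm <- nullCommunity(5, 2, seed = 4)

  # saturated occupancy: huge probit intercept, no factors
  comm_hi <- comm
  comm_hi@beta[, 1] <- 10
  sim <- simulateDetectionData(comm_hi, sites, seed = 9)
  expect_true(all(sim$truth$z == 1))
  y <- detections(sim$data)
  expect_true(all(y <= matrix(effort(sim$data), nrow(y), ncol(y),
                              byrow = TRUE)))

  # detection floor: tiny logit intercept suppresses counts, not occupancy
  comm_lo <- comm_hi
  comm_lo@gamma[, 1] <- -10
  comm_lo@gamma[, 2:3] <- 0
  sim2 <- simulateDetectionData(comm_lo, sites, seed = 9)
  expect_identical(sim2$truth$z, sim$truth$z)
  expect_lt(mean(detections(sim2$data)), 0.01)

  # counts vanish wherever the species is absent
  simg <- simulateDetectionData(simulateCommunity(5, 2, seed = 4), sites,
                                seed = 10)
  expect_true(all(detections(simg$data)[simg$truth$z == 0] == 0))
})

test_that("empirical occupancy matches the probit oracle", {
  sites <- simulateSites(2000, "PA", mean_effort = 10, sd_effort = 0,
                         seed = 5)
  comm <- nullCommunity(8, 2, seed = 6)
  sim <- simulateDetectionData(comm, sites, seed = 7)
  # oracle: marginal occupancy = mean_j Phi(beta0 + beta1 TREE_j); with
  # theta = 0 the residual is standard normal
  expected <- rowMeans(pnorm(comm@beta[, 1] +
                               outer(comm@beta[, 2], sites$TREE)))
  got <- rowMeans(sim$truth$z)
  expect_lt(max(abs(got - expected)), 3.5 * sqrt(0.25 / 2000) + 0.01)
})

test_that("simulated latent residuals reproduce the target correlation", {
  sites <- simulateSites(5000, "PA", mean_effort = 5, sd_effort = 0,
                         seed = 11)
  comm <- plantedCommunity(6, 2, rho = 0.7, seed = 12)
  sim <- simulateDetectionData(comm, sites, seed = 13)
  resid <- sim$truth$u - comm@beta[, 1] -
    outer(comm@beta[, 2], sites$TREE)
  emp <- cor(t(resid))
  expect_lt(max(abs(emp - trueResidualCorrelation(comm))), 0.05)
})

test_that("record simulation matches its circular ground truth", {
  sites <- simulateSites(10, "PA", mean_effort = 30, sd_effort = 0,
                         seed = 21)
  # near point mass at solar noon
  spec <- list(sp1 = data.frame(mu = pi, kappa = 1e6, w = 1))
  r <- simulateRecords(spec, 50, sites, seed = 22, cluster_frac = 0)
  lt <- as.POSIXlt(r$timestamp)
  frac <- (lt$hour * 3600 + lt$min * 60 + lt$sec) / 86400 * 2 * pi
  expect_lt(max(abs(frac - pi)), 0.01)

  # uniform activity: resultant length near zero at large n
  spec_u <- list(sp1 = data.frame(mu = 0, kappa = 0, w = 1))
  ru <- simulateRecords(spec_u, 4000, sites, seed = 23, cluster_frac = 0)
  ltu <- as.POSIXlt(ru$timestamp)
  a <- (ltu$hour * 3600 + ltu$min * 60 + ltu$sec) / 86400 * 2 * pi
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  expect_lt(rbar, 0.05)

  # determinism and clustered detections
  expect_identical(simulateRecords(spec, 20, sites, seed = 5),
                   simulateRecords(spec, 20, sites, seed = 5))
  rc <- simulateRecords(spec_u, 100, sites, seed = 24, cluster_frac = 0.3)
  expect_equal(nrow(rc), 130)
  flt <- filterIndependent(rc)
  expect_lt(nrow(flt), nrow(rc))
  expect_error(simulateRecords(list(), 10, sites, seed = 1), "empty")
})

test_that("trait table ranks are consistent with the mass thresholds", {
  tr <- defaultTraitTable()
  expect_equal(sum(tr$rank == "Apex"), 1)
  expect_true(all(tr$body_mass[tr$rank == "Large"] > 20))
  expect_true(all(tr$body_mass[tr$rank == "Medium"] >= 5 &
                    tr$body_mass[tr$rank == "Medium"] <= 20))
  expect_true(all(tr$body_mass[tr$rank == "Small"] < 5))
  expect_true(all(lengths(tr$diet) > 0))
  asm <- defaultAssemblages()
  expect_equal(lengths(asm), c(PA = 13L, PR = 11L, GR = 8L))
})
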