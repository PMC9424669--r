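test_that("pair trait primitives follow their definitions", {
  expect_equal(dietOverlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(dietOverlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(dietOverlap(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(dietOverlap(character(), "a"), "non-empty")

  expect_equal(bodyMassRatio(10, 5), 2)
  expect_equal(bodyMassRatio(5, 10), 2)
  expect_equal(bodyMassRatio(7, 7), 1)
  expect_equal(round(bodyMassRatio(170, 3), 2), 56.67)
  expect_error(bodyMassRatio(-1, 2), "positive")
})

test_that("pair table enumerates pairs with exclusive rank dummies", {
  tr <- defaultTraitTable()
  asm <- defaultAssemblages()
  pt <- buildPairTable(tr, asm)
  expect_equal(nrow(pt), 78 + 55 + 28)
  expect_equal(as.vector(table(pt$area)[c("PA", "PR", "GR")]),
               c(78L, 55L, 28L))

  # exactly one rank-pairing dummy fires per pair
  dcols <- paste0("dom_", gsub("\\|", "_", coocc:::.rank_pairings))
  expect_true(all(rowSums(pt[, dcols]) == 1))

  # apex x small carnivore pairing
  row <- pt[pt$area == "PA" & pt$pair_id ==
              coocc:::.pair_key("lion", "slender_mongoose"), ]
  expect_equal(row$dom_Apex_Small, 1)
  expect_equal(sum(row[, setdiff(dcols, "dom_Apex_Small")]), 0)
  expect_equal(row$dom_Apex_Any, 1)

  # two herpestids share a family
  row2 <- pt[pt$area == "PA" & pt$pair_id ==
               coocc:::.pair_key("banded_mongoose", "slender_mongoose"), ]
  expect_equal(row2$same_family, 1)
  expect_equal(row2$same_rank_Small, 1)

  # no apex pairings can exist in the game-ranch assemblage
  sz <- attr(pt, "structural_zeros")
  expect_true(all(c("dom_Apex_Small", "dom_Apex_Large") %in% sz$GR))

  # row count = sum of C(n_a, 2) for arbitrary assemblages
  asm2 <- list(X = tr$species[1:5], Y = tr$species[3:9])
  expect_equal(nrow(buildPairTable(tr, asm2)), choose(5, 2) + choose(7, 2))

  expect_error(buildPairTable(tr, list(A = c("lion", "unicorn"))), "unicorn")
})

test_that("collinearity screen keeps the stronger predictor", {
  set.seed(161)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.8^2) * rnorm(n)  # r ~ 0.8 with x1
  x3 <- rnorm(n)                               # independent
  y <- x1 + 0.2 * rnorm(n)                     # x1 is the true driver
  pt <- data.frame(a = x1, b = x2, c = x3, response_spatial = y)

  scr0 <- collinearityScreen(pt, c("a", "c"), "response_spatial")
  expect_equal(sort(scr0$retained), c("a", "c"))
  expect_equal(length(scr0$dropped), 0)

  scr <- collinearityScreen(pt, c("a", "b"), "response_spatial")
  expect_equal(scr$retained, "a")
  expect_equal(scr$dropped, "b")

  # duplicated covariate (r = 1): deterministic first-named tie-break
  pt$dup <- pt$a
  scr2 <- collinearityScreen(pt, c("a", "dup"), "response_spatial")
  expect_equal(scr2$retained, "a")
})

test_that("dominance preselection recovers a planted hierarchy effect", {
  tr <- defaultTraitTable()
  asm <- defaultAssemblages()
  base <- buildPairTable(tr, asm)
  hits <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    pt <- base
    pt$response_spatial <- -0.4 * pt$dom_Apex_Small + rnorm(nrow(pt), 0, 0.15)
    sel <- preselectDominance(pt, "spatial")
    hits <- hits + (sel$best == "dom_Apex_Small")
  }
  expect_gte(hits, 18)

  sel1 <- preselectDominance(base |> transform(
    response_spatial = rnorm(nrow(base))), "spatial",
    candidates = "dom_Large_Medium")
  expect_equal(sel1$best, "dom_Large_Medium")
  expect_error(preselectDominance(base, "spatial", candidates = character()),
               "structurally zero")
})

test_that("spatial OLS equals the normal-equations oracle", {
  tr <- defaultTraitTable()
  pt <- buildPairTable(tr, defaultAssemblages())
  set.seed(171)
  pt$response_spatial <- 0.1 - 0.2 * pt$dom_Apex_Small +
    0.15 * pt$body_mass_ratio / 10 + rnorm(nrow(pt), 0, 0.1)
  f <- coocc:::.driver_formula("response_spatial",
                               c("dom_Apex_Small", "same_family",
                                 "body_mass_ratio"))
  fit <- fitSpatialGLM(pt, f)
  # independent oracle: explicit normal equations
  X <- model.matrix(f, pt)
  X <- X[, colSums(X != 0) > 0]
  bhat <- solve(t(X) %*% X, t(X) %*% pt$response_spatial)
  expect_equal(coef(fit)$estimate, as.vector(bhat), tolerance = 1e-10)
  s2 <- sum((pt$response_spatial - X %*% bhat)^2) / (nrow(X) - ncol(X))
  se_oracle <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(coef(fit)$se, unname(se_oracle), tolerance = 1e-10)

  # exact interpolation: noise-free linear response recovered to 1e-10
  pt$response_spatial <- 0.3 - 0.1 * pt$dom_Apex_Small +
    0.02 * pt$body_mass_ratio
  fit2 <- fitSpatialGLM(pt, f)
  cf <- coef(fit2)
  expect_equal(cf$estimate[cf$term == "areaPA:body_mass_ratio"], 0.02,
               tolerance = 1e-10)
  expect_equal(fit2@r.squared, 1, tolerance = 1e-10)

  # aliased columns are reported by name
  pt$copy <- pt$dom_Apex_Small
  expect_error(fitSpatialGLM(pt, coocc:::.driver_formula(
    "response_spatial", c("dom_Apex_Small", "copy"))), "aliased")
})

test_that("beta regression maximizes the likelihood it reports", {
  set.seed(181)
  n <- 250
  x <- rnorm(n)
  mu <- plogis(0.4 + 0.8 * x)
  phi <- 25
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  d <- data.frame(x = x, y = y)
  fit <- fitBetaRegression(d, y ~ x)
  expect_lt(abs(coef(fit)$estimate[2] - 0.8), 2.5 * coef(fit)$se[2])
  expect_lt(abs(fit@phi - phi) / phi, 0.35)
  # score at the optimum vanishes
  expect_lt(fit@score, 1e-6)

  # optimality: log-likelihood beats any perturbed parameter on a grid
  X <- cbind(1, x)
  yc <- (y * (n - 1) + 0.5) / n
  par_hat <- c(coef(fit)$estimate, log(fit@phi))
  for (eps in c(-0.05, 0.05)) for (j in 1:3) {
    p <- par_hat; p[j] <- p[j] + eps
    expect_lte(coocc:::.beta_ll(p, X, yc), fit@logLik)
  }

  # intercept-only fit equals the ML beta mean (fitdistrplus oracle)
  fit0 <- fitBetaRegression(d, y ~ 1)
  ml <- suppressWarnings(fitdistrplus::fitdist(yc, "beta"))
  mu_ml <- ml$estimate[1] / sum(ml$estimate)
  expect_equal(plogis(coef(fit0)$estimate), unname(mu_ml),
               tolerance = 1e-4)

  # independent implementation cross-check (glmmTMB beta family)
  tmb <- glmmTMB::glmmTMB(y ~ x, data = data.frame(x = x, y = yc),
                          family = glmmTMB::beta_family())
  expect_equal(coef(fit)$estimate,
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 1e-3)

  expect_error(fitBetaRegression(data.frame(x = 1:5, y = c(0.1, 2, 0.3,
                                                           0.4, 0.5)),
                                 y ~ x), "lie in")
})

test_that("boundary responses are admissible via compression", {
  set.seed(191)
  n <- 120
  x <- rnorm(n)
  y <- plogis(x + rnorm(n, 0, 0.5))
  y[1:3] <- 0; y[4:6] <- 1  # exact boundary overlaps
  fit <- fitBetaRegression(data.frame(x = x, y = y), y ~ x)
  expect_true(is.finite(fit@logLik))
  expect_gt(coef(fit)$estimate[2], 0)
  # the compression moves interior observations by less than 1/(2n)
  yc <- (y * (n - 1) + 0.5) / n
  expect_lt(max(abs(yc - y)[y > 0 & y < 1]), 1 / (2 * n))
})

test_that("context comparison classifies shared pairs", {
  ss <- data.frame(
    species_a = c("a", "a", "b", "b", "c", "c"),
    species_b = c("b", "b", "c", "c", "d", "d"),
    area = rep(c("PA", "PR"), 3),
    mean = c(0.2, -0.1, 0.3, 0.1, -0.2, -0.05),
    evidence = "none")
  ov <- data.frame(species_a = c("a", "a", "b", "b"),
                   species_b = c("b", "b", "c", "c"),
                   area = rep(c("PA", "PR"), 2),
                   overlap = c(0.60, 0.65, 0.2, 0.6))
  ctx <- compareContexts(ss, ov)
  expect_equal(ctx$summary$n_shared_pairs, 3)
  # one of three pairs (a|b) flips sign across areas
  expect_equal(ctx$summary$pct_contrasting_sign, 100 / 3)
  # overlap differences: 0.05 (within 0.1) and 0.4 (not)
  expect_equal(ctx$summary$pct_overlap_within_0.1, 50)
  ab <- ctx$pairs[ctx$pairs$pair_id == "a|b", ]
  expect_true(ab$contrasting_sign)
  expect_equal(ab$max_overlap_diff, 0.05)
})
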