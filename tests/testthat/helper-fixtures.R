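# Shared fixtures, built in code.

# community with one planted residual correlation (rho between species 1, 2)
plantedCommunity <- function(n_species = 8, T = 2, rho = 0.7, seed = 1) {
  comm <- simulateCommunity(n_species, T, seed = seed)
  th <- matrix(0, n_species, T)
  th[1, 1] <- sqrt(rho)
  th[2, 1] <- sqrt(rho)
  rownames(th) <- comm@species
  comm@theta <- th
  comm@rescaled <- rep(FALSE, n_species)
  validObject(comm)
  comm
}

nullCommunity <- function(n_species = 8, T = 2, seed = 1) {
  comm <- simulateCommunity(n_species, T, seed = seed)
  comm@theta[] <- 0
  comm@rescaled <- rep(FALSE, n_species)
  comm
}

# tiny record table with explicit timestamps (UTC)
recordsAt <- function(species, site, times) {
  data.frame(species = species, site_id = site,
             timestamp = as.POSIXct(times, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# minimal site table for hand-built record fixtures
tinySites <- function(ids = "s1", effort = 30, start = "2017-08-01",
                      longitude = 30) {
  start <- as.Date(start)
  data.frame(site_id = ids, area = "PA", TREE = 0, TRAIL_W = 0, VEG_D = 0,
             effort = effort, longitude = longitude, deploy_start = start,
             deploy_end = start + effort - 1, stringsAsFactors = FALSE)
}

# exact von Mises density on a grid
vmDensity <- function(x, mu, kappa)
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))

# PosteriorSamples with crafted correlation draws via a single loading pair:
# R12 per draw = th1 * th2
craftedPosterior <- function(th1, th2, chains = 1) {
  nd <- length(th1)
  theta <- array(0, c(nd, 2, 1))
  theta[, 1, 1] <- th1; theta[, 2, 1] <- th2
  sigma2 <- cbind(1 - th1^2, 1 - th2^2)
  R <- array(0, c(nd, 2, 2))
  for (d in seq_len(nd))
    R[d, , ] <- residualCorrelation(matrix(c(th1[d], th2[d]), 2, 1),
                                    sigma2[d, ])
  new("PosteriorSamples", species = c("a", "b"), area = "PA",
      chain = rep(seq_len(chains), length.out = nd), draw = seq_len(nd),
      beta = array(0, c(nd, 2, 2)), gamma = array(0, c(nd, 2, 3)),
      theta = theta, sigma2 = sigma2, R = R,
      z = array(1L, c(nd, 2, 1)), l = array(0, c(nd, 1, 1)),
      y = matrix(1L, 2, 1), effort = 1, warnings = character())
}
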