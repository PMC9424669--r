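# End-to-end orchestration: simulate -> prep -> fit-jsdm -> activity ->
# drivers -> report, from a single validated config with named seed
# substreams and a reproducibility manifest.

.known_config_keys <- c("areas", "seed", "out_dir", "mean_effort",
                        "sd_effort", "n_records", "gap_minutes",
                        "min_records", "estimator", "jsdm", "hyperparams",
                        "traits", "start_date", "tz_offset", "cluster_frac")
.known_area_keys <- c("n_sites", "assemblage", "T")
.known_jsdm_keys <- c("n_chains", "n_iter", "n_burn", "thin")

#' Default pipeline configuration
#'
#' The built-in synthetic landscape: three areas with 100/100/50 camera
#' sites, assemblages of 13/11/8 carnivore species, about 75 +/- 15
#' trap-days of effort, n/2 latent factors per area, and the full MCMC
#' settings (3 chains, 30000 retained iterations after 10000 burn-in,
#' thinned by 10).  Override any element for smaller runs.
#'
#' @param seed master seed for all substreams.
#' @return a validated config list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  asm <- defaultAssemblages()
  list(
    areas = list(
      PA = list(n_sites = 100, assemblage = asm$PA, T = 7),
      PR = list(n_sites = 100, assemblage = asm$PR, T = 6),
      GR = list(n_sites = 50, assemblage = asm$GR, T = 5)
    ),
    seed = as.integer(seed), out_dir = NULL,
    mean_effort = 75, sd_effort = 15,
    n_records = 150, gap_minutes = 60, min_records = 10,
    estimator = "tv",
    jsdm = list(n_chains = 3, n_iter = 30000, n_burn = 10000, thin = 10),
    hyperparams = defaultHyperparams(),
    traits = defaultTraitTable(),
    start_date = "2017-08-01", tz_offset = 2, cluster_frac = 0.2
  )
}

#' Validate a pipeline configuration
#'
#' Fills unset elements from [defaultRunConfig()] and rejects unknown keys
#' by name.
#'
#' @param config list (possibly partial) or path to a YAML file.
#' @return the completed config list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), .known_config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base <- defaultRunConfig()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  if (length(base$areas) == 0) stop("config must define at least one area")
  for (a in names(base$areas)) {
    bad <- setdiff(names(base$areas[[a]]), .known_area_keys)
    if (length(bad))
      stop("unknown key(s) in area ", a, ": ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(base$jsdm), .known_jsdm_keys)
  if (length(bad))
    stop("unknown key(s) in jsdm config: ", paste(bad, collapse = ", "))
  base
}

.digest_file <- function(path) unname(tools::md5sum(path))

#' Run the full co-occurrence pipeline on synthetic data
#'
#' Executes, in order: site/community/detection/record simulation per area,
#' record preparation (independence filter and solar time), the JSDM fit
#' per area, pairwise activity overlap, the driver regressions, and the
#' summary report.  Every stage draws from its own named substream of the
#' master seed.  When \code{config$out_dir} is set, each stage writes its
#' outputs as CSV (plus a JSON truth sidecar) and the returned manifest
#' records per-stage outputs, wall times and file digests.
#'
#' @param config config list or YAML path; see [defaultRunConfig()].
#' @return list with elements per stage (sites, records, detection, truth,
#'   fits, spatial, activity, pairs, drivers, report) plus \code{manifest}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- validateRunConfig(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list())
  res <- list(config = config)
  emit <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
      outputs = files,
      digests = if (length(files)) vapply(files, .digest_file,
                                          character(1)) else character())
  }

  # ---- stage 1: simulate ----
  t0 <- as.numeric(Sys.time())
  sites <- list(); dets <- list(); truths <- list(); recs <- list()
  files <- character()
  for (ai in seq_along(config$areas)) {
    a <- names(config$areas)[ai]
    ar <- config$areas[[a]]
    asm <- ar$assemblage
    if (length(asm) < 2) { message("area ", a, " omitted: assemblage too small"); next }
    sa <- simulateSites(ar$n_sites, a, config$mean_effort, config$sd_effort,
                        seed = substreamSeed(config$seed, "sites", ai),
                        start_date = config$start_date)
    TT <- if (!is.null(ar$T)) ar$T else defaultFactorCount(length(asm))
    comm <- simulateCommunity(length(asm), TT,
                              hyperparams = config$hyperparams,
                              seed = substreamSeed(config$seed, "community", ai),
                              species = asm)
    sim <- simulateDetectionData(comm, sa,
                                 seed = substreamSeed(config$seed, "occupancy", ai))
    spec <- defaultActivitySpec(asm)
    rr <- simulateRecords(spec, config$n_records, sa,
                          seed = substreamSeed(config$seed, "records", ai),
                          cluster_frac = config$cluster_frac)
    rr$area <- a
    sites[[a]] <- sa; dets[[a]] <- sim$data
    truths[[a]] <- c(sim$truth, list(params = comm)); recs[[a]] <- rr
    if (!is.null(out_dir)) {
      f1 <- file.path(out_dir, paste0("sites_", a, ".csv"))
      writeSiteTable(sa, f1)
      f2 <- file.path(out_dir, paste0("records_", a, ".csv"))
      writeRecordTable(rr, f2)
      stem <- file.path(out_dir, paste0("detection_", a))
      writeDetectionData(sim$data, stem)
      f4 <- file.path(out_dir, paste0("truth_", a, ".json"))
      jsonlite::write_json(list(R = sim$truth$R, z = sim$truth$z),
                           f4, digits = NA, matrix = "rowmajor")
      files <- c(files, f1, f2, paste0(stem, "_counts.csv"),
                 paste0(stem, "_sites.csv"), f4)
    }
  }
  if (!length(sites)) stop("no usable areas in config")
  emit("simulate", files, t0)

  # ---- stage 2: prep ----
  t0 <- as.numeric(Sys.time()); files <- character()
  prepped <- list()
  for (a in names(recs)) {
    pa <- annotateRecords(recs[[a]], sites[[a]],
                          gap_minutes = config$gap_minutes,
                          tz_offset = config$tz_offset)
    prepped[[a]] <- pa
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0("records_independent_", a, ".csv"))
      writeRecordTable(pa[pa$independent, ], f)
      files <- c(files, f)
    }
  }
  records <- do.call(rbind, c(prepped, make.row.names = FALSE))
  emit("prep", files, t0)

  # ---- stage 3: fit-jsdm ----
  t0 <- as.numeric(Sys.time()); files <- character()
  fits <- list(); spat <- list()
  for (ai in seq_along(sites)) {
    a <- names(sites)[ai]
    cfgT <- config$areas[[a]]$T
    cfg <- jsdmConfig(T = cfgT,
                      n_chains = config$jsdm$n_chains,
                      n_iter = config$jsdm$n_iter,
                      n_burn = config$jsdm$n_burn,
                      thin = config$jsdm$thin,
                      seed = substreamSeed(config$seed, "jsdm", ai))
    fits[[a]] <- fitJSDM(dets[[a]], cfg)
    spat[[a]] <- summarizeCorrelations(fits[[a]])
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0("spatial_", a, ".csv"))
      write.csv(spat[[a]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  spatial <- do.call(rbind, c(spat, make.row.names = FALSE))
  emit("fit_jsdm", files, t0)

  # ---- stage 4: activity ----
  t0 <- as.numeric(Sys.time()); files <- character()
  act <- pairwiseOverlap(records, min_records = config$min_records,
                         estimator = config$estimator)
  if (!is.null(out_dir) && !is.null(act$overlaps)) {
    f <- file.path(out_dir, "activity_overlap.csv")
    write.csv(act$overlaps, f, row.names = FALSE)
    files <- c(files, f)
  }
  emit("activity", files, t0)

  # ---- stage 5: drivers ----
  t0 <- as.numeric(Sys.time()); files <- character()
  assemblages <- lapply(config$areas[names(sites)], `[[`, "assemblage")
  pairs <- buildPairTable(config$traits, assemblages, spatial, act$overlaps)
  pairs$response_spatial_other <- pairs$response_temporal
  pairs$response_temporal_other <- pairs$response_spatial
  drv <- .fit_drivers(pairs)
  if (!is.null(out_dir)) {
    f1 <- file.path(out_dir, "pair_table.csv")
    write.csv(pairs, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "driver_coefficients.csv")
    write.csv(drv$coefficients, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  emit("drivers", files, t0)

  # ---- stage 6: report ----
  t0 <- as.numeric(Sys.time()); files <- character()
  res <- c(res, list(sites = sites, records = records, detection = dets,
                     truth = truths, fits = fits, spatial = spatial,
                     activity = act, pairs = pairs, drivers = drv))
  rep <- cooccReport(res)
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "report.txt")
    writeLines(rep$text, f)
    files <- c(files, f)
  }
  emit("report", files, t0)
  res$report <- rep
  res$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  res
}

# driver regressions on a finished pair table (both responses)
.fit_drivers <- function(pairs) {
  es_cov <- c("same_rank_Large", "same_rank_Medium", "same_rank_Small",
              "same_family", "body_mass_ratio", "body_mass_ratio2")
  scr <- collinearityScreen(pairs, c("body_mass_ratio", "diet_overlap"),
                            response = "response_spatial")
  out <- list(collinearity = scr)
  ok_sp <- sum(!is.na(pairs$response_spatial)) > 20
  ok_tm <- sum(!is.na(pairs$response_temporal)) > 20
  coefs <- list()
  if (ok_sp) {
    pre_s <- preselectDominance(pairs, "spatial")
    covs <- unique(c(pre_s$best, es_cov, "response_spatial_other"))
    covs <- setdiff(covs, scr$dropped)
    covs <- .prune_aliased(pairs, "response_spatial",
                           .nonzero(pairs, covs))
    fit_s <- fitSpatialGLM(pairs, .driver_formula("response_spatial", covs))
    out$preselect_spatial <- pre_s
    out$spatial <- fit_s
    coefs$spatial <- cbind(response = "spatial", coef(fit_s))
  }
  if (ok_tm) {
    pre_t <- preselectDominance(pairs, "temporal")
    covs <- unique(c(pre_t$best, es_cov, "response_temporal_other"))
    covs <- setdiff(covs, scr$dropped)
    covs <- .prune_aliased(pairs, "response_temporal",
                           .nonzero(pairs, covs))
    fit_t <- fitBetaRegression(pairs, .driver_formula("response_temporal",
                                                      covs))
    out$preselect_temporal <- pre_t
    out$temporal <- fit_t
    coefs$temporal <- cbind(response = "temporal", coef(fit_t))
  }
  out$coefficients <- if (length(coefs))
    do.call(rbind, c(coefs, make.row.names = FALSE)) else data.frame()
  out
}

# drop covariates whose per-area blocks are aliased with earlier columns
# (small assemblages can make rank dummies exact duplicates); keeps the
# earlier-listed covariate, deterministically
.prune_aliased <- function(pairs, response, covs) {
  repeat {
    f <- .driver_formula(response, covs)
    d <- pairs[!is.na(pairs[[response]]), ]
    X <- stats::model.matrix(f, d)
    X <- X[, colSums(X != 0) > 0, drop = FALSE]
    qrx <- qr(X)
    if (qrx$rank == ncol(X)) return(covs)
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    bad <- unique(sub("^area[^:]*:", "", aliased))
    bad <- intersect(bad, covs)
    if (!length(bad)) stop("cannot resolve aliased design columns: ",
                           paste(aliased, collapse = ", "))
    message("dropping aliased driver covariate(s): ",
            paste(bad, collapse = ", "))
    covs <- setdiff(covs, bad)
  }
}

.nonzero <- function(pairs, covs)
  covs[vapply(covs, function(v) {
    x <- pairs[[v]]; sum(x != 0, na.rm = TRUE) > 0 &&
      sd(x, na.rm = TRUE) > 0
  }, logical(1))]

#' Summary report of a pipeline run
#'
#' Recomputes the run's headline numbers from its stage outputs: per-area
#' pair counts, assemblage-level summaries of both co-occurrence
#' dimensions, the strong-evidence pair list, context-dependency
#' percentages, driver coefficient tables, and (when the synthetic truth is
#' available) recovery diagnostics comparing estimated with true residual
#' correlations.
#'
#' @param run the list returned by [runPipeline()].
#' @return list with data pieces and a plain-text rendering in
#'   \code{$text}.
#' @export
cooccReport <- function(run) {
  stopifnot(!is.null(run$spatial))
  counts <- table(run$spatial$area)
  spatial_sum <- assemblageSummary(data.frame(area = run$spatial$area,
                                              value = run$spatial$mean))
  strong <- run$spatial[run$spatial$evidence == "strong", ]
  ctx <- compareContexts(run$spatial, run$activity$overlaps)
  overlap_sum <- if (!is.null(run$activity$overlaps))
    assemblageSummary(data.frame(area = run$activity$overlaps$area,
                                 value = run$activity$overlaps$overlap))
  else NULL
  recovery <- NULL
  if (!is.null(run$truth)) {
    recovery <- do.call(rbind, lapply(names(run$fits), function(a) {
      fit <- run$fits[[a]]
      trueR <- run$truth[[a]]$R
      sp <- speciesNames(fit)
      trueR <- trueR[sp, sp]
      estR <- apply(correlationDraws(fit), c(2, 3), mean)
      off <- upper.tri(trueR)
      data.frame(area = a,
                 rmse_R = sqrt(mean((estR[off] - trueR[off])^2)),
                 cor_R = if (sd(trueR[off]) > 0)
                   cor(estR[off], trueR[off]) else NA_real_)
    }))
  }
  txt <- c(
    "Co-occurrence pipeline report",
    sprintf("Species pairs per area: %s (total %d)",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", "), sum(counts)),
    "", "Assemblage-level residual occupancy correlation:",
    utils::capture.output(print(spatial_sum, row.names = FALSE)),
    "", sprintf("Strong-evidence pairs (sign prob > 0.9): %d", nrow(strong)),
    if (nrow(strong)) utils::capture.output(
      print(strong[, c("area", "species_a", "species_b", "mean",
                       "sign_prob")], row.names = FALSE)),
    "", sprintf("Context-dependency: %.1f%% contrasting-sign pairs; %.1f%% overlap diffs <= 0.1 (n shared = %d)",
                ctx$summary$pct_contrasting_sign,
                ctx$summary$pct_overlap_within_0.1,
                ctx$summary$n_shared_pairs))
  if (!is.null(overlap_sum))
    txt <- c(txt, "", "Assemblage-level activity overlap:",
             utils::capture.output(print(overlap_sum, row.names = FALSE)))
  if (!is.null(recovery))
    txt <- c(txt, "", "Truth recovery (synthetic run):",
             utils::capture.output(print(recovery, row.names = FALSE)))
  list(pair_counts = counts, spatial_summary = spatial_sum,
       overlap_summary = overlap_sum, strong_pairs = strong,
       context = ctx, recovery = recovery, text = txt)
}
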