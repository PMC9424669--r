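#' @rdname coocc-accessors
#' @aliases detections,DetectionData-method
setMethod("detections", "DetectionData", function(object)
  SummarizedExperiment::assay(object, "detections"))

#' @rdname coocc-accessors
setMethod("effort", "DetectionData", function(object)
  SummarizedExperiment::colData(object)$effort)

#' @rdname coocc-accessors
setMethod("siteCovariates", "DetectionData", function(object) {
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  cd[, c("TREE", "TRAIL_W", "VEG_D"), drop = FALSE]
})

#' @rdname coocc-accessors
setMethod("areaName", "DetectionData", function(object)
  as.character(SummarizedExperiment::colData(object)$area[1]))

#' @rdname coocc-accessors
setMethod("speciesNames", "DetectionData", function(object) rownames(object))

#' @rdname coocc-accessors
setMethod("nSpecies", "DetectionData", function(object) nrow(object))

#' @rdname coocc-accessors
setMethod("speciesNames", "CommunityParams", function(object) object@species)

#' @rdname coocc-accessors
setMethod("nSpecies", "CommunityParams", function(object) length(object@species))

#' @rdname coocc-accessors
setMethod("loadings", "CommunityParams", function(object) object@theta)

#' @rdname coocc-accessors
setMethod("speciesNames", "PosteriorSamples", function(object) object@species)

#' @rdname coocc-accessors
setMethod("nSpecies", "PosteriorSamples", function(object) length(object@species))

#' @rdname coocc-accessors
setMethod("loadings", "PosteriorSamples", function(object) object@theta)

#' @rdname coocc-accessors
setMethod("correlationDraws", "PosteriorSamples", function(object) object@R)

#' @rdname coocc-accessors
setMethod("bandwidth", "ActivityDensity", function(object) object@kappa)

setMethod("show", "CommunityParams", function(object) {
  cat("CommunityParams:", length(object@species), "species,",
      ncol(object@theta), "latent factor(s)\n")
  cat("  occupancy beta0 range:",
      paste(sprintf("%.2f", range(object@beta[, 1])), collapse = " .. "), "\n")
  cat("  loadings rescaled for", sum(object@rescaled), "species\n")
})

setMethod("show", "DetectionData", function(object) {
  cat("DetectionData (", areaName(object), "): ", nrow(object), " species x ",
      ncol(object), " sites, ", sum(effort(object)), " trap-days\n", sep = "")
  callNextMethod()
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples (", object@area, "): ", length(object@chain),
      " draws (", length(unique(object@chain)), " chains), ",
      length(object@species), " species, ",
      dim(object@theta)[3], " latent factor(s)\n", sep = "")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ActivityDensity", function(object) {
  cat("ActivityDensity", if (nzchar(object@species)) paste0("(", object@species, ")"),
      ": n =", object@n, ", kappa =", signif(object@kappa, 4),
      ", grid size", length(object@grid), "\n")
})

setMethod("show", "Isopleth", function(object) {
  cat("Isopleth: level", object@level, "->", nrow(object@arcs),
      "arc(s), coverage", signif(object@coverage, 4), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@family, "): n = ", object@n,
      ", R2 = ", signif(object@r.squared, 3),
      ", logLik = ", signif(object@logLik, 6), "\n", sep = "")
  print(object@coefficients, digits = 3)
})

#' Extract the coefficient table of a driver regression
#'
#' @param object a \linkS4class{FitResult}.
#' @param ... ignored.
#' @return data.frame with columns term, estimate, se, statistic, p.value.
#' @export
setMethod("coef", "FitResult", function(object, ...) object@coefficients)

#' @describeIn FitResult maximised log-likelihood.
#' @param object a FitResult.
#' @export
setMethod("logLik", "FitResult", function(object, ...) object@logLik)
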