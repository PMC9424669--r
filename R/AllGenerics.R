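#' Accessors for coocc S4 containers
#'
#' Small family of accessor generics: \code{detections()} returns the
#' species x site count matrix, \code{effort()} the trap-days per site,
#' \code{siteCovariates()} the standardized site covariate table,
#' \code{areaName()} the area label, \code{speciesNames()} the species
#' labels, \code{nSpecies()} their number, \code{loadings()} the
#' latent-factor loading matrix, and \code{correlationDraws()} the per-draw
#' residual correlation array.
#'
#' @param object a coocc S4 object.
#' @return See the individual method descriptions.
#' @name coocc-accessors
NULL

#' @rdname coocc-accessors
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname coocc-accessors
#' @export
setGeneric("effort", function(object) standardGeneric("effort"))

#' @rdname coocc-accessors
#' @export
setGeneric("siteCovariates", function(object) standardGeneric("siteCovariates"))

#' @rdname coocc-accessors
#' @export
setGeneric("areaName", function(object) standardGeneric("areaName"))

#' @rdname coocc-accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname coocc-accessors
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' @rdname coocc-accessors
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' @rdname coocc-accessors
#' @export
setGeneric("correlationDraws", function(object) standardGeneric("correlationDraws"))

#' @rdname coocc-accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
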