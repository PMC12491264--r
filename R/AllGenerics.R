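#' @rdname OmicLayer
#' @param object,x an object.
#' @export
setGeneric("layerKind", function(object) standardGeneric("layerKind"))

#' @rdname RCDInventory-class
#' @param object an object.
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname PanCancerCohort-class
#' @param object an object.
#' @export
setGeneric("cancerCode", function(object) standardGeneric("cancerCode"))

#' @rdname PanCancerCohort-class
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname PanCancerCohort-class
#' @export
setGeneric("omicLayer",
           function(object, layer, normal = FALSE)
             standardGeneric("omicLayer"))

#' @rdname PanCancerCohort-class
#' @export
setGeneric("infiltrationScores",
           function(object) standardGeneric("infiltrationScores"))

#' @rdname PanCancerCohort-class
#' @export
setGeneric("inventory", function(object) standardGeneric("inventory"))

#' @rdname PanCancerCohort-class
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

#' Survival table for one endpoint
#'
#' @param object a [PanCancerCohort-class].
#' @param endpoint one of [survivalEndpoints()].
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
setGeneric("endpointSurvival",
           function(object, endpoint) standardGeneric("endpointSurvival"))
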