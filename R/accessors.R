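#' @rdname OmicLayer
#' @export
setMethod("layerKind", "OmicLayer", function(object) object@layerKind)

#' @rdname RCDInventory-class
#' @export
setMethod("membership", "RCDInventory", function(object) object@membership)

#' @describeIn RCDInventory-class genes present in the inventory.
#' @param x an `RCDInventory`.
#' @export
setMethod("names", "RCDInventory", function(x) names(x@membership))

#' @describeIn RCDInventory-class number of genes.
#' @export
setMethod("length", "RCDInventory", function(x) length(x@membership))

#' @describeIn RCDInventory-class form set of one gene.
#' @param i gene identifier.
#' @param j,... unused.
#' @export
setMethod("[[", "RCDInventory", function(x, i, j, ...) {
  if (!i %in% names(x@membership))
    stop("gene '", i, "' is not in the inventory")
  x@membership[[i]]
})

setMethod("show", "RCDInventory", function(object) {
  cat("RCDInventory with", length(object), "genes over",
      length(rcdForms()), "RCD forms\n")
  if (length(object)) {
    n <- vapply(object@membership, length, integer(1))
    cat(sprintf("  multi-form genes: %d (%.1f%%)\n",
                sum(n >= 2), 100 * mean(n >= 2)))
    ap <- vapply(object@membership, function(f) "apoptosis" %in% f,
                 logical(1))
    cat(sprintf("  apoptosis-associated: %d (%.1f%%)\n",
                sum(ap), 100 * mean(ap)))
  }
})

setMethod("show", "OmicLayer", function(object) {
  cat(sprintf("OmicLayer '%s': %d features x %d samples\n",
              object@layerKind, nrow(object), ncol(object)))
  callNextMethod()
})

#' @rdname PanCancerCohort-class
#' @export
setMethod("cancerCode", "PanCancerCohort", function(object) object@cancerCode)

#' @rdname PanCancerCohort-class
#' @export
setMethod("phenotypes", "PanCancerCohort", function(object) object@phenotypes)

#' @rdname PanCancerCohort-class
#' @param layer layer name.
#' @param normal logical; return the matched non-tumor layer instead.
#' @export
setMethod("omicLayer", "PanCancerCohort", function(object, layer,
                                                   normal = FALSE) {
  pool <- if (normal) object@normals else object@layers
  if (!layer %in% names(pool)) {
    if (normal) return(NULL)
    stop("cohort has no layer '", layer, "'")
  }
  pool[[layer]]
})

#' @rdname PanCancerCohort-class
#' @export
setMethod("infiltrationScores", "PanCancerCohort",
          function(object) object@infiltration)

#' @rdname PanCancerCohort-class
#' @export
setMethod("inventory", "PanCancerCohort", function(object) object@inventory)

#' @rdname PanCancerCohort-class
#' @export
setMethod("plantedTruth", "PanCancerCohort", function(object) object@truth)

#' @rdname endpointSurvival
#' @export
setMethod("endpointSurvival", "PanCancerCohort", function(object, endpoint) {
  endpoint <- match.arg(endpoint, survivalEndpoints())
  ph <- object@phenotypes
  data.frame(sample = rownames(ph),
             time = ph[[paste0(endpoint, "_time")]],
             event = ph[[paste0(endpoint, "_event")]],
             row.names = NULL)
})

setMethod("show", "PanCancerCohort", function(object) {
  cat(sprintf("PanCancerCohort %s: %d tumor samples\n",
              object@cancerCode, nrow(object@phenotypes)))
  for (nm in names(object@layers)) {
    l <- object@layers[[nm]]
    nn <- if (nm %in% names(object@normals))
      ncol(object@normals[[nm]]) else 0L
    cat(sprintf("  %-12s %5d features%s\n", nm, nrow(l),
                if (nn) sprintf(" (+%d normal samples)", nn) else ""))
  }
  cat(sprintf("  inventory: %d genes; planted effects: %d\n",
              length(object@inventory),
              if (is.null(object@truth)) 0L else nrow(object@truth)))
})

setMethod("show", "SignatureIdentifier", function(object) {
  cat(formatIdentifier(object), "\n")
})
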