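#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' RCDInventory: gene to RCD-form membership
#'
#' Maps each gene of the regulated-cell-death inventory to the non-empty
#' subset of the 25 RCD forms it is term-associated with. Membership is
#' tagging, stored as data: it records literature/term association, not
#' functional or causative involvement.
#'
#' @slot membership named list; each element a character vector of form
#'   tokens drawn from [rcdForms()].
#' @seealso [loadInventory()], [generateRCDInventory()], [sharedForms()]
#' @export
setClass("RCDInventory", representation(membership = "list"))

setValidity("RCDInventory", function(object) {
  m <- object@membership
  if (length(m) == 0L) return(TRUE)
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("all genes must be named")
  if (anyDuplicated(names(m)))
    return("duplicate gene names in membership")
  ok <- vapply(m, function(f) length(f) >= 1L && all(f %in% rcdForms()),
               logical(1))
  if (!all(ok)) {
    bad <- names(m)[!ok][1L]
    return(sprintf("gene '%s' has an empty or out-of-vocabulary form set",
                   bad))
  }
  TRUE
})

#' OmicLayer: one omic layer's feature-by-sample matrix
#'
#' A `SummarizedExperiment` holding a single assay `"values"` (features in
#' rows, samples in columns) together with the layer kind. `rowData` carries
#' `gene`, the parent gene symbol of each feature, used for RCD-form lookup
#' and for bi-layer annotation (companion mRNA of the same locus).
#' Validity enforces the layer codomains: mutation values in \{0, 1\}, CNV in
#' \{-2, ..., 2\}, methylation beta values in \[0, 1\].
#'
#' @slot layerKind one of [omicLayers()].
#' @export
setClass("OmicLayer", contains = "SummarizedExperiment",
         representation(layerKind = "character"))

setValidity("OmicLayer", function(object) {
  k <- object@layerKind
  if (length(k) != 1L || !k %in% omicLayers())
    return(sprintf("layerKind must be one of: %s",
                   paste(omicLayers(), collapse = ", ")))
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("assay 'values' is required")
  if (!"gene" %in% colnames(rowData(object)))
    return("rowData column 'gene' is required")
  v <- assay(object, "values")
  vv <- v[!is.na(v)]
  if (k == "mutation" && !all(vv %in% c(0, 1)))
    return("mutation values must lie in {0,1}")
  if (k == "cnv" && !all(vv %in% -2:2))
    return("CNV values must lie in {-2,-1,0,1,2}")
  if (k == "methylation" && length(vv) && (min(vv) < 0 || max(vv) > 1))
    return("methylation beta values must lie in [0,1]")
  TRUE
})

#' Construct an OmicLayer
#'
#' @param values numeric matrix, features x samples, with rownames and
#'   colnames set.
#' @param layerKind one of [omicLayers()].
#' @param gene parent gene symbol per feature (recycled from rownames when
#'   the features are genes themselves).
#' @return an [OmicLayer-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
#' ol <- OmicLayer(m, "mrna")
#' layerKind(ol)
#' @export
OmicLayer <- function(values, layerKind, gene = rownames(values)) {
  if (!layerKind %in% omicLayers())
    stop("unknown omic layer '", layerKind, "'; must be one of: ",
         paste(omicLayers(), collapse = ", "))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  se <- SummarizedExperiment(
    assays = list(values = values),
    rowData = DataFrame(gene = gene, row.names = rownames(values)))
  new("OmicLayer", se, layerKind = layerKind)
}

#' PanCancerCohort: one cancer type's multi-omic dataset
#'
#' Container for a single cohort: the omic layers (tumor samples), matched
#' non-tumor expression layers where available, the per-sample phenotype
#' table (TMB/MSI/TSM indices plus time/event for the four survival
#' endpoints), the 29 cell-type infiltration score matrix, the RCD gene
#' inventory, and — for synthetic cohorts — the planted-effect truth table.
#'
#' @slot cancerCode TCGA-style 3-4 letter cohort label.
#' @slot layers [S4Vectors::SimpleList] of [OmicLayer-class], named by layer.
#' @slot normals `SimpleList` of `OmicLayer` for expression layers (may be
#'   empty).
#' @slot phenotypes [S4Vectors::DataFrame] with rownames = tumor samples and
#'   columns `TMB`, `MSI`, `TSM` and `<endpoint>_time` / `<endpoint>_event`.
#' @slot infiltration numeric matrix samples x 29 cell types.
#' @slot inventory [RCDInventory-class].
#' @slot truth `data.frame` of planted effects or `NULL`.
#' @export
setClass("PanCancerCohort",
         representation(cancerCode = "character",
                        layers = "SimpleList",
                        normals = "SimpleList",
                        phenotypes = "DataFrame",
                        infiltration = "matrix",
                        inventory = "RCDInventory",
                        truth = "dataframeOrNULL"))

setValidity("PanCancerCohort", function(object) {
  if (!grepl("^[A-Z]{3,4}$", object@cancerCode))
    return("cancerCode must be 3-4 uppercase letters")
  samp <- rownames(object@phenotypes)
  for (nm in names(object@layers)) {
    l <- object@layers[[nm]]
    if (!is(l, "OmicLayer")) return("layers must contain OmicLayer objects")
    if (!identical(colnames(l), samp))
      return(sprintf("samples of layer '%s' do not match the phenotype table",
                     nm))
  }
  if (nrow(object@infiltration) &&
      !identical(rownames(object@infiltration), samp))
    return("infiltration rows do not match the phenotype table")
  need <- c("TMB", "MSI", "TSM",
            paste0(rep(survivalEndpoints(), each = 2),
                   c("_time", "_event")))
  miss <- setdiff(need, colnames(object@phenotypes))
  if (length(miss))
    return(paste("phenotype table lacks columns:",
                 paste(miss, collapse = ", ")))
  TRUE
})

#' SignatureIdentifier: the 11-component signature code
#'
#' Holds the parsed components of a signature identifier
#' `CTAB-GSI.GFC.PFC.SCS.TNC.HRC.SMC.TMC.TIC.RCD`, e.g.
#' `KIRP-107.3.2.N.1.44.44.1.1.2`: cancer-type abbreviation, gene signature
#' identifier, genomic feature code (1 Protein ... 7 Methylation),
#' phenotypic feature code (1 TMB, 2 MSI, 3 TSM), Spearman correlation sign
#' (P/N), tumor-vs-normal code (0-3), hazard-ratio and survival-metric array
#' codes, tumor-microenvironment and immune-infiltrate codes (1-4), and the
#' number of RCD forms (1-25).
#'
#' @seealso [parseIdentifier()], [formatIdentifier()]
#' @export
setClass("SignatureIdentifier",
         representation(ctab = "character", gsi = "integer", gfc = "integer",
                        pfc = "integer", scs = "character", tnc = "integer",
                        hrc = "integer", smc = "integer", tmc = "integer",
                        tic = "integer", rcd = "integer"))

setValidity("SignatureIdentifier", function(object) {
  if (!grepl("^[A-Z]{3,4}$", object@ctab))
    return("ctab must be 3-4 uppercase letters")
  if (object@gsi < 1L || object@gsi > 9999L)
    return("gsi out of range 1-9999")
  if (!object@gfc %in% 1:7) return("gfc out of range 1-7")
  if (!object@pfc %in% 1:3) return("pfc out of range 1-3")
  if (!object@scs %in% c("P", "N")) return("scs must be 'P' or 'N'")
  if (!object@tnc %in% 0:3) return("tnc out of range 0-3")
  if (object@hrc < 0L) return("hrc must be non-negative")
  if (object@smc < 0L) return("smc must be non-negative")
  if (!object@tmc %in% 1:4) return("tmc out of range 1-4")
  if (!object@tic %in% 1:4) return("tic out of range 1-4")
  if (!object@rcd %in% 1:25) return("rcd out of range 1-25")
  TRUE
})
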