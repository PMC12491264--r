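#' Closed vocabularies of the multi-optosis model
#'
#' The model works over fixed vocabularies: 25 regulated-cell-death (RCD)
#' forms, 7 omic layers, 3 tumor-intrinsic phenotypes, 4 survival endpoints
#' and 29 deconvoluted cell types. These helpers expose the vocabularies so
#' that user-supplied tables can be validated against them.
#'
#' @return `rcdForms()` returns the 25 RCD form tokens; `omicLayers()` the
#'   7 layer names in genomic-feature-code (GFC) order; `phenotypeNames()`
#'   the 3 phenotype indices in phenotypic-feature-code (PFC) order;
#'   `survivalEndpoints()` the endpoint labels in identifier digit order;
#'   `cellTypes()` the 29 cell-type names.
#' @examples
#' length(rcdForms())   # 25
#' omicLayers()[3]      # "cnv"
#' @export
rcdForms <- function() {
  c("apoptosis", "necroptosis", "pyroptosis", "ferroptosis", "autophagy",
    "cuproptosis", "mitotic_catastrophe", "parthanatos",
    "immunogenic_cell_death", "autosis", "netosis", "disulfidptosis",
    "alkaliptosis", "lysosome_dependent_cell_death", "entosis", "anoikis",
    "oxeiptosis", "paraptosis", "cellular_senescence", "mitoptosis",
    "erebosis", "efferocytosis", "mitochondrial_permeability_transition",
    "methuosis", "necrosis")
}

#' @rdname rcdForms
#' @export
omicLayers <- function() {
  c("protein", "mutation", "cnv", "mirna", "transcript", "mrna",
    "methylation")
}

#' @rdname rcdForms
#' @export
phenotypeNames <- function() c("TMB", "MSI", "TSM")

#' @rdname rcdForms
#' @export
survivalEndpoints <- function() c("DSS", "DFI", "PFI", "OS")

#' @rdname rcdForms
#' @export
cellTypes <- function() {
  c("B cells naive", "B cells memory", "Plasma cells",
    "B cells class-switched memory", "T cells CD8", "T cells CD4 naive",
    "T cells CD4 memory resting", "T cells CD4 memory activated",
    "T cells CD4 Th1", "T cells CD4 Th2", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta", "NK cells resting",
    "NK cells activated", "Monocytes", "Macrophages M0", "Macrophages M1",
    "Macrophages M2", "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells activated", "Eosinophils", "Neutrophils",
    "Cancer associated fibroblasts", "Common lymphoid progenitor",
    "Endothelial cells", "Granulocyte-monocyte progenitor",
    "Hematopoietic stem cells")
}

# expression-like layers (continuous values, normals possible)
expressionLayers <- function() c("protein", "mirna", "transcript", "mrna")

# layers whose phenotypic contexture is inferred from the companion mRNA of
# the same gene locus (bi-layer annotation)
bilayerLayers <- function() c("protein", "mutation", "cnv", "methylation")

#' Analysis configuration
#'
#' Bundles the thresholds and conventions used throughout the screen:
#' the genome-wide significance level applied to Holm-adjusted correlation
#' p-values, the per-feature level used for Wilcoxon, Cox, log-rank and
#' cell-infiltrate tests, the meta-Z validation threshold (|Z| > 3.09,
#' two-sided p < 0.001), the endpoint order and the dichotomization rule for
#' continuous features in Kaplan-Meier contrasts.
#'
#' @param genomeWideAlpha significance level on Holm-adjusted screen p-values.
#' @param perFeatureAlpha level for individually evaluated associations.
#' @param metaZThreshold absolute meta-Z needed for external validation.
#' @param dichotomization rule for continuous-feature survival groups;
#'   only `"median"` is implemented (ties at the median go to the Low group).
#' @param tieEpsilon tie tolerance on contexture aggregate scores.
#' @return a list with class `"moAnalysisConfig"`.
#' @examples
#' analysisConfig()$genomeWideAlpha
#' @export
analysisConfig <- function(genomeWideAlpha = 5e-8,
                           perFeatureAlpha = 0.05,
                           metaZThreshold = 3.09,
                           dichotomization = "median",
                           tieEpsilon = 1e-9) {
  stopifnot(genomeWideAlpha > 0, genomeWideAlpha < 1,
            perFeatureAlpha > 0, perFeatureAlpha < 1,
            metaZThreshold > 0)
  dichotomization <- match.arg(dichotomization, "median")
  structure(list(genomeWideAlpha = genomeWideAlpha,
                 perFeatureAlpha = perFeatureAlpha,
                 metaZThreshold = metaZThreshold,
                 endpoints = survivalEndpoints(),
                 dichotomization = dichotomization,
                 tieEpsilon = tieEpsilon),
            class = "moAnalysisConfig")
}

# run `code` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards; all generators funnel through this
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# round half away from zero at `digits` decimals (printed-value convention;
# base round() is half-even)
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
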