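#' Run the full signature-discovery pipeline on one cohort
#'
#' Orchestrates the whole analysis for one cancer type: every omic layer
#' is screened against TMB, MSI and TSM by Spearman correlation with Holm
#' control per (layer x phenotype) family; genome-wide-significant
#' features (adjusted p below the configured threshold) are coded for
#' tumor-vs-normal polarity (TNC, rank-sum test with BH adjustment across
#' genes), Cox hazard (HRC) and Kaplan-Meier (SMC) contexture over the
#' four endpoints, and microenvironment/immune contexture (TMC/TIC) from
#' cell-infiltrate correlations; annotations are grouped into mono-omic
#' multi-phenotypic signatures, ranked, and encoded as identifiers.
#'
#' Bi-layer annotation: for protein, mutation, CNV and methylation
#' features the continuous contexture inputs (TNC, HRC, TMC/TIC profile)
#' come from the companion mRNA of the parent gene locus; SMC group
#' construction keeps the native categories for mutation (MT/WT) and CNV
#' (Deleted/Duplicated). A feature whose parent gene has no mRNA row gets
#' no-data codes (TNC 0, TMC/TIC 4, all-A endpoint arrays, flagged).
#'
#' @param cohort a [PanCancerCohort-class].
#' @param config an [analysisConfig()].
#' @param catmap a [cellCategoryMap()].
#' @param rankMap a [defaultRankMap()].
#' @param arrayTable array code table used to encode HRC/SMC integers
#'   (see [loadArrayCodeTable()]).
#' @return list of class `moPipelineResult` with elements `associations`
#'   (all screen records), `annotations` (accepted features),
#'   `signatures` (ranked table with `identifier` column) and `cancer`.
#' @export
runSignaturePipeline <- function(cohort, config = analysisConfig(),
                                 catmap = cellCategoryMap(),
                                 rankMap = defaultRankMap(),
                                 arrayTable = defaultArrayCodeTable()) {
  stopifnot(is(cohort, "PanCancerCohort"))
  ph <- phenotypes(cohort)
  samples <- rownames(ph)
  inv <- inventory(cohort)
  infl <- infiltrationScores(cohort)
  survTabs <- stats::setNames(
    lapply(survivalEndpoints(), endpointSurvival, object = cohort),
    survivalEndpoints())

  mrna <- omicLayer(cohort, "mrna")
  mrnaMat <- assay(mrna, "values")
  mrnaNorm <- omicLayer(cohort, "mrna", normal = TRUE)
  mrnaTNC <- classifyTNCBatch(
    mrnaMat, if (is.null(mrnaNorm)) NULL else assay(mrnaNorm, "values"),
    alpha = config$perFeatureAlpha)

  associations <- list()
  annotations <- list()
  for (ly in names(cohort@layers)) {
    layer <- omicLayer(cohort, ly)
    mat <- assay(layer, "values")
    geneOf <- stats::setNames(rowData(layer)$gene, rownames(layer))
    norm <- omicLayer(cohort, ly, normal = TRUE)
    # native-layer TNC for expression layers that are not bi-layer
    layerTNC <- if (ly %in% bilayerLayers()) NULL else
      classifyTNCBatch(mat,
                       if (is.null(norm)) NULL else assay(norm, "values"),
                       alpha = config$perFeatureAlpha)
    for (phn in phenotypeNames()) {
      scr <- spearmanScreen(layer, stats::setNames(ph[[phn]], samples),
                            phenotype = phn, config = config)
      if (nrow(scr)) {
        scr$cancer <- cancerCode(cohort)
        scr$layer <- ly
        associations[[paste(ly, phn)]] <- scr
      }
      hits <- scr[scr$significant, , drop = FALSE]
      for (i in seq_len(nrow(hits))) {
        feat <- hits$feature[i]
        gene <- geneOf[[feat]]
        if (!gene %in% names(inv)) next   # outside the RCD inventory
        # continuous contexture source: companion mRNA for bi-layer
        # layers, the feature's own values otherwise
        ctxValues <- if (ly %in% bilayerLayers()) {
          if (gene %in% rownames(mrnaMat))
            stats::setNames(mrnaMat[gene, ], samples) else NULL
        } else stats::setNames(mat[feat, ], samples)
        if (is.null(ctxValues)) {
          tnc <- 0L
          hrcL <- rep("A", 4L); smcL <- rep("A", 4L)
          tmc <- 4L; tic <- 4L
        } else {
          tnc <- if (ly %in% bilayerLayers()) mrnaTNC[[gene]]
          else layerTNC[[feat]]
          hrcL <- fitHRC(ctxValues, survTabs, config)$letters
          smcValues <- if (ly %in% c("mutation", "cnv"))
            stats::setNames(mat[feat, ], samples) else ctxValues
          smcL <- fitSMC(smcValues, ly, survTabs, config)$letters
          prof <- cellCorrelationProfile(ctxValues, infl,
                                         alpha = config$perFeatureAlpha)
          tmc <- classifyTMC(prof, tnc, catmap, config)
          tic <- classifyTIC(prof, tnc, catmap, config)
        }
        annotations[[paste(ly, phn, feat)]] <-
          annotateFeature(hits[i, , drop = FALSE],
                          cancer = cancerCode(cohort), layer = ly,
                          gene = gene, tnc = tnc, hrcLetters = hrcL,
                          smcLetters = smcL, tmc = tmc, tic = tic,
                          formSet = inv[[gene]])
      }
    }
  }
  associations <- if (length(associations))
    do.call(rbind, c(associations, make.row.names = FALSE)) else
      data.frame()
  annotations <- if (length(annotations))
    do.call(rbind, c(annotations, make.row.names = FALSE)) else
      data.frame()
  signatures <- groupSignatures(annotations)
  if (nrow(signatures)) {
    signatures <- rankSignatures(signatures, rankMap)
    signatures$identifier <- vapply(seq_len(nrow(signatures)), function(i)
      formatIdentifier(signatureIdentifier(
        ctab = signatures$cancer[i], gsi = signatures$gsi[i],
        gfc = match(signatures$layer[i], omicLayers()),
        pfc = match(signatures$phenotype[i], phenotypeNames()),
        scs = signatures$scs[i], tnc = signatures$tnc[i],
        hrc = encodeEndpointArray(signatures$hrc[i], arrayTable),
        smc = encodeEndpointArray(signatures$smc[i], arrayTable),
        tmc = signatures$tmc[i], tic = signatures$tic[i],
        rcd = signatures$rcd_count[i])), character(1))
  }
  structure(list(cancer = cancerCode(cohort),
                 associations = associations,
                 annotations = annotations,
                 signatures = signatures,
                 arrayTableSource = attr(arrayTable, "source")),
            class = "moPipelineResult")
}

#' @export
print.moPipelineResult <- function(x, ...) {
  cat(sprintf("Signature pipeline result for %s\n", x$cancer))
  cat(sprintf("  %d association records, %d accepted features, %d signatures\n",
              nrow(x$associations), nrow(x$annotations),
              nrow(x$signatures)))
  cat(sprintf("  array code table: %s\n", x$arrayTableSource))
  invisible(x)
}

#' Run the pipeline over several cohorts and summarize
#'
#' @param cohorts list of [PanCancerCohort-class] objects.
#' @param ... passed to [runSignaturePipeline()].
#' @return list with combined `signatures`, `annotations`, and a
#'   `cohortCounts` table (cancer, n_patients, n_signatures, ratio).
#' @export
runPanCancerPipeline <- function(cohorts, ...) {
  results <- lapply(cohorts, runSignaturePipeline, ...)
  signatures <- do.call(rbind, c(lapply(results, `[[`, "signatures"),
                                 make.row.names = FALSE))
  annotations <- do.call(rbind, c(lapply(results, `[[`, "annotations"),
                                  make.row.names = FALSE))
  counts <- do.call(rbind, lapply(seq_along(cohorts), function(i) {
    nPat <- nrow(phenotypes(cohorts[[i]]))
    nSig <- nrow(results[[i]]$signatures)
    data.frame(cancer = cancerCode(cohorts[[i]]), n_patients = nPat,
               n_signatures = nSig,
               ratio = cohortRatio(nSig, nPat))
  }))
  list(signatures = signatures, annotations = annotations,
       cohortCounts = counts, results = results)
}
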