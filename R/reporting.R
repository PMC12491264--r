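#' Signature-to-patient ratio of a cohort
#'
#' @param nSignatures signature count.
#' @param nPatients patient count (> 0).
#' @return the ratio rounded half-up to 2 decimals.
#' @examples
#' cohortRatio(1564, 119)   # 13.14
#' @export
cohortRatio <- function(nSignatures, nPatients) {
  if (nPatients <= 0) stop("nPatients must be positive")
  roundHalfUp(nSignatures / nPatients, 2L)
}

#' Spearman correlation between cohort size and signature yield
#'
#' @param rows data.frame with columns `n_patients` and `n_signatures`
#'   (one row per cancer type; at least 3 rows).
#' @return list with `rho` and `p` (`NA` when either margin is constant).
#' @export
cohortSizeCorrelation <- function(rows) {
  if (nrow(rows) < 3L) stop("need at least 3 cohorts")
  if (stats::var(rows$n_signatures) == 0 || stats::var(rows$n_patients) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  sp <- rowSpearman(matrix(rows$n_signatures, nrow = 1L), rows$n_patients)
  list(rho = sp$rho, p = sp$p)
}

#' Tabulate signatures by omic layer
#'
#' Per omic layer: total signature count, risky (B) and protective (C)
#' HRC counts per endpoint, Kaplan-Meier poorer-prognosis (non-A SMC)
#' counts per endpoint, microenvironment (TMC) and immune (TIC) category
#' counts, with a totals row equal to the column sums.
#'
#' @param signatures signature table from [groupSignatures()].
#' @return data.frame, one row per layer plus a `Total` row.
#' @export
summarizeByOmic <- function(signatures) {
  eps <- survivalEndpoints()
  cols <- c("total",
            paste0("hrc_risky_", eps), paste0("hrc_protective_", eps),
            paste0("smc_poorer_", eps),
            "tmc_anti", "tmc_dual", "tmc_pro",
            "tic_hot", "tic_variable", "tic_cold")
  out <- matrix(0L, nrow = length(omicLayers()), ncol = length(cols),
                dimnames = list(omicLayers(), cols))
  for (i in seq_len(nrow(signatures))) {
    ly <- signatures$layer[i]
    out[ly, "total"] <- out[ly, "total"] + 1L
    hrc <- strsplit(signatures$hrc[i], "")[[1]]
    smc <- strsplit(signatures$smc[i], "")[[1]]
    for (k in seq_along(eps)) {
      if (hrc[k] == "B")
        out[ly, paste0("hrc_risky_", eps[k])] <-
          out[ly, paste0("hrc_risky_", eps[k])] + 1L
      if (hrc[k] == "C")
        out[ly, paste0("hrc_protective_", eps[k])] <-
          out[ly, paste0("hrc_protective_", eps[k])] + 1L
      if (smc[k] != "A")
        out[ly, paste0("smc_poorer_", eps[k])] <-
          out[ly, paste0("smc_poorer_", eps[k])] + 1L
    }
    tmcCol <- c("tmc_anti", "tmc_dual", "tmc_pro", NA)[signatures$tmc[i]]
    if (!is.na(tmcCol)) out[ly, tmcCol] <- out[ly, tmcCol] + 1L
    ticCol <- c("tic_hot", "tic_variable", "tic_cold",
                NA)[signatures$tic[i]]
    if (!is.na(ticCol)) out[ly, ticCol] <- out[ly, ticCol] + 1L
  }
  df <- as.data.frame(out)
  df <- rbind(df, Total = colSums(out))
  df[] <- lapply(df, as.integer)
  cbind(layer = rownames(df), df, row.names = NULL)
}

#' Drug-gene interaction summary
#'
#' Counts curated interactions for a gene list after excluding rows with
#' missing, "unknown" or "undefined" interaction types and deduplicating
#' exact (gene, drug, type) triples. Only interactions of genes in the
#' query list are counted.
#'
#' @param genes query gene list.
#' @param interactions data.frame with columns `gene`, `drug`,
#'   `interaction_type`.
#' @return list with `nGenesWithInteractions`, `nInteractions`, `nByType`
#'   (named vector) and `pctByType` (percent, rounded half-up to one
#'   decimal).
#' @export
drugInteractionSummary <- function(genes, interactions) {
  if (nrow(interactions) == 0L)
    return(list(nGenesWithInteractions = 0L, nInteractions = 0L,
                nByType = integer(), pctByType = numeric()))
  ty <- tolower(trimws(as.character(interactions$interaction_type)))
  keep <- !is.na(interactions$interaction_type) & nzchar(ty) &
    !ty %in% c("unknown", "undefined", "na") &
    interactions$gene %in% genes
  sub <- unique(interactions[keep, c("gene", "drug", "interaction_type")])
  nByType <- sort(table(sub$interaction_type), decreasing = TRUE)
  nByType <- stats::setNames(as.integer(nByType), names(nByType))
  list(nGenesWithInteractions = length(unique(sub$gene)),
       nInteractions = nrow(sub),
       nByType = nByType,
       pctByType = roundHalfUp(100 * nByType / nrow(sub), 1))
}

#' Write cohort tables as TSV
#'
#' Serializes a cohort the way the pipeline consumes external data: one
#' TSV per omic layer (rows = features, first column = feature id),
#' phenotype and survival tables in long format, the inventory as a
#' two-column TSV.
#'
#' @param cohort a [PanCancerCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortTSV <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLayer <- function(l, path) {
    m <- assay(l, "values")
    df <- data.frame(feature = rownames(m), gene = rowData(l)$gene, m,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (nm in names(cohort@layers))
    writeLayer(cohort@layers[[nm]], file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(cohort@normals))
    writeLayer(cohort@normals[[nm]],
               file.path(dir, paste0(nm, "_normal.tsv")))
  ph <- as.data.frame(phenotypes(cohort))
  idx <- data.frame(sample = rownames(ph),
                    variable = rep(c("TMB", "MSI", "TSM"),
                                   each = nrow(ph)))
  idx$value <- c(ph$TMB, ph$MSI, ph$TSM)
  utils::write.table(idx, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sv <- do.call(rbind, lapply(survivalEndpoints(), function(ep) {
    st <- endpointSurvival(cohort, ep)
    cbind(st[, "sample", drop = FALSE], endpoint = ep,
          st[, c("time", "event")])
  }))
  utils::write.table(sv, file.path(dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeInventory(inventory(cohort), file.path(dir, "inventory.tsv"))
  invisible(dir)
}
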