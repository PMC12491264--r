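#' Cell-category map for microenvironment and immune classification
#'
#' Assigns each of the 29 deconvoluted cell types a tumor role
#' (anti_tumoral / pro_tumoral / dual) used by [classifyTMC()], and a TIC
#' marker role used by [classifyTIC()]: hot markers are CD8 T cells,
#' activated NK cells and M1 macrophages; cold markers are M2 macrophages
#' and regulatory T cells; every other cell is `other`. The defaults follow
#' the usual literature roles (cytotoxic CD8/NK/M1 anti-tumoral; M2, Tregs
#' and cancer-associated fibroblasts pro-tumoral; the remainder dual) and
#' ship as an editable TSV, so a different role assignment can be loaded.
#'
#' @param path optional TSV with columns `cell`, `tumor_role`, `tic_role`;
#'   defaults to the packaged map.
#' @return data.frame with columns `cell`, `tumor_role`, `tic_role`.
#' @export
cellCategoryMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cell_categories.tsv",
                        package = "multioptosis", mustWork = TRUE)
  map <- utils::read.delim(path, sep = "\t", colClasses = "character")
  need <- c("cell", "tumor_role", "tic_role")
  if (!all(need %in% colnames(map)))
    stop("cell category map needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(map$cell, cellTypes())
  if (length(bad))
    stop("unknown cell type(s) in category map: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(map$cell))
    stop("duplicate cell types in category map")
  if (!all(map$tumor_role %in% c("anti_tumoral", "pro_tumoral", "dual")))
    stop("tumor_role must be anti_tumoral / pro_tumoral / dual")
  if (!all(map$tic_role %in% c("hot_marker", "cold_marker", "other")))
    stop("tic_role must be hot_marker / cold_marker / other")
  map
}

#' Presence sign of a cell-infiltrate correlation
#'
#' Converts the sign of a feature-vs-cell-type correlation into presence
#' (+1) or absence (-1) of that cell type, conditioned on the feature's
#' tumor-vs-normal polarity: for overexpressed, unchanged or no-data
#' features the correlation sign is read directly, while for underexpressed
#' features it is inverted (a positive correlation with an underexpressed
#' feature means a lower presence, and vice versa).
#'
#' @param rho non-zero correlation coefficient.
#' @param tnc integer TNC code 0-3 (see [classifyTNC()]).
#' @return +1 (presence) or -1 (absence).
#' @examples
#' presenceSign(0.4, 3)   # +1
#' presenceSign(0.4, 2)   # -1
#' @export
presenceSign <- function(rho, tnc) {
  stopifnot(tnc %in% 0:3)
  if (rho == 0) {
    out <- NA_integer_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  s <- sign(rho)
  if (tnc == 2L) -s else s
}

#' Correlate a feature with the cell-infiltration scores
#'
#' Spearman correlation of one expression vector against every column of
#' the infiltration score matrix, with the per-cell significance gate used
#' by the contexture classifiers (p < `alpha`, unadjusted).
#'
#' @param featureValues named numeric vector (names = samples).
#' @param infiltration samples x cell-types numeric matrix.
#' @param alpha per-cell significance level.
#' @return data.frame with columns `cell`, `rho`, `p`, `significant`.
#' @export
cellCorrelationProfile <- function(featureValues, infiltration,
                                   alpha = 0.05) {
  samp <- intersect(names(featureValues), rownames(infiltration))
  if (length(samp) < 3L) stop("fewer than 3 shared samples")
  sp <- rowSpearman(t(infiltration[samp, , drop = FALSE]),
                    featureValues[samp])
  data.frame(cell = colnames(infiltration), rho = sp$rho, p = sp$p,
             significant = sp$p < alpha, row.names = NULL)
}

# sum of |rho| per tumor role over significant, presence-indicating cells
tmcRoleScores <- function(profile, tnc, catmap) {
  roles <- c("anti_tumoral", "pro_tumoral", "dual")
  scores <- stats::setNames(numeric(3), roles)
  sig <- profile[profile$significant & !is.na(profile$rho) &
                   profile$rho != 0, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    cell <- sig$cell[i]
    j <- match(cell, catmap$cell)
    if (is.na(j)) stop("unknown cell type '", cell, "' in profile")
    if (presenceSign(sig$rho[i], tnc) == 1L) {
      role <- catmap$tumor_role[j]
      scores[role] <- scores[role] + abs(sig$rho[i])
    }
  }
  scores
}

#' Tumor-microenvironment contexture (TMC)
#'
#' Classifies a feature/signature from its cell-infiltrate correlation
#' profile: using only significant cells whose presence sign (see
#' [presenceSign()]) indicates presence, the absolute correlations are
#' summed per tumor role; the role with the largest combined magnitude
#' gives the code (1 anti-tumoral, 2 dual, 3 pro-tumoral). No significant
#' presence-indicating cell gives 4 (no significant data); an exact tie
#' involving the top role gives 2 (dual).
#'
#' @param profile data.frame as from [cellCorrelationProfile()].
#' @param tnc integer TNC code of the feature.
#' @param catmap a [cellCategoryMap()].
#' @param config an [analysisConfig()] (supplies the tie tolerance).
#' @return integer code 1-4.
#' @export
classifyTMC <- function(profile, tnc, catmap = cellCategoryMap(),
                        config = analysisConfig()) {
  scores <- tmcRoleScores(profile, tnc, catmap)
  if (all(scores <= 0)) return(4L)
  top <- max(scores)
  winners <- names(scores)[scores >= top - config$tieEpsilon]
  if (length(winners) > 1L) return(2L)
  switch(winners, anti_tumoral = 1L, dual = 2L, pro_tumoral = 3L)
}

#' Tumor-immune contexture (TIC): hot / variable / cold
#'
#' Sums presence-adjusted significant correlations (presence sign times
#' |rho|) over the hot markers (CD8 T, activated NK, M1) and the cold
#' markers (M2, Tregs). A positive hot score exceeding the cold score codes
#' 1 (hot); a positive cold score exceeding the hot score codes 3 (cold);
#' nothing significant, or neither score positive, codes 4; anything else
#' codes 2 (variable). Near-ties (|hot - cold| < tie tolerance) are
#' re-decided with CD8 T and NK weighted twice, reflecting their priority
#' in immune-hotness calling; a persisting tie codes 2.
#'
#' @inheritParams classifyTMC
#' @return integer code 1-4.
#' @export
classifyTIC <- function(profile, tnc, catmap = cellCategoryMap(),
                        config = analysisConfig()) {
  markers <- catmap$cell[catmap$tic_role != "other"]
  miss <- setdiff(markers, profile$cell)
  if (length(miss))
    stop("profile lacks marker cell type(s): ",
         paste(miss, collapse = ", "))
  sub <- profile[profile$cell %in% markers, , drop = FALSE]
  sig <- sub[sub$significant & !is.na(sub$rho) & sub$rho != 0, ,
             drop = FALSE]
  if (nrow(sig) == 0L) return(4L)
  ticScore <- function(weights) {
    hot <- 0; cold <- 0
    for (i in seq_len(nrow(sig))) {
      j <- match(sig$cell[i], catmap$cell)
      w <- weights[[sig$cell[i]]] %||% 1
      adj <- presenceSign(sig$rho[i], tnc) * abs(sig$rho[i]) * w
      if (catmap$tic_role[j] == "hot_marker") hot <- hot + adj
      else cold <- cold + adj
    }
    c(hot = hot, cold = cold)
  }
  s <- ticScore(list())
  if (s[["hot"]] <= 0 && s[["cold"]] <= 0) return(4L)
  if (abs(s[["hot"]] - s[["cold"]]) < config$tieEpsilon) {
    boost <- list("T cells CD8" = 2, "NK cells activated" = 2,
                  "NK cells resting" = 2)
    s <- ticScore(boost)
    if (abs(s[["hot"]] - s[["cold"]]) < config$tieEpsilon) return(2L)
    if (s[["hot"]] <= 0 && s[["cold"]] <= 0) return(4L)
  }
  if (s[["hot"]] > s[["cold"]] && s[["hot"]] > 0) return(1L)
  if (s[["cold"]] > s[["hot"]] && s[["cold"]] > 0) return(3L)
  2L
}
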