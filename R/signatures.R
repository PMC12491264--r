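#' Annotate a genome-wide-significant feature
#'
#' Joins one association record with its contexture codes into a complete
#' feature annotation, the unit that signature grouping consumes. Only
#' features that reached genome-wide significance in the screen are
#' accepted; others are rejected with the reason. Missing contexture is
#' recorded as no-data codes (TNC 0, TMC/TIC 4), never dropped.
#'
#' @param association one-row data.frame from [spearmanScreen()] (columns
#'   `feature`, `phenotype`, `rho`, `p`, `padj`, `scs`, `significant`).
#' @param cancer,layer cohort and omic layer of the feature.
#' @param gene parent gene symbol.
#' @param tnc,tmc,tic integer codes.
#' @param hrcLetters,smcLetters length-4 letter vectors (or 4-char strings)
#'   over the endpoints.
#' @param formSet character vector of RCD forms of the parent gene
#'   (non-empty).
#' @return one-row data.frame annotation.
#' @export
annotateFeature <- function(association, cancer, layer, gene,
                            tnc, hrcLetters, smcLetters, tmc, tic,
                            formSet) {
  if (!isTRUE(association$significant[1]))
    stop("feature '", association$feature[1],
         "' did not reach genome-wide significance (padj = ",
         format(association$padj[1]), ") and cannot enter a signature")
  if (length(formSet) == 0L)
    stop("empty RCD form set for gene '", gene, "'")
  stopifnot(layer %in% omicLayers(), tnc %in% 0:3, tmc %in% 1:4,
            tic %in% 1:4)
  hrc <- paste(hrcLetters, collapse = "")
  smc <- paste(smcLetters, collapse = "")
  stopifnot(nchar(hrc) == 4L, nchar(smc) == 4L)
  data.frame(cancer = cancer, layer = layer,
             feature = association$feature[1], gene = gene,
             phenotype = association$phenotype[1],
             rho = association$rho[1], p = association$p[1],
             padj = association$padj[1], scs = association$scs[1],
             tnc = as.integer(tnc), hrc = hrc, smc = smc,
             tmc = as.integer(tmc), tic = as.integer(tic),
             forms = paste(sort(formSet), collapse = ";"),
             rcd_count = length(formSet),
             row.names = NULL)
}

groupingKey <- function(ann) {
  paste(ann$cancer, ann$layer, ann$phenotype, ann$scs, ann$tnc, ann$hrc,
        ann$smc, ann$tmc, ann$tic, ann$forms, sep = "|")
}

#' Group annotated features into mono-omic multi-phenotypic signatures
#'
#' Partitions feature annotations by exact equality of the full grouping
#' key (cancer, layer, phenotype, correlation sign, TNC, HRC, SMC, TMC,
#' TIC and the gene-level RCD-form set): every annotation lands in exactly
#' one signature, and members of a signature agree on every identifier
#' component. Grouping requires an identical form set across members;
#' genes whose form sets differ are never merged. GSI numbers are assigned
#' deterministically within each cancer by sorting signatures on (layer
#' code, phenotype code, first member id) and numbering from 1, so the
#' result is invariant to input order.
#'
#' @param annotations data.frame of rows from [annotateFeature()].
#' @return data.frame with one row per signature: the shared key
#'   components plus `gsi`, `members`, `member_genes`, `n_members`,
#'   sorted by (cancer, gsi).
#' @export
groupSignatures <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(data.frame())
  key <- groupingKey(annotations)
  parts <- split(seq_len(nrow(annotations)), key)
  sigs <- do.call(rbind, lapply(parts, function(idx) {
    a <- annotations[idx, , drop = FALSE]
    members <- sort(unique(a$feature))
    first <- a[match(members[1], a$feature), , drop = FALSE]
    data.frame(cancer = first$cancer, layer = first$layer,
               phenotype = first$phenotype, scs = first$scs,
               tnc = first$tnc, hrc = first$hrc, smc = first$smc,
               tmc = first$tmc, tic = first$tic, forms = first$forms,
               rcd_count = first$rcd_count,
               members = paste(members, collapse = ";"),
               member_genes = paste(sort(unique(a$gene)), collapse = ";"),
               n_members = length(members),
               row.names = NULL)
  }))
  # deterministic GSI: per cancer, order by layer code, phenotype code,
  # first member id
  gfc <- match(sigs$layer, omicLayers())
  pfc <- match(sigs$phenotype, phenotypeNames())
  firstMember <- vapply(strsplit(sigs$members, ";"), `[`, character(1), 1L)
  ord <- order(sigs$cancer, gfc, pfc, firstMember)
  sigs <- sigs[ord, , drop = FALSE]
  sigs$gsi <- as.integer(stats::ave(seq_len(nrow(sigs)), sigs$cancer,
                                    FUN = seq_along))
  rownames(sigs) <- NULL
  sigs[, c("cancer", "gsi", "layer", "phenotype", "scs", "tnc", "hrc",
           "smc", "tmc", "tic", "forms", "rcd_count", "members",
           "member_genes", "n_members")]
}

#' Per-sample composite score of a signature
#'
#' Sums the member features' values element-wise across samples
#' (member 1 + member 2 + ... + member n), on the raw value scale. A
#' missing member value makes the composite missing for that sample.
#' With `standardize = TRUE` each member is z-scored before summation.
#'
#' @param members character vector of member feature ids.
#' @param values feature-by-sample numeric matrix holding the members
#'   (companion-mRNA values for layers under bi-layer annotation).
#' @param standardize z-score members before summing.
#' @return named numeric per-sample vector.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' colnames(m) <- c("s1", "s2", "s3")
#' compositeScore(c("a", "b"), m)   # 5 7 9
#' @export
compositeScore <- function(members, values, standardize = FALSE) {
  miss <- setdiff(members, rownames(values))
  if (length(miss))
    stop("member(s) absent from the layer: ", paste(miss, collapse = ", "))
  sub <- values[members, , drop = FALSE]
  if (standardize) sub <- t(scale(t(sub)))
  colSums(sub)   # na.rm = FALSE: missing member value -> missing composite
}

#' Re-evaluate survival contexture at the signature level
#'
#' Computes the composite score of a signature and reruns the Cox (HRC)
#' and Kaplan-Meier (SMC) coding on it. The consistency flag records
#' whether the composite endpoint arrays equal the arrays shared by the
#' members; when they disagree the member-level codes remain authoritative
#' for the identifier and the disagreement is reported, not hidden.
#'
#' @param signature one-row data.frame from [groupSignatures()].
#' @param values feature-by-sample matrix holding the members (see
#'   [compositeScore()]).
#' @param survivalTables named list over endpoints of `sample`/`time`/
#'   `event` data.frames.
#' @param config an [analysisConfig()].
#' @return list with `composite` (per-sample vector), `hrc`, `smc`
#'   (letters), and `consistent` (logical).
#' @export
evaluateComposite <- function(signature, values, survivalTables,
                              config = analysisConfig()) {
  members <- strsplit(signature$members[1], ";")[[1]]
  comp <- compositeScore(members, values)
  hrc <- fitHRC(comp, survivalTables, config)
  # a composite is a continuous score, so the continuous grouping applies
  smc <- fitSMC(comp, "mrna", survivalTables, config)
  consistent <- identical(paste(hrc$letters, collapse = ""),
                          signature$hrc[1]) &&
    identical(paste(smc$letters, collapse = ""), signature$smc[1])
  list(composite = comp, hrc = hrc$letters, smc = smc$letters,
       consistent = consistent)
}
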