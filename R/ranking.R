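#' Default clinical-meaningfulness rank map
#'
#' Additive integer contributions per identifier component. The defaults
#' preserve the orderings the contexture codes are meant to express — hot
#' immune infiltrates, anti-tumoral microenvironments, informative
#' tumor-vs-normal polarity and survival effects across all endpoints rank
#' highest — while every value can be overridden: TIC hot = 3 / variable =
#' 2 / cold = 1 / no data = 0; TMC anti-tumoral = 3 / dual = 2 /
#' pro-tumoral = 1 / no data = 0; HRC and SMC contribute 1 per non-A
#' endpoint letter; TNC contributes 1 when informative (codes 2 or 3);
#' each member beyond the first contributes 1, capped at
#' `memberCap`. Under this map a signature at the minimum of every
#' component ranks 0.
#'
#' @param tic,tmc,tnc named integer vectors keyed by code.
#' @param endpointLetterWeight contribution per non-A letter in HRC/SMC.
#' @param memberWeight contribution per member beyond the first.
#' @param memberCap cap on the member contribution.
#' @return a `rankMap` list.
#' @export
defaultRankMap <- function(tic = c("1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L),
                           tmc = c("1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L),
                           tnc = c("0" = 0L, "1" = 0L, "2" = 1L,
                                   "3" = 1L),
                           endpointLetterWeight = 1L,
                           memberWeight = 1L, memberCap = 5L) {
  structure(list(tic = tic, tmc = tmc, tnc = tnc,
                 endpointLetterWeight = endpointLetterWeight,
                 memberWeight = memberWeight, memberCap = memberCap),
            class = "rankMap")
}

nonALetters <- function(letters) {
  sum(strsplit(letters, "")[[1]] != "A")
}

#' Rank a signature's clinical meaningfulness
#'
#' Sums the rank-map contributions of the signature's components plus the
#' capped element-count contribution. Deterministic, additive and monotone
#' in each component's contribution.
#'
#' @param signature one-row data.frame from [groupSignatures()] (needs
#'   columns `tic`, `tmc`, `tnc`, `hrc`, `smc`, `n_members`).
#' @param rankMap a [defaultRankMap()].
#' @return integer rank.
#' @export
rankSignature <- function(signature, rankMap = defaultRankMap()) {
  lookup <- function(map, value) {
    key <- as.character(value)
    if (!key %in% names(map))
      stop("rank map has no entry for component value '", key, "'")
    map[[key]]
  }
  lookup(rankMap$tic, signature$tic[1]) +
    lookup(rankMap$tmc, signature$tmc[1]) +
    lookup(rankMap$tnc, signature$tnc[1]) +
    rankMap$endpointLetterWeight * nonALetters(signature$hrc[1]) +
    rankMap$endpointLetterWeight * nonALetters(signature$smc[1]) +
    rankMap$memberWeight * min(signature$n_members[1] - 1L,
                               rankMap$memberCap)
}

#' @describeIn rankSignature vectorized over a signature table; returns
#'   the table with a `rank` column appended.
#' @param signatures data.frame from [groupSignatures()].
#' @export
rankSignatures <- function(signatures, rankMap = defaultRankMap()) {
  if (nrow(signatures) == 0L) {
    signatures$rank <- integer()
    return(signatures)
  }
  signatures$rank <- vapply(seq_len(nrow(signatures)), function(i)
    as.integer(rankSignature(signatures[i, , drop = FALSE], rankMap)),
    integer(1))
  signatures
}

# tie-break comparison values after rank: member count, then TIC, TMC,
# SMC, HRC rank contributions (higher is better), then identifier string
tieBreakFrame <- function(signatures, rankMap) {
  data.frame(
    rank = signatures$rank,
    n_members = signatures$n_members,
    tic = rankMap$tic[as.character(signatures$tic)],
    tmc = rankMap$tmc[as.character(signatures$tmc)],
    smc = vapply(signatures$smc, nonALetters, numeric(1)),
    hrc = vapply(signatures$hrc, nonALetters, numeric(1)))
}

#' Select representative top signatures
#'
#' Picks, per group, the maximal signature under the lexicographic
#' comparison (rank, member count, TIC, TMC, SMC, HRC) — ties resolved in
#' that order, with a deterministic final fallback on the identifier key
#' string (logged via a `tie_fallback` column). Grouping mode:
#' `per_rcd_form` selects one representative for every RCD form covered by
#' any signature's form set; `per_omic_feature` selects one per omic
#' layer, so every layer with at least one signature is represented even
#' when its best candidate ranks low. Output is ordered by descending
#' rank.
#'
#' @param signatures ranked signature table (see [rankSignatures()]).
#' @param mode `"per_rcd_form"` or `"per_omic_feature"`.
#' @param rankMap the map used for tie-break contributions.
#' @return subset of `signatures` with columns `group` and `tie_fallback`
#'   appended.
#' @export
selectRepresentatives <- function(signatures,
                                  mode = c("per_rcd_form",
                                           "per_omic_feature"),
                                  rankMap = defaultRankMap()) {
  mode <- match.arg(mode)
  if (nrow(signatures) == 0L) return(signatures)
  if (!"rank" %in% colnames(signatures))
    stop("signatures must be ranked first (see rankSignatures)")
  groups <- if (mode == "per_omic_feature") {
    stats::setNames(lapply(unique(signatures$layer), function(ly)
      which(signatures$layer == ly)), unique(signatures$layer))
  } else {
    formsList <- strsplit(signatures$forms, ";")
    allForms <- sort(unique(unlist(formsList)))
    stats::setNames(lapply(allForms, function(f)
      which(vapply(formsList, function(x) f %in% x, logical(1)))),
      allForms)
  }
  tb <- tieBreakFrame(signatures, rankMap)
  keyString <- groupingKey(signatures)
  picked <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    sub <- tb[idx, , drop = FALSE]
    ord <- order(-sub$rank, -sub$n_members, -sub$tic, -sub$tmc,
                 -sub$smc, -sub$hrc, keyString[idx])
    best <- idx[ord[1]]
    # fallback fired iff the runner-up ties on every numeric criterion
    fallback <- length(idx) > 1L &&
      all(sub[ord[1], ] == sub[ord[2], ])
    out <- signatures[best, , drop = FALSE]
    out$group <- g
    out$tie_fallback <- fallback
    out
  })
  out <- do.call(rbind, picked)
  out <- out[order(-out$rank, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signature-level meta-Z score
#'
#' Single-gene signatures take the gene's meta-Z directly; multi-gene
#' signatures take the median over the member genes found in the table.
#' Genes absent from the table are excluded and counted; when every gene
#' is missing the result is missing.
#'
#' @param memberGenes character vector of member gene symbols.
#' @param cancer cancer code to query.
#' @param table meta-Z table (see [generateMetaZTable()]).
#' @return list with `metaZ` (numeric or `NA`), `nUsed`, `nExcluded`.
#' @export
signatureMetaZ <- function(memberGenes, cancer, table) {
  z <- vapply(memberGenes, metaZLookup, numeric(1),
              table = table, cancer = cancer)
  found <- z[!is.na(z)]
  list(metaZ = if (length(found)) stats::median(found) else NA_real_,
       nUsed = length(found),
       nExcluded = length(z) - length(found))
}

#' Expected prognosis direction implied by an HRC array
#'
#' A risky OS letter (B) implies poor expected prognosis and a protective
#' OS letter (C) favorable; with no OS signal the majority of B vs C
#' letters across all endpoints decides, and an unresolved mix returns
#' `NA` (validation is then skipped with a reason).
#'
#' @param hrcLetters 4-character HRC string over DSS, DFI, PFI, OS.
#' @return `"poor"`, `"favorable"` or `NA`.
#' @export
hrcDirection <- function(hrcLetters) {
  l <- strsplit(hrcLetters, "")[[1]]
  os <- l[4]
  if (os == "B") return("poor")
  if (os == "C") return("favorable")
  nB <- sum(l == "B"); nC <- sum(l == "C")
  if (nB > nC) "poor" else if (nC > nB) "favorable" else NA_character_
}

#' Validate a signature against an independent meta-Z score
#'
#' A signature is validated when its meta-Z magnitude exceeds the
#' threshold (default 3.09, two-sided p < 0.001) and the sign matches the
#' expected direction (positive meta-Z = poor prognosis, negative =
#' favorable).
#'
#' @param metaZ signature-level meta-Z (may be `NA`).
#' @param expectedDirection `"poor"` or `"favorable"` (see
#'   [hrcDirection()]).
#' @param config an [analysisConfig()].
#' @return `"validated"`, `"not_validated"`, or `"missing"`.
#' @export
validateSignature <- function(metaZ, expectedDirection,
                              config = analysisConfig()) {
  if (is.na(metaZ)) return("missing")
  if (is.na(expectedDirection)) return("missing")
  expectedDirection <- match.arg(expectedDirection, c("poor", "favorable"))
  ok <- abs(metaZ) > config$metaZThreshold &&
    ((expectedDirection == "poor" && metaZ > 0) ||
       (expectedDirection == "favorable" && metaZ < 0))
  if (ok) "validated" else "not_validated"
}

#' Validate a table of signatures
#'
#' @param signatures ranked signature table (needs `member_genes`,
#'   `cancer`, `hrc`).
#' @param table meta-Z table.
#' @param config an [analysisConfig()].
#' @return the table with `meta_z`, `n_genes_excluded` and `verdict`
#'   columns appended.
#' @export
validateSignatures <- function(signatures, table,
                               config = analysisConfig()) {
  if (nrow(signatures) == 0L) {
    signatures$meta_z <- numeric()
    signatures$n_genes_excluded <- integer()
    signatures$verdict <- character()
    return(signatures)
  }
  res <- lapply(seq_len(nrow(signatures)), function(i) {
    genes <- strsplit(signatures$member_genes[i], ";")[[1]]
    mz <- signatureMetaZ(genes, signatures$cancer[i], table)
    verdict <- validateSignature(mz$metaZ,
                                 hrcDirection(signatures$hrc[i]), config)
    data.frame(meta_z = mz$metaZ, n_genes_excluded = mz$nExcluded,
               verdict = verdict)
  })
  cbind(signatures, do.call(rbind, res))
}
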