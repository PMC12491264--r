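#' Default RCD-form marginal frequencies
#'
#' Target marginal fraction of inventory genes tagged with each form. The
#' apoptosis fraction (0.814) is the dominant, literature-calibrated value;
#' the remaining forms use plausible descending weights, with alkaliptosis,
#' lysosome-dependent cell death and methuosis rarest. Only the apoptosis
#' marginal is controlled exactly by the generator; the other values act as
#' relative sampling weights for the non-apoptosis slots of each gene.
#'
#' @return named numeric vector over [rcdForms()].
#' @export
defaultFormFrequencies <- function() {
  f <- c(apoptosis = 0.814, autophagy = 0.24, necrosis = 0.20,
         ferroptosis = 0.15, pyroptosis = 0.12, necroptosis = 0.10,
         cellular_senescence = 0.09, anoikis = 0.07, cuproptosis = 0.05,
         parthanatos = 0.05, immunogenic_cell_death = 0.05,
         mitotic_catastrophe = 0.04, netosis = 0.04, entosis = 0.035,
         disulfidptosis = 0.03, oxeiptosis = 0.03, paraptosis = 0.03,
         mitoptosis = 0.025, erebosis = 0.02, efferocytosis = 0.02,
         mitochondrial_permeability_transition = 0.02, autosis = 0.02,
         alkaliptosis = 0.008, lysosome_dependent_cell_death = 0.008,
         methuosis = 0.008)
  f[rcdForms()]
}

normalizeFormToken <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]+", "_", x)
}

#' Construct an RCD inventory from a membership list
#'
#' @param membership named list mapping gene to a character vector of form
#'   tokens (case/space tolerant).
#' @return an [RCDInventory-class].
#' @examples
#' inv <- RCDInventory(list(TP53 = c("apoptosis", "ferroptosis")))
#' inv[["TP53"]]
#' @export
RCDInventory <- function(membership = list()) {
  membership <- lapply(membership, function(f) {
    f <- unique(normalizeFormToken(f))
    bad <- setdiff(f, rcdForms())
    if (length(bad))
      stop("unknown RCD form token(s): ", paste(bad, collapse = ", "))
    f
  })
  new("RCDInventory", membership = membership)
}

#' Read / write an inventory as two-column TSV
#'
#' The on-disk format is a header row then one line per gene:
#' `gene<TAB>form1;form2;...`. Duplicate gene rows are merged by union of
#' their form sets.
#'
#' @param path file path.
#' @param inventory an [RCDInventory-class] (for `writeInventory`).
#' @return `loadInventory` returns an [RCDInventory-class];
#'   `writeInventory` returns `path` invisibly.
#' @export
loadInventory <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("inventory TSV needs (gene, forms) columns")
  genes <- df[[1L]]
  forms <- strsplit(df[[2L]], ";", fixed = TRUE)
  if (any(lengths(forms) == 0L) || any(!nzchar(unlist(forms))))
    stop("empty form list for gene(s): ",
         paste(genes[lengths(forms) == 0L | !vapply(
           forms, function(f) all(nzchar(f)), logical(1))], collapse = ", "))
  memb <- tapply(forms, genes, function(fl) unique(unlist(fl)),
                 simplify = FALSE)
  RCDInventory(memb[unique(genes)])
}

#' @rdname loadInventory
#' @export
writeInventory <- function(inventory, path) {
  stopifnot(is(inventory, "RCDInventory"))
  df <- data.frame(
    gene = names(inventory),
    forms = vapply(membership(inventory),
                   function(f) paste(sort(f), collapse = ";"),
                   character(1)),
    row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic RCD gene inventory
#'
#' Draws a gene-to-form membership whose three headline fractions match the
#' calibration of the real inventory in expectation: the apoptosis marginal
#' (`formFrequencies["apoptosis"]`, default 0.814), the fraction of genes
#' tagged with two or more forms (`multiFormFraction`, default
#' 2403/5913 = 0.406) and the fraction tagged with apoptosis only
#' (`apoptosisOnlyFraction`, default 2511/5913 = 0.425). Each gene is first
#' drawn single- or multi-form, apoptosis membership is then drawn with the
#' conditional probability implied by the three targets, and remaining
#' multi-form slots are filled by sampling the other 24 forms proportional
#' to `formFrequencies`.
#'
#' @param nGenes number of genes.
#' @param formFrequencies named vector over [rcdForms()]; see
#'   [defaultFormFrequencies()].
#' @param multiFormFraction fraction of genes with >= 2 forms.
#' @param apoptosisOnlyFraction fraction of genes tagged apoptosis only;
#'   must be <= min(1 - multiFormFraction, apoptosis marginal).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an [RCDInventory-class] with genes named `G0001`, `G0002`, ...
#' @examples
#' inv <- generateRCDInventory(500, seed = 7)
#' mean(vapply(membership(inv), function(f) "apoptosis" %in% f, logical(1)))
#' @export
generateRCDInventory <- function(nGenes,
                                 formFrequencies = defaultFormFrequencies(),
                                 multiFormFraction = 2403 / 5913,
                                 apoptosisOnlyFraction = 2511 / 5913,
                                 seed = 1L) {
  stopifnot(nGenes >= 1L,
            multiFormFraction >= 0, multiFormFraction <= 1,
            all(formFrequencies >= 0), all(formFrequencies <= 1))
  bad <- setdiff(names(formFrequencies), rcdForms())
  if (length(bad))
    stop("unknown RCD form name(s) in formFrequencies: ",
         paste(bad, collapse = ", "))
  fA <- formFrequencies[["apoptosis"]]
  pSingle <- 1 - multiFormFraction
  pMulti <- multiFormFraction
  # conditional apoptosis probabilities implied by the three targets,
  # feasibility-adjusted so the apoptosis marginal fA always dominates
  a0 <- min(apoptosisOnlyFraction, pSingle, fA)
  pApopSingle <- if (pSingle > 0) a0 / pSingle else 0
  pApopMulti <- if (pMulti > 0)
    min(1, max(0, (fA - a0) / pMulti)) else 0
  realized <- pSingle * pApopSingle + pMulti * pApopMulti
  if (realized < fA && pSingle > 0)
    pApopSingle <- min(1, (fA - pMulti * pApopMulti) / pSingle)
  others <- setdiff(rcdForms(), "apoptosis")
  wOther <- formFrequencies[others]
  wOther[is.na(wOther)] <- 0
  if (sum(wOther) <= 0) wOther[] <- 1
  withSeed(seed, {
    isMulti <- stats::runif(nGenes) < multiFormFraction
    hasApop <- stats::runif(nGenes) <
      ifelse(isMulti, pApopMulti, pApopSingle)
    memb <- vector("list", nGenes)
    for (g in seq_len(nGenes)) {
      if (!isMulti[g]) {
        memb[[g]] <- if (hasApop[g]) "apoptosis" else
          sample(others, 1L, prob = wOther)
      } else {
        # total set size 2-6, skewed small
        k <- sample(2:6, 1L, prob = c(0.55, 0.25, 0.10, 0.06, 0.04))
        nOther <- k - as.integer(hasApop[g])
        extra <- sample(others, max(nOther, if (hasApop[g]) 1L else 2L),
                        prob = wOther)
        memb[[g]] <- c(if (hasApop[g]) "apoptosis", extra)
      }
    }
    names(memb) <- sprintf("G%04d", seq_len(nGenes))
    RCDInventory(memb)
  })
}

#' Shared RCD forms of a gene group
#'
#' Form set common to all genes in a prospective signature. An empty
#' intersection is reported explicitly (zero-length vector with attribute
#' `disjoint = TRUE`), never silently dropped.
#'
#' @param genes character vector of gene identifiers.
#' @param inventory an [RCDInventory-class].
#' @return character vector of shared form tokens (possibly empty, flagged).
#' @examples
#' inv <- RCDInventory(list(A = c("apoptosis", "ferroptosis"),
#'                          B = c("apoptosis", "ferroptosis")))
#' sharedForms(c("A", "B"), inv)
#' @export
sharedForms <- function(genes, inventory) {
  stopifnot(is(inventory, "RCDInventory"))
  genes <- unique(genes)
  miss <- setdiff(genes, names(inventory))
  if (length(miss))
    stop("gene(s) not in inventory: ", paste(miss, collapse = ", "))
  sets <- membership(inventory)[genes]
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L)
    attr(shared, "disjoint") <- TRUE
  shared
}

#' Classify signature modularity from its RCD-form set
#'
#' One shared form makes a signature RCD-specific; two or more make it
#' multi-modular.
#'
#' @param formSet character vector of form tokens (non-empty).
#' @return `"rcd_specific"` or `"multi_modular"`.
#' @export
classifyModularity <- function(formSet) {
  if (length(formSet) == 0L)
    stop("cannot classify an empty RCD-form set")
  if (length(formSet) == 1L) "rcd_specific" else "multi_modular"
}

#' Summarize an inventory
#'
#' Per-form gene counts plus headline fractions: genes with >= 2 forms,
#' apoptosis-only genes. Percentages are rounded half-up to one decimal.
#'
#' @param inventory an [RCDInventory-class].
#' @return list with `perForm` (data.frame form, n, pct), `nGenes`,
#'   `multiFormCount`/`multiFormPct`, `apoptosisOnlyCount`/`apoptosisOnlyPct`.
#' @export
inventorySummary <- function(inventory) {
  stopifnot(is(inventory, "RCDInventory"))
  m <- membership(inventory)
  n <- length(m)
  if (n == 0L)
    return(list(perForm = data.frame(form = character(), n = integer(),
                                     pct = numeric()),
                nGenes = 0L, multiFormCount = 0L, multiFormPct = NA_real_,
                apoptosisOnlyCount = 0L, apoptosisOnlyPct = NA_real_))
  counts <- vapply(rcdForms(),
                   function(f) sum(vapply(m, function(s) f %in% s,
                                          logical(1))),
                   integer(1))
  sizes <- lengths(m)
  apopOnly <- sum(sizes == 1L &
                    vapply(m, function(s) identical(s, "apoptosis"),
                           logical(1)))
  list(perForm = data.frame(form = rcdForms(), n = unname(counts),
                            pct = roundHalfUp(100 * counts / n, 1),
                            row.names = NULL),
       nGenes = n,
       multiFormCount = sum(sizes >= 2L),
       multiFormPct = roundHalfUp(100 * mean(sizes >= 2L), 1),
       apoptosisOnlyCount = apopOnly,
       apoptosisOnlyPct = roundHalfUp(100 * apopOnly / n, 1))
}
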