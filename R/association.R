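#' Holm step-down adjustment
#'
#' Adjusts a vector of p-values by the Holm-Bonferroni step-down procedure
#' (monotone non-decreasing in sorted order, capped at 1; output order
#' matches input order). The adjustment is delegated to
#' [stats::p.adjust()]; this wrapper adds the range validation the screen
#' relies on.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holmAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

# rank rows with average ties, then Pearson against a ranked vector;
# vectorized over features. Returns list(rho, p, n) using the large-sample
# t approximation with average-rank tie correction.
rowSpearman <- function(mat, y) {
  n <- length(y)
  ry <- rank(y)
  rmat <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) rmat <- matrix(rmat, nrow = 1L)
  rmat <- rmat - rowMeans(rmat)
  ry <- ry - mean(ry)
  denom <- sqrt(rowSums(rmat^2) * sum(ry^2))
  rho <- as.vector(rmat %*% ry) / denom
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) == 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Genome-scale Spearman screen of one omic layer against one phenotype
#'
#' Computes, for every feature of the layer, the Spearman rank correlation
#' (average-rank ties) with the per-sample phenotype index, a p-value from
#' the large-sample t approximation, and Holm-adjusted p-values over the
#' screen family (one family per cancer x layer x phenotype run, which is
#' what makes the genome-wide threshold meaningful). Zero-variance features
#' are excluded from testing and reported in the `excluded` attribute
#' rather than emitted as rho = 0.
#'
#' @param layer an [OmicLayer-class] or a feature-by-sample numeric matrix.
#' @param phenotypeValues named numeric vector of the phenotype index;
#'   names must cover the layer's samples.
#' @param phenotype label stored in the result (one of [phenotypeNames()]).
#' @param config an [analysisConfig()].
#' @return data.frame with columns `feature`, `phenotype`, `rho`, `p`,
#'   `padj`, `scs` (P/N), `significant`; attribute `excluded` lists
#'   zero-variance features.
#' @export
spearmanScreen <- function(layer, phenotypeValues, phenotype = "TMB",
                           config = analysisConfig()) {
  mat <- if (is(layer, "OmicLayer")) assay(layer, "values") else layer
  if (!is.null(names(phenotypeValues))) {
    if (!all(colnames(mat) %in% names(phenotypeValues)))
      stop("phenotype values do not cover the layer samples")
    phenotypeValues <- phenotypeValues[colnames(mat)]
  } else if (length(phenotypeValues) != ncol(mat)) {
    stop("phenotype length does not match the layer sample count")
  }
  keep <- rowSums(!is.na(mat)) >= 3L
  v <- apply(mat, 1L, function(x) stats::var(x, na.rm = TRUE))
  constant <- !is.na(v) & v == 0
  testable <- keep & !constant
  excluded <- data.frame(
    feature = rownames(mat)[!testable],
    reason = ifelse(constant[!testable], "zero variance", "too few values"))
  if (!any(testable)) {
    warning("no testable features (all constant or too sparse)")
    out <- data.frame(feature = character(), phenotype = character(),
                      rho = numeric(), p = numeric(), padj = numeric(),
                      scs = character(), significant = logical())
    attr(out, "excluded") <- excluded
    return(out)
  }
  sp <- rowSpearman(mat[testable, , drop = FALSE], phenotypeValues)
  padj <- holmAdjust(sp$p)
  out <- data.frame(feature = rownames(mat)[testable],
                    phenotype = phenotype,
                    rho = sp$rho, p = sp$p, padj = padj,
                    scs = ifelse(sp$rho > 0, "P", "N"),
                    significant = padj < config$genomeWideAlpha,
                    row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Tumor-versus-normal expression contexture (TNC)
#'
#' Codes the polarity of a feature's expression in tumor relative to
#' non-tumor tissue: 0 no data (no normals), 1 unchanged (adjusted
#' Wilcoxon p >= 0.05), 2 underexpressed, 3 overexpressed (adjusted p
#' < 0.05 with lower / higher tumor median). An exact median tie with a
#' significant test is coded 1. When `padj` is not supplied the two-sided
#' rank-sum p-value is computed here and used unadjusted (single-feature
#' call); for transcriptome-wide use compute the family of p-values and
#' adjust with [classifyTNCBatch()].
#'
#' @param tumorValues,normalValues numeric vectors; `normalValues` may be
#'   `NULL`.
#' @param padj optional pre-adjusted Wilcoxon p-value.
#' @param alpha significance level (default 0.05).
#' @return integer code 0-3.
#' @export
classifyTNC <- function(tumorValues, normalValues = NULL, padj = NULL,
                        alpha = 0.05) {
  if (length(tumorValues) == 0L) stop("empty tumor group")
  if (is.null(normalValues) || length(normalValues) == 0L) return(0L)
  if (is.null(padj))
    padj <- suppressWarnings(
      stats::wilcox.test(tumorValues, normalValues)$p.value)
  if (is.na(padj) || padj >= alpha) return(1L)
  mt <- stats::median(tumorValues)
  mn <- stats::median(normalValues)
  if (mt > mn) 3L else if (mt < mn) 2L else 1L
}

#' @describeIn classifyTNC transcriptome-wide TNC: computes per-feature
#'   two-sided rank-sum p-values of tumor vs normal, adjusts them across
#'   features by Benjamini-Hochberg within the cancer type, and codes each
#'   feature. Features absent from the normal matrix get code 0.
#' @param tumorMat,normalMat feature-by-sample matrices (matched rownames
#'   where possible); `normalMat` may be `NULL`.
#' @return `classifyTNCBatch`: named integer vector of codes per feature.
#' @export
classifyTNCBatch <- function(tumorMat, normalMat = NULL, alpha = 0.05) {
  codes <- stats::setNames(rep(0L, nrow(tumorMat)), rownames(tumorMat))
  if (is.null(normalMat)) return(codes)
  shared <- intersect(rownames(tumorMat), rownames(normalMat))
  if (!length(shared)) return(codes)
  p <- vapply(shared, function(f) suppressWarnings(
    stats::wilcox.test(tumorMat[f, ], normalMat[f, ])$p.value), numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  for (f in shared)
    codes[[f]] <- classifyTNC(tumorMat[f, ], normalMat[f, ],
                              padj = padj[[f]], alpha = alpha)
  codes
}

#' Hazard-ratio contexture (HRC) of one feature
#'
#' Fits a univariate Cox proportional-hazards model of the feature value
#' against each survival endpoint (no clinical covariates) and codes each
#' endpoint A (no effect), B (risky: p < 0.05, HR > 1) or C (protective:
#' p < 0.05, HR < 1). Endpoints with fewer than 2 events, zero-variance
#' covariates or non-converging fits are coded A with a flag.
#'
#' @param featureValues named numeric vector (names = samples).
#' @param survivalTables named list over [survivalEndpoints()], each a
#'   data.frame with columns `sample`, `time`, `event`.
#' @param config an [analysisConfig()].
#' @return list with `letters` (named character 4-vector over endpoints)
#'   and `fits` (data.frame endpoint, hr, p, n_events, flag).
#' @export
fitHRC <- function(featureValues, survivalTables,
                   config = analysisConfig()) {
  letters <- stats::setNames(rep("A", 4L), config$endpoints)
  fits <- data.frame(endpoint = config$endpoints, hr = NA_real_,
                     p = NA_real_, n_events = NA_integer_,
                     flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(config$endpoints)) {
    ep <- config$endpoints[k]
    st <- survivalTables[[ep]]
    if (is.null(st)) { fits$flag[k] <- "no-survival"; next }
    if (any(st$time <= 0)) stop("non-positive survival times for ", ep)
    x <- featureValues[st$sample]
    ok <- !is.na(x) & !is.na(st$time) & !is.na(st$event)
    nEvents <- sum(st$event[ok])
    fits$n_events[k] <- nEvents
    if (nEvents < 2L) { fits$flag[k] <- "fit-skipped"; next }
    if (stats::sd(x[ok]) == 0) { fits$flag[k] <- "constant"; next }
    fit <- tryCatch(
      survival::coxph(survival::Surv(st$time[ok], st$event[ok]) ~ x[ok]),
      warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition")) {
      fits$flag[k] <- "no-convergence"
      next
    }
    s <- summary(fit)$coefficients
    hr <- s[1, "exp(coef)"]
    p <- s[1, "Pr(>|z|)"]
    fits$hr[k] <- hr
    fits$p[k] <- p
    if (!is.na(p) && p < config$perFeatureAlpha)
      letters[k] <- if (hr > 1) "B" else "C"
  }
  list(letters = letters, fits = fits)
}

# group samples for the Kaplan-Meier contrast of one layer kind;
# returns a factor whose FIRST level is the letter-B group of that layer
smcGroups <- function(values, layerKind) {
  if (layerKind == "mutation") {
    factor(ifelse(values == 1, "MT", "WT"), levels = c("MT", "WT"))
  } else if (layerKind == "cnv") {
    g <- rep(NA_character_, length(values))
    g[values %in% c(-2, -1)] <- "Deleted"
    g[values %in% c(1, 2)] <- "Duplicated"
    factor(g, levels = c("Deleted", "Duplicated"))
  } else {
    # continuous layers: median split, ties to the Low group
    med <- stats::median(values, na.rm = TRUE)
    factor(ifelse(values > med, "High", "Low"), levels = c("High", "Low"))
  }
}

logrankPoorer <- function(group, time, event, alpha) {
  ok <- !is.na(group) & !is.na(time) & !is.na(event)
  if (length(unique(group[ok])) < 2L)
    return(list(call = NA_character_, flag = "group-empty"))
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time[ok], event[ok]) ~ group[ok]),
    error = function(e) NULL)
  if (is.null(sd)) return(list(call = NA_character_, flag = "fit-failed"))
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  if (is.na(p) || p >= alpha)
    return(list(call = "A", flag = ""))
  # poorer survival group: observed deaths exceed expected
  poorer <- names(sd$n)[which.max(sd$obs - sd$exp)]
  poorer <- sub("^group\\[ok\\]=", "", poorer)
  list(call = poorer, flag = "")
}

#' Survival-metric contexture (SMC) of one feature
#'
#' Kaplan-Meier / log-rank coding of which patient group shows poorer
#' survival per endpoint. Groups depend on the layer: continuous layers are
#' split at the median (ties to Low; letters B = High poorer, C = Low
#' poorer); mutation contrasts carriers vs wild type (B = MT poorer,
#' C = WT poorer); CNV first contrasts Deleted (-2/-1) vs Duplicated (1/2)
#' excluding neutral (B = Deleted poorer, C = Duplicated poorer) and, when
#' that contrast is unavailable or not significant, pooled non-neutral vs
#' neutral, coded D when the pooled Deleted/Duplicated group is poorer.
#' A non-significant log-rank test (p >= 0.05) or an empty group codes A.
#'
#' @inheritParams fitHRC
#' @param layerKind one of [omicLayers()].
#' @return list with `letters` (named character 4-vector) and `detail`
#'   (data.frame endpoint, p_group, flag).
#' @export
fitSMC <- function(featureValues, layerKind, survivalTables,
                   config = analysisConfig()) {
  stopifnot(layerKind %in% omicLayers())
  letters <- stats::setNames(rep("A", 4L), config$endpoints)
  detail <- data.frame(endpoint = config$endpoints, group = NA_character_,
                       flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(config$endpoints)) {
    ep <- config$endpoints[k]
    st <- survivalTables[[ep]]
    if (is.null(st)) { detail$flag[k] <- "no-survival"; next }
    x <- featureValues[st$sample]
    grp <- smcGroups(x, layerKind)
    res <- logrankPoorer(grp, st$time, st$event, config$perFeatureAlpha)
    if (layerKind == "cnv" &&
        (res$flag != "" || identical(res$call, "A"))) {
      pooled <- factor(ifelse(x == 0, "Neutral", "DeletedDuplicated"),
                       levels = c("DeletedDuplicated", "Neutral"))
      res2 <- logrankPoorer(pooled, st$time, st$event,
                            config$perFeatureAlpha)
      if (res2$flag == "" && identical(res2$call, "DeletedDuplicated")) {
        letters[k] <- "D"
        detail$group[k] <- "Deleted/Duplicated"
        next
      }
      if (res$flag != "") { detail$flag[k] <- res$flag; next }
    }
    if (res$flag != "") { detail$flag[k] <- res$flag; next }
    if (identical(res$call, "A")) next
    letters[k] <- switch(res$call,
                         High = "B", Low = "C",
                         MT = "B", WT = "C",
                         Deleted = "B", Duplicated = "C",
                         "A")
    detail$group[k] <- res$call
  }
  list(letters = letters, detail = detail)
}
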