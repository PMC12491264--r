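#' Describe a planted effect for the cohort generator
#'
#' A planted effect gives one feature a controlled relationship with the
#' phenotypes: a target Spearman correlation with one tumor-intrinsic index
#' (via a Gaussian copula on the latent scale, so rank correlation is
#' controlled directly), a tumor-versus-normal location shift on the
#' log-expression scale, per-endpoint log hazard ratios acting through the
#' feature's latent value, and signed loadings onto cell-infiltration
#' scores so microenvironment/immune classifiers can be tested against
#' ground truth.
#'
#' @param featureId feature identifier within `layer`.
#' @param layer one of [omicLayers()].
#' @param phenotype one of [phenotypeNames()].
#' @param targetRho target Spearman correlation in \[-1, 1\]. For the binary
#'   mutation and ordinal CNV layers the realized rank correlation is
#'   attenuated by discretization of the latent.
#' @param tumorShift location shift of tumor vs normal expression
#'   (log scale); only meaningful for expression layers.
#' @param logHR numeric length-4 vector of log hazard ratios per endpoint
#'   (DSS, DFI, PFI, OS).
#' @param infiltrationProfile named numeric vector over [cellTypes()];
#'   values +1/-1 give the sign of the planted correlation.
#' @return a `plantedEffect` list.
#' @export
plantedEffect <- function(featureId, layer, phenotype, targetRho = 0,
                          tumorShift = 0, logHR = c(0, 0, 0, 0),
                          infiltrationProfile = numeric()) {
  if (!layer %in% omicLayers())
    stop("unknown omic layer '", layer, "'")
  if (!phenotype %in% phenotypeNames())
    stop("unknown phenotype '", phenotype, "'; must be one of ",
         paste(phenotypeNames(), collapse = ", "))
  stopifnot(abs(targetRho) <= 1, length(logHR) == 4L)
  if (length(infiltrationProfile)) {
    bad <- setdiff(names(infiltrationProfile), cellTypes())
    if (length(bad))
      stop("unknown cell type(s) in infiltrationProfile: ",
           paste(bad, collapse = ", "))
  }
  structure(list(featureId = featureId, layer = layer,
                 phenotype = phenotype, targetRho = targetRho,
                 tumorShift = tumorShift, logHR = logHR,
                 infiltrationProfile = infiltrationProfile),
            class = "plantedEffect")
}

#' Configure a synthetic cohort
#'
#' @param cancerCode 3-4 uppercase letter cohort label.
#' @param nTumor tumor sample count (>= 2 when any survival effect is
#'   planted).
#' @param nNormal matched non-tumor sample count (0 allowed).
#' @param nGenes genes in the inventory / mRNA, mutation, CNV and
#'   methylation layers.
#' @param transcriptsPerGene isoforms per gene in the transcript layer.
#' @param mirnaCount,proteinCount feature counts of those layers.
#' @param plantedEffects list of [plantedEffect()].
#' @param censoringRate target censoring fraction in \[0, 1\] shared by all
#'   endpoints (administrative censoring at a quantile of the event times).
#' @param mutationPrevalence per-gene mutation carrier fraction.
#' @param cnvProbs marginal distribution over CNV states -2..2.
#' @param infiltrationLoading loading strength of planted infiltration
#'   profiles.
#' @param seed integer seed.
#' @return a `cohortConfig` list.
#' @export
cohortConfig <- function(cancerCode, nTumor, nNormal = 0L,
                         nGenes = 200L, transcriptsPerGene = 2L,
                         mirnaCount = 30L, proteinCount = 20L,
                         plantedEffects = list(), censoringRate = 0.3,
                         mutationPrevalence = 0.05,
                         cnvProbs = c(0.02, 0.18, 0.60, 0.18, 0.02),
                         infiltrationLoading = 0.5, seed = 1L) {
  if (!grepl("^[A-Z]{3,4}$", cancerCode))
    stop("cancerCode must be 3-4 uppercase letters")
  stopifnot(nTumor >= 0, nNormal >= 0, nGenes >= 1,
            transcriptsPerGene >= 1, mirnaCount >= 0, proteinCount >= 0,
            censoringRate >= 0, censoringRate <= 1,
            mutationPrevalence > 0, mutationPrevalence < 1,
            length(cnvProbs) == 5L, abs(sum(cnvProbs) - 1) < 1e-8)
  hasSurv <- any(vapply(plantedEffects,
                        function(e) any(e$logHR != 0), logical(1)))
  if (hasSurv && nTumor < 2L)
    stop("nTumor must be >= 2 when a survival effect is planted")
  for (e in plantedEffects)
    if (!inherits(e, "plantedEffect"))
      stop("plantedEffects must be built with plantedEffect()")
  structure(list(cancerCode = cancerCode, nTumor = as.integer(nTumor),
                 nNormal = as.integer(nNormal), nGenes = as.integer(nGenes),
                 transcriptsPerGene = as.integer(transcriptsPerGene),
                 mirnaCount = as.integer(mirnaCount),
                 proteinCount = as.integer(proteinCount),
                 plantedEffects = plantedEffects,
                 censoringRate = censoringRate,
                 mutationPrevalence = mutationPrevalence,
                 cnvProbs = cnvProbs,
                 infiltrationLoading = infiltrationLoading,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Generate exponential survival times with administrative censoring
#'
#' Event times follow an exponential model with hazard
#' `baselineHazard * exp(linearPredictor)`. Censoring is administrative at
#' the `1 - censoringRate` quantile of the drawn event times, which makes
#' the realized censoring fraction reproducible.
#'
#' @param linearPredictor per-sample linear predictor (log hazard scale).
#' @param baselineHazard positive baseline hazard.
#' @param censoringRate target censored fraction in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `time` (positive) and `event` (0/1).
#' @examples
#' s <- generateSurvival(rep(0, 10), 0.1, 0, seed = 1)
#' all(s$event == 1)
#' @export
generateSurvival <- function(linearPredictor, baselineHazard,
                             censoringRate = 0, seed = 1L) {
  if (baselineHazard <= 0) stop("baselineHazard must be positive")
  stopifnot(censoringRate >= 0, censoringRate < 1)
  n <- length(linearPredictor)
  withSeed(seed, {
    u <- stats::runif(n)
    t <- -log(u) / (baselineHazard * exp(linearPredictor))
    event <- rep(1L, n)
    if (censoringRate > 0 && n > 0) {
      cutoff <- stats::quantile(t, 1 - censoringRate, names = FALSE)
      event[t > cutoff] <- 0L
      t[t > cutoff] <- cutoff
    }
    data.frame(time = t, event = event)
  })
}

# Pearson latent correlation giving a target Spearman rho under a Gaussian
# copula with continuous marginals
latentPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

# draw a latent feature matrix (nFeat x n), with rows listed in `planted`
# (index -> list(r, zPheno)) tied to a phenotype latent
latentMatrix <- function(nFeat, n, planted = list()) {
  z <- matrix(stats::rnorm(nFeat * n), nFeat, n)
  for (idx in names(planted)) {
    p <- planted[[idx]]
    i <- as.integer(idx)
    z[i, ] <- p$r * p$zPheno + sqrt(1 - p$r^2) * stats::rnorm(n)
  }
  z
}

#' Generate a synthetic pan-cancer cohort
#'
#' Builds a full [PanCancerCohort-class] for one cancer type: seven omic
#' layers with the correct codomains (continuous log-scale expression;
#' binary mutation; ordinal CNV in -2..2; methylation beta values in
#' \[0, 1\]), continuous TMB/MSI/TSM indices, four survival endpoints with
#' administrative censoring, a 29-cell infiltration score matrix with a
#' shared latent immune axis, matched non-tumor expression layers, an RCD
#' inventory and the planted-effect truth table. All planted structure goes
#' through a Gaussian copula on the latent scale, so rank correlations hit
#' their targets for continuous layers (discrete layers attenuate).
#' Deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @param inventory optional [RCDInventory-class]; generated from the
#'   config seed when omitted.
#' @return a [PanCancerCohort-class].
#' @examples
#' cfg <- cohortConfig("ACC", nTumor = 50, nNormal = 10, nGenes = 40,
#'                     seed = 11)
#' cohort <- generatePanCancerDataset(cfg)
#' cohort
#' @export
generatePanCancerDataset <- function(config, inventory = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  if (is.null(inventory))
    inventory <- generateRCDInventory(config$nGenes,
                                      seed = config$seed + 101L)
  genes <- names(inventory)
  if (length(genes) < config$nGenes)
    stop("inventory has fewer genes than nGenes")
  genes <- genes[seq_len(config$nGenes)]
  nT <- config$nTumor
  nN <- config$nNormal
  tumorSamples <- sprintf("%s-T%03d", config$cancerCode, seq_len(nT))
  normalSamples <- if (nN > 0)
    sprintf("%s-N%03d", config$cancerCode, seq_len(nN)) else character()

  withSeed(config$seed, {
    phenoLatent <- list(TMB = stats::rnorm(nT), MSI = stats::rnorm(nT),
                        TSM = stats::rnorm(nT))

    # feature id table per layer
    featIds <- list(
      mrna = genes,
      mutation = genes,
      cnv = genes,
      methylation = paste0("cg_", genes),
      transcript = as.vector(t(outer(genes, seq_len(config$transcriptsPerGene),
                                     function(g, k) paste0(g, ".T", k)))),
      mirna = if (config$mirnaCount > 0)
        sprintf("hsa-mir-%04d", seq_len(config$mirnaCount)) else character(),
      protein = if (config$proteinCount > 0)
        sprintf("PR_%s", genes[((seq_len(config$proteinCount) - 1L) %%
                                  length(genes)) + 1L]) else character())
    featGenes <- list(
      mrna = genes, mutation = genes, cnv = genes, methylation = genes,
      transcript = rep(genes, each = config$transcriptsPerGene),
      mirna = if (config$mirnaCount > 0)
        genes[((seq_len(config$mirnaCount) - 1L) %% length(genes)) + 1L]
      else character(),
      protein = if (config$proteinCount > 0)
        genes[((seq_len(config$proteinCount) - 1L) %% length(genes)) + 1L]
      else character())

    # index planted effects by layer
    planted <- split(config$plantedEffects,
                     vapply(config$plantedEffects, `[[`, character(1),
                            "layer"))
    for (e in config$plantedEffects) {
      if (!e$featureId %in% featIds[[e$layer]])
        stop("planted feature '", e$featureId,
             "' not present in layer '", e$layer, "'")
    }

    latents <- list()   # tumor latent matrices per layer
    layers <- list()
    normals <- list()
    for (ly in omicLayers()) {
      ids <- featIds[[ly]]
      if (!length(ids)) next
      tie <- list()
      for (e in planted[[ly]] %||% list()) {
        i <- match(e$featureId, ids)
        tie[[as.character(i)]] <-
          list(r = latentPearson(e$targetRho),
               zPheno = phenoLatent[[e$phenotype]])
      }
      z <- latentMatrix(length(ids), nT, tie)
      # tumor shift (log-scale location, applied on the latent)
      for (e in planted[[ly]] %||% list()) {
        if (e$tumorShift != 0)
          z[match(e$featureId, ids), ] <-
            z[match(e$featureId, ids), ] + e$tumorShift
      }
      rownames(z) <- ids
      colnames(z) <- tumorSamples
      latents[[ly]] <- z
      vals <- switch(
        ly,
        mutation = {
          v <- (z > stats::qnorm(1 - config$mutationPrevalence)) + 0
          v
        },
        cnv = {
          br <- stats::qnorm(cumsum(config$cnvProbs)[-5])
          v <- matrix(as.numeric(
            cut(z, breaks = c(-Inf, br, Inf), labels = FALSE)) - 3,
            nrow(z), ncol(z), dimnames = dimnames(z))
          v
        },
        methylation = {
          mf <- stats::runif(nrow(z), 0.1, 0.9)
          stats::pnorm(z + stats::qnorm(mf))
        },
        {
          # expression-like layers: per-feature log-scale baseline
          b <- stats::rnorm(nrow(z), 8, 1.5)
          z + b
        })
      layers[[ly]] <- OmicLayer(vals, ly, gene = featGenes[[ly]])

      if (nN > 0 && ly %in% expressionLayers()) {
        zn <- matrix(stats::rnorm(length(ids) * nN), length(ids), nN,
                     dimnames = list(ids, normalSamples))
        # reuse the tumor baselines so only planted shifts separate groups
        bn <- vals[, 1] - z[, 1]
        normals[[ly]] <- OmicLayer(zn + bn, ly, gene = featGenes[[ly]])
      }
    }

    # infiltration: latent immune axis + noise + planted loadings
    zImm <- stats::rnorm(nT)
    infl <- sapply(cellTypes(), function(ct)
      0.3 * zImm + 0.95 * stats::rnorm(nT))
    rownames(infl) <- tumorSamples
    for (e in config$plantedEffects) {
      if (!length(e$infiltrationProfile)) next
      zf <- latents[[e$layer]][e$featureId, ]
      zf <- (zf - mean(zf)) / stats::sd(zf)
      for (ct in names(e$infiltrationProfile))
        infl[, ct] <- infl[, ct] +
          sign(e$infiltrationProfile[[ct]]) *
          config$infiltrationLoading * zf
    }

    # survival: per-endpoint linear predictor from planted log hazards
    survCols <- list()
    for (k in seq_along(survivalEndpoints())) {
      ep <- survivalEndpoints()[k]
      lp <- rep(0, nT)
      for (e in config$plantedEffects) {
        if (e$logHR[k] == 0) next
        zf <- latents[[e$layer]][e$featureId, ]
        lp <- lp + e$logHR[k] * as.numeric(scale(zf))
      }
      st <- generateSurvival(lp, baselineHazard = 0.1,
                             censoringRate = config$censoringRate,
                             seed = config$seed + 200L + k)
      survCols[[paste0(ep, "_time")]] <- st$time
      survCols[[paste0(ep, "_event")]] <- st$event
    }

    ph <- DataFrame(TMB = phenoLatent$TMB, MSI = phenoLatent$MSI,
                    TSM = phenoLatent$TSM, row.names = tumorSamples)
    for (nm in names(survCols)) ph[[nm]] <- survCols[[nm]]

    truth <- if (length(config$plantedEffects)) {
      do.call(rbind, lapply(config$plantedEffects, function(e)
        data.frame(featureId = e$featureId, layer = e$layer,
                   phenotype = e$phenotype, targetRho = e$targetRho,
                   tumorShift = e$tumorShift,
                   logHR_DSS = e$logHR[1], logHR_DFI = e$logHR[2],
                   logHR_PFI = e$logHR[3], logHR_OS = e$logHR[4],
                   profile = paste(sprintf("%s:%+d",
                                           names(e$infiltrationProfile),
                                           sign(e$infiltrationProfile)),
                                   collapse = ";"),
                   row.names = NULL)))
    } else NULL

    new("PanCancerCohort", cancerCode = config$cancerCode,
        layers = SimpleList(layers), normals = SimpleList(normals),
        phenotypes = ph, infiltration = infl,
        inventory = RCDInventory(membership(inventory)[genes]),
        truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic meta-Z table
#'
#' Unplanted (gene, cancer) entries are standard-normal draws; planted
#' entries are set exactly. Used to exercise the external-validation stage
#' without the real meta-analysis resource.
#'
#' @param inventory an [RCDInventory-class] supplying the gene universe.
#' @param cancerCodes character vector of cancer labels.
#' @param planted named numeric vector, names `"gene|cancer"`, values the
#'   exact meta-Z to plant.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `cancer`, `meta_z`.
#' @seealso [metaZLookup()], [signatureMetaZ()]
#' @export
generateMetaZTable <- function(inventory, cancerCodes,
                               planted = numeric(), seed = 1L) {
  stopifnot(is(inventory, "RCDInventory"))
  genes <- names(inventory)
  tab <- withSeed(seed, {
    data.frame(gene = rep(genes, times = length(cancerCodes)),
               cancer = rep(cancerCodes, each = length(genes)),
               meta_z = stats::rnorm(length(genes) * length(cancerCodes)))
  })
  if (length(planted)) {
    key <- strsplit(names(planted), "|", fixed = TRUE)
    for (i in seq_along(planted)) {
      g <- key[[i]][1]; cc <- key[[i]][2]
      if (!g %in% genes) stop("planted gene '", g, "' not in inventory")
      if (!cc %in% cancerCodes)
        stop("planted cancer '", cc, "' not in cancerCodes")
      tab$meta_z[tab$gene == g & tab$cancer == cc] <- planted[[i]]
    }
  }
  tab
}

#' Look up a meta-Z entry
#'
#' @param table data.frame as produced by [generateMetaZTable()] or read
#'   from a `(gene, cancer, meta_z)` TSV.
#' @param gene,cancer keys.
#' @return the meta-Z value, or `NA` when the entry is missing.
#' @export
metaZLookup <- function(table, gene, cancer) {
  hit <- table$meta_z[table$gene == gene & table$cancer == cancer]
  if (length(hit) == 0L) NA_real_ else hit[[1L]]
}

#' Generate a synthetic drug-gene interaction fixture
#'
#' Builds a drug-gene interaction table with controlled totals: a chosen
#' subset of the query genes receives typed interactions with synthetic
#' drug names, distributed over interaction types per `typeCounts`;
#' `nUntyped` extra rows carry missing/"unknown" types (which the summary
#' must exclude) and a few exact duplicate rows exercise deduplication.
#' The table is entirely synthetic — drug names are placeholders.
#'
#' @param genes query gene list.
#' @param nGenesWithInteractions genes that receive interactions.
#' @param typeCounts named integer vector: interactions per type.
#' @param nUntyped rows with unknown/missing type.
#' @param nDuplicates duplicated rows appended.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `drug`, `interaction_type`.
#' @export
generateDrugInteractionFixture <- function(genes,
                                           nGenesWithInteractions,
                                           typeCounts,
                                           nUntyped = 5L,
                                           nDuplicates = 3L,
                                           seed = 1L) {
  stopifnot(nGenesWithInteractions <= length(genes),
            all(typeCounts >= 0))
  withSeed(seed, {
    hot <- sample(genes, nGenesWithInteractions)
    nInt <- sum(typeCounts)
    g <- c(hot, sample(hot, max(0L, nInt - length(hot)), replace = TRUE))
    g <- sample(g)
    df <- data.frame(
      gene = g[seq_len(nInt)],
      drug = sprintf("drug_%04d", seq_len(nInt)),
      interaction_type = rep(names(typeCounts), times = typeCounts))
    if (nUntyped > 0L)
      df <- rbind(df, data.frame(
        gene = sample(hot, nUntyped, replace = TRUE),
        drug = sprintf("drug_u%03d", seq_len(nUntyped)),
        interaction_type = sample(c("unknown", "undefined", NA),
                                  nUntyped, replace = TRUE)))
    if (nDuplicates > 0L)
      df <- rbind(df, df[sample(seq_len(nInt), nDuplicates), ])
    rownames(df) <- NULL
    df
  })
}
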