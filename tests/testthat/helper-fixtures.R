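# fixtures built in code; all stochastic pieces carry explicit seeds

# tiny inventory with known form sets
tinyInventory <- function() {
  RCDInventory(list(
    A = c("apoptosis", "ferroptosis"),
    B = c("apoptosis", "ferroptosis"),
    C = "apoptosis",
    D = "necrosis",
    E = c("apoptosis", "autophagy", "necrosis")))
}

# small cohort with one strong planted mRNA effect; used across modules
smallCohort <- function(seed = 42, nTumor = 250, nNormal = 25) {
  cfg <- cohortConfig(
    "ACC", nTumor = nTumor, nNormal = nNormal, nGenes = 60,
    transcriptsPerGene = 1L, mirnaCount = 10L, proteinCount = 10L,
    plantedEffects = list(
      plantedEffect("G0005", "mrna", "TSM", targetRho = 0.65,
                    tumorShift = 2,
                    logHR = c(0.8, 0.8, 0.8, 0.8),
                    infiltrationProfile = c("T cells CD8" = 1,
                                            "NK cells activated" = 1,
                                            "Macrophages M1" = 1))),
    censoringRate = 0.3, seed = seed)
  generatePanCancerDataset(cfg)
}

# survival tables keyed by endpoint for hand-built survival data
survListFromDF <- function(df) {
  stats::setNames(
    lapply(survivalEndpoints(), function(ep) df),
    survivalEndpoints())
}

# an annotation row with overridable fields, bypassing the screen
makeAnnotation <- function(feature = "F1", gene = "A", cancer = "ACC",
                           layer = "mrna", phenotype = "TSM", scs = "P",
                           tnc = 3L, hrc = "BBBB", smc = "BBBB",
                           tmc = 1L, tic = 1L,
                           forms = c("apoptosis", "ferroptosis"),
                           rho = 0.7, padj = 1e-10) {
  assoc <- data.frame(feature = feature, phenotype = phenotype, rho = rho,
                      p = padj / 10, padj = padj, scs = scs,
                      significant = TRUE)
  annotateFeature(assoc, cancer = cancer, layer = layer, gene = gene,
                  tnc = tnc, hrcLetters = strsplit(hrc, "")[[1]],
                  smcLetters = strsplit(smc, "")[[1]], tmc = tmc,
                  tic = tic, formSet = forms)
}

# calibrated multi-cohort run: 4 cancers x 2000 genes, a dozen planted
# effects each spread over the seven layers; the mRNA pair G0001/G0002
# shares one form set so grouping can merge features
calibratedCohorts <- function(seed = 2026) {
  codes <- c("BRCA", "LUAD", "KIRP", "CESC")
  lapply(seq_along(codes), function(i) {
    s <- seed + i * 17L
    inv <- generateRCDInventory(2000, seed = s + 1L)
    memb <- membership(inv)
    memb[["G0001"]] <- c("apoptosis", "necrosis")
    memb[["G0002"]] <- c("apoptosis", "necrosis")
    inv <- RCDInventory(memb)
    hotCells <- c("T cells CD8" = 1, "NK cells activated" = 1,
                  "Macrophages M1" = 1)
    effects <- list(
      plantedEffect("G0001", "mrna", "TSM", targetRho = 0.6,
                    tumorShift = 2, logHR = rep(0.7, 4),
                    infiltrationProfile = hotCells),
      plantedEffect("G0002", "mrna", "TSM", targetRho = 0.6,
                    tumorShift = 2, logHR = rep(0.7, 4),
                    infiltrationProfile = hotCells),
      plantedEffect("G0003", "mrna", "TMB", targetRho = -0.55,
                    tumorShift = -1.5),
      plantedEffect("G0004", "mrna", "MSI", targetRho = 0.5,
                    logHR = c(0, 0, 0, -0.6)),
      plantedEffect("G0005.T1", "transcript", "TSM", targetRho = 0.6,
                    tumorShift = 1.5),
      plantedEffect("G0006.T2", "transcript", "MSI", targetRho = -0.6),
      plantedEffect("hsa-mir-0001", "mirna", "TMB", targetRho = 0.55),
      plantedEffect("PR_G0008", "protein", "TSM", targetRho = 0.6),
      plantedEffect("G0009", "mutation", "TMB", targetRho = 0.85),
      plantedEffect("G0010", "cnv", "MSI", targetRho = 0.7),
      plantedEffect("cg_G0011", "methylation", "TSM", targetRho = -0.6))
    cfg <- cohortConfig(codes[i], nTumor = 250, nNormal = 40,
                        nGenes = 2000, transcriptsPerGene = 2L,
                        mirnaCount = 50L, proteinCount = 30L,
                        plantedEffects = effects, censoringRate = 0.3,
                        seed = s)
    generatePanCancerDataset(cfg, inventory = inv)
  })
}

# constructed cell-correlation profile; named rho values, rest zero/ns
makeProfile <- function(rhos, pvals = NULL) {
  cells <- cellTypes()
  rho <- stats::setNames(rep(0, length(cells)), cells)
  rho[names(rhos)] <- rhos
  p <- stats::setNames(rep(1, length(cells)), cells)
  p[names(rhos)] <- if (is.null(pvals)) 1e-4 else pvals
  data.frame(cell = cells, rho = unname(rho), p = unname(p),
             significant = unname(p) < 0.05, row.names = NULL)
}
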