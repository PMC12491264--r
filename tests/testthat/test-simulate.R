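test_that("planted correlations are realized on the continuous layers", {
  cfg <- cohortConfig("ACC", nTumor = 500, nGenes = 50,
                      plantedEffects = list(
                        plantedEffect("G0007", "mrna", "TSM",
                                      targetRho = 0.6)),
                      seed = 1)
  co <- generatePanCancerDataset(cfg)
  m <- SummarizedExperiment::assay(omicLayer(co, "mrna"), "values")
  # independent rank-correlation oracle
  rho <- cor(rank(m["G0007", ]), rank(phenotypes(co)$TSM))
  expect_gt(rho, 0.45)
  expect_lt(rho, 0.75)
})

test_that("null features are calibrated: p < 0.05 at roughly the nominal rate", {
  cfg <- cohortConfig("ACC", nTumor = 100, nGenes = 2000,
                      transcriptsPerGene = 1L, mirnaCount = 0L,
                      proteinCount = 0L, seed = 5)
  co <- generatePanCancerDataset(cfg)
  scr <- spearmanScreen(omicLayer(co, "mrna"),
                        setNames(phenotypes(co)$TMB,
                                 rownames(phenotypes(co))),
                        phenotype = "TMB")
  fpr <- mean(scr$p < 0.05)
  expect_gt(fpr, 0.03)
  expect_lt(fpr, 0.07)
  expect_false(any(abs(scr$rho) > 0.5))
})

test_that("the generator is deterministic given the config seed", {
  cfg <- cohortConfig("BRCA", nTumor = 40, nNormal = 10, nGenes = 30,
                      seed = 9)
  a <- generatePanCancerDataset(cfg)
  b <- generatePanCancerDataset(cfg)
  expect_identical(
    SummarizedExperiment::assay(omicLayer(a, "mrna")),
    SummarizedExperiment::assay(omicLayer(b, "mrna")))
  expect_identical(as.data.frame(phenotypes(a)),
                   as.data.frame(phenotypes(b)))
  expect_identical(infiltrationScores(a), infiltrationScores(b))
})

test_that("layer codomains hold for every generated matrix", {
  co <- smallCohort(seed = 8, nTumor = 60, nNormal = 0)
  mut <- SummarizedExperiment::assay(omicLayer(co, "mutation"))
  expect_true(all(mut %in% c(0, 1)))
  cnv <- SummarizedExperiment::assay(omicLayer(co, "cnv"))
  expect_true(all(cnv %in% -2:2))
  met <- SummarizedExperiment::assay(omicLayer(co, "methylation"))
  expect_true(all(met >= 0 & met <= 1))
})

test_that("generated survival respects censoring and recovers planted effects", {
  s0 <- generateSurvival(rep(0, 50), 0.1, censoringRate = 0, seed = 1)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time > 0))

  s <- generateSurvival(rnorm(400), 0.1, censoringRate = 0.4, seed = 2)
  expect_lt(abs(mean(s$event == 0) - 0.4), 0.1)

  x <- withr::with_seed(3, rnorm(500))
  st <- generateSurvival(0.7 * x, 0.1, censoringRate = 0, seed = 3)
  fit <- survival::coxph(survival::Surv(st$time, st$event) ~ x)
  expect_lt(abs(unname(coef(fit)) - 0.7), 0.2)

  expect_identical(generateSurvival(0.7 * x, 0.1, 0.2, seed = 4),
                   generateSurvival(0.7 * x, 0.1, 0.2, seed = 4))
  expect_error(generateSurvival(x, 0, 0, seed = 1), "positive")
})

test_that("meta-Z fixtures plant exact entries over a standard-normal null", {
  inv <- generateRCDInventory(1000, seed = 6)
  tab <- generateMetaZTable(inv, c("ACC", "BLCA"),
                            planted = c("G0001|ACC" = 4.0), seed = 5)
  expect_identical(metaZLookup(tab, "G0001", "ACC"), 4.0)
  expect_true(is.na(metaZLookup(tab, "nope", "ACC")))
  nullZ <- tab$meta_z[!(tab$gene == "G0001" & tab$cancer == "ACC")]
  tail <- mean(abs(nullZ) > 3.09)
  expect_lt(tail, 0.004)   # two-sided normal tail at 3.09 is ~0.2%
  expect_error(
    generateMetaZTable(inv, "ACC", planted = c("zz|ACC" = 1), seed = 1),
    "zz")
})

test_that("planted effects at rho 0.6, n = 300 clear the genome-wide screen", {
  hits <- vapply(1:20, function(s) {
    cfg <- cohortConfig("ACC", nTumor = 300, nGenes = 500,
                        transcriptsPerGene = 1L, mirnaCount = 0L,
                        proteinCount = 0L,
                        plantedEffects = list(
                          plantedEffect("G0001", "mrna", "MSI",
                                        targetRho = 0.6)),
                        seed = 1000 + s)
    co <- generatePanCancerDataset(cfg)
    scr <- spearmanScreen(omicLayer(co, "mrna"),
                          setNames(phenotypes(co)$MSI,
                                   rownames(phenotypes(co))),
                          phenotype = "MSI")
    scr$significant[scr$feature == "G0001"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cohort TSV export writes every table", {
  co <- smallCohort(seed = 4, nTumor = 30, nNormal = 5)
  dir <- withr::local_tempdir()
  writeCohortTSV(co, dir)
  expect_true(file.exists(file.path(dir, "mrna.tsv")))
  expect_true(file.exists(file.path(dir, "mrna_normal.tsv")))
  expect_true(file.exists(file.path(dir, "phenotypes.tsv")))
  expect_true(file.exists(file.path(dir, "survival.tsv")))
  inv <- loadInventory(file.path(dir, "inventory.tsv"))
  expect_identical(sort(names(inv)), sort(names(inventory(co))))
})
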