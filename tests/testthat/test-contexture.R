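test_that("presence sign inverts for underexpressed features only", {
  expect_identical(presenceSign(0.4, 3), 1)
  expect_identical(presenceSign(0.4, 2), -1)
  expect_identical(presenceSign(-0.4, 2), 1)
  expect_identical(presenceSign(-0.4, 3), -1)
  expect_identical(presenceSign(0.4, 1), 1)
  expect_identical(presenceSign(0.4, 0), 1)
  undef <- presenceSign(0, 3)
  expect_true(is.na(undef))
  expect_true(attr(undef, "undefined"))
})

test_that("presence sign is odd in rho and invariant under joint flips", {
  for (tnc in 0:3) {
    for (rho in c(-0.8, -0.1, 0.1, 0.8)) {
      expect_identical(presenceSign(-rho, tnc), -presenceSign(rho, tnc))
    }
  }
  # negating rho while flipping tnc 2 <-> 3 preserves the presence sign
  for (tnc in 2:3) {
    flipped <- c(`2` = 3L, `3` = 2L)[[as.character(tnc)]]
    for (rho in c(-0.8, -0.1, 0.1, 0.8))
      expect_identical(presenceSign(-rho, flipped), presenceSign(rho, tnc))
  }
})

test_that("TMC classifies constructed profiles by combined magnitude", {
  catmap <- cellCategoryMap()
  anti <- catmap$cell[catmap$tumor_role == "anti_tumoral"]
  pro <- catmap$cell[catmap$tumor_role == "pro_tumoral"]

  onlyAnti <- makeProfile(setNames(rep(0.5, length(anti)), anti))
  expect_identical(classifyTMC(onlyAnti, tnc = 3, catmap), 1L)

  onlyPro <- makeProfile(setNames(rep(0.5, length(pro)), pro))
  expect_identical(classifyTMC(onlyPro, tnc = 3, catmap), 3L)

  # underexpressed feature: negative rho on anti cells means presence
  negAnti <- makeProfile(setNames(rep(-0.5, length(anti)), anti))
  expect_identical(classifyTMC(negAnti, tnc = 2, catmap), 1L)

  nothing <- makeProfile(c())
  expect_identical(classifyTMC(nothing, tnc = 3, catmap), 4L)

  # exact anti/pro tie -> dual
  tie <- makeProfile(setNames(c(0.6, 0.6),
                              c(anti[1], pro[1])))
  expect_identical(classifyTMC(tie, tnc = 3, catmap), 2L)
})

test_that("TMC is invariant to cell order and common rescaling of |rho|", {
  catmap <- cellCategoryMap()
  prof <- makeProfile(c("T cells CD8" = 0.6, "NK cells resting" = 0.3,
                        "Macrophages M2" = 0.4))
  base <- classifyTMC(prof, tnc = 3, catmap)
  shuffled <- prof[withr::with_seed(5, sample(nrow(prof))), ]
  expect_identical(classifyTMC(shuffled, tnc = 3, catmap), base)
  scaled <- prof
  scaled$rho <- scaled$rho * 0.5
  expect_identical(classifyTMC(scaled, tnc = 3, catmap), base)
})

test_that("TIC separates hot, cold, variable and no-data profiles", {
  catmap <- cellCategoryMap()
  hot <- makeProfile(c("T cells CD8" = 0.5, "NK cells activated" = 0.5,
                       "Macrophages M1" = 0.4))
  expect_identical(classifyTIC(hot, tnc = 3, catmap), 1L)

  cold <- makeProfile(c("T cells CD8" = -0.4,
                        "NK cells activated" = -0.4,
                        "Macrophages M2" = 0.5,
                        "T cells regulatory (Tregs)" = 0.5))
  expect_identical(classifyTIC(cold, tnc = 3, catmap), 3L)

  nothing <- makeProfile(c())
  expect_identical(classifyTIC(nothing, tnc = 3, catmap), 4L)

  # joint negation of rho with tnc flip 3 -> 2 preserves the call
  hotFlipped <- hot
  hotFlipped$rho <- -hotFlipped$rho
  expect_identical(classifyTIC(hotFlipped, tnc = 2, catmap), 1L)

  # near-tie resolved by the CD8/NK double weighting
  tie <- makeProfile(c("T cells CD8" = 0.5, "Macrophages M2" = 0.5))
  expect_identical(classifyTIC(tie, tnc = 3, catmap), 1L)
})

test_that("cell correlation profiles carry the significance gate", {
  co <- smallCohort(seed = 17, nTumor = 200, nNormal = 0)
  m <- SummarizedExperiment::assay(omicLayer(co, "mrna"))
  prof <- cellCorrelationProfile(
    setNames(m["G0005", ], colnames(m)), infiltrationScores(co))
  expect_setequal(prof$cell, cellTypes())
  planted <- prof[prof$cell %in% c("T cells CD8", "NK cells activated",
                                   "Macrophages M1"), ]
  expect_true(all(planted$significant))
  expect_true(all(planted$rho > 0))
})
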