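test_that("annotation gates on genome-wide significance and keeps no-data codes", {
  ann <- makeAnnotation()
  expect_identical(ncol(ann), 16L)
  expect_identical(ann$rcd_count, 2L)

  noNormals <- makeAnnotation(tnc = 0L)
  expect_identical(noNormals$tnc, 0L)

  assoc <- data.frame(feature = "F9", phenotype = "TMB", rho = 0.3,
                      p = 1e-7, padj = 1e-6, scs = "P",
                      significant = FALSE)
  expect_error(
    annotateFeature(assoc, "ACC", "mrna", "A", 1L, rep("A", 4),
                    rep("A", 4), 4L, 4L, "apoptosis"),
    "genome-wide")
})

test_that("grouping partitions annotations by exact key equality", {
  a1 <- makeAnnotation(feature = "F1", gene = "A")
  a2 <- makeAnnotation(feature = "F2", gene = "B")
  one <- groupSignatures(rbind(a1, a2))
  expect_identical(nrow(one), 1L)
  expect_identical(one$members, "F1;F2")
  expect_identical(one$n_members, 2L)

  a3 <- makeAnnotation(feature = "F3", gene = "C", scs = "N", rho = -0.7,
                       forms = c("apoptosis", "ferroptosis"))
  two <- groupSignatures(rbind(a1, a3))
  expect_identical(nrow(two), 2L)

  expect_identical(nrow(groupSignatures(data.frame())), 0L)
})

test_that("differing RCD form sets are never merged", {
  a1 <- makeAnnotation(feature = "F1", gene = "A",
                       forms = c("apoptosis", "ferroptosis"))
  a2 <- makeAnnotation(feature = "F2", gene = "D", forms = "necrosis")
  out <- groupSignatures(rbind(a1, a2))
  expect_identical(nrow(out), 2L)
})

test_that("grouping and GSI assignment are invariant to input order", {
  rows <- rbind(
    makeAnnotation(feature = "F1", gene = "A"),
    makeAnnotation(feature = "F2", gene = "B"),
    makeAnnotation(feature = "F3", gene = "C", layer = "transcript"),
    makeAnnotation(feature = "F4", gene = "D", phenotype = "TMB"))
  base <- groupSignatures(rows)
  shuffled <- groupSignatures(rows[c(3, 1, 4, 2), ])
  expect_identical(base, shuffled)
  # partition property: member counts sum to accepted annotations
  expect_identical(sum(base$n_members), nrow(rows))
  expect_identical(base$gsi, seq_len(nrow(base)))
})

test_that("composite scores sum members and propagate missingness", {
  m <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(unname(compositeScore("a", m)), c(1, 2, 3))
  expect_equal(unname(compositeScore(c("a", "b"), m)), c(5, 7, 9))
  m2 <- m; m2["b", 2] <- NA
  comp <- compositeScore(c("a", "b"), m2)
  expect_true(is.na(comp[["s2"]]))
  expect_false(anyNA(comp[c("s1", "s3")]))
  expect_error(compositeScore(c("a", "zz"), m), "zz")
})

test_that("composite re-evaluation confirms shared member contexture", {
  n <- 400
  ids <- paste0("s", 1:n)
  withr::with_seed(41, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    st <- generateSurvival(0.5 * scale(x1)[, 1] + 0.5 * scale(x2)[, 1],
                           0.1, 0, seed = 42)
  })
  tabs <- survListFromDF(data.frame(sample = ids, time = st$time,
                                    event = st$event))
  m <- rbind(F1 = x1, F2 = x2)
  colnames(m) <- ids
  sig <- groupSignatures(rbind(
    makeAnnotation(feature = "F1", gene = "A"),
    makeAnnotation(feature = "F2", gene = "B")))
  out <- evaluateComposite(sig, m, tabs)
  expect_identical(unname(out$hrc), rep("B", 4))
  expect_true(out$consistent)

  # single member: composite must equal the member's own arrays
  soloAnn <- makeAnnotation(feature = "F1", gene = "A")
  soloAnn$hrc <- paste(fitHRC(setNames(x1, ids), tabs)$letters,
                       collapse = "")
  soloAnn$smc <- paste(fitSMC(setNames(x1, ids), "mrna", tabs)$letters,
                       collapse = "")
  solo <- groupSignatures(soloAnn)
  outSolo <- evaluateComposite(solo, m, tabs)
  expect_true(outSolo$consistent)
})

test_that("the pipeline recovers a planted signature end to end", {
  co <- smallCohort(seed = 42)
  res <- runSignaturePipeline(co)
  sig <- res$signatures
  expect_gte(nrow(sig), 1L)
  hit <- sig[sig$members == "G0005", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$layer, "mrna")
  expect_identical(hit$phenotype, "TSM")
  expect_identical(hit$scs, "P")
  expect_identical(hit$tnc, 3L)        # shifted +2 vs normals
  expect_identical(hit$hrc, "BBBB")    # risky on all endpoints
  expect_identical(hit$tmc, 1L)        # anti-tumoral loadings
  expect_identical(hit$tic, 1L)        # hot markers planted
  expect_match(hit$identifier, "^ACC-\\d+\\.6\\.3\\.P\\.3\\.")
  # homogeneity: every signature internally consistent by construction
  expect_identical(sum(sig$n_members), nrow(res$annotations))
})
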