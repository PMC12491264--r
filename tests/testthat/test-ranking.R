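baseSig <- function(...) {
  sig <- groupSignatures(makeAnnotation(...))
  sig
}

test_that("the default rank map is additive with a zero floor", {
  floor <- baseSig(tnc = 0L, hrc = "AAAA", smc = "AAAA", tmc = 4L,
                   tic = 4L)
  expect_identical(rankSignature(floor), 0L)

  hot <- baseSig(tic = 1L)
  cold <- baseSig(tic = 3L)
  expect_gt(rankSignature(hot), rankSignature(cold))
  # additivity: the difference is exactly the TIC contribution gap
  expect_identical(rankSignature(hot) - rankSignature(cold), 3L - 1L)

  full <- baseSig(tnc = 3L, hrc = "BBBB", smc = "BBBB", tmc = 1L,
                  tic = 1L)
  expect_identical(rankSignature(full), 1L + 4L + 4L + 3L + 3L)
})

test_that("member contributions cap and rank errors on unmapped values", {
  many <- groupSignatures(do.call(rbind, lapply(1:10, function(i)
    makeAnnotation(feature = paste0("F", i), gene = "A"))))
  expect_identical(many$n_members, 10L)
  capped <- rankSignature(many)
  lessMembers <- groupSignatures(do.call(rbind, lapply(1:7, function(i)
    makeAnnotation(feature = paste0("F", i), gene = "A"))))
  expect_identical(capped, rankSignature(lessMembers))  # both at the cap

  map <- defaultRankMap()
  map$tic <- map$tic[c("1", "2")]
  expect_error(rankSignature(baseSig(tic = 3L), map), "no entry")
})

test_that("representative selection applies the tie-break chain", {
  s1 <- do.call(rbind, lapply(1:3, function(i)
    makeAnnotation(feature = paste0("F", i), gene = "A")))
  s2 <- makeAnnotation(feature = "G1", gene = "B", phenotype = "TMB")
  sigs <- rankSignatures(groupSignatures(rbind(s1, s2)))
  expect_identical(nrow(sigs), 2L)
  picked <- selectRepresentatives(sigs, mode = "per_rcd_form")
  # one representative per form; the 3-member signature wins both forms
  expect_true(all(picked$n_members == 3L))

  # equal rank, member counts 3 vs 1: the 3-member signature is selected
  tie <- sigs
  tie$rank <- max(sigs$rank)
  pick2 <- selectRepresentatives(tie, mode = "per_rcd_form")
  expect_true(all(pick2$n_members == 3L))
})

test_that("per-omic-feature selection represents every layer present", {
  rows <- rbind(
    makeAnnotation(feature = "F1", gene = "A", layer = "mrna",
                   tic = 1L),
    makeAnnotation(feature = "P1", gene = "B", layer = "protein",
                   tnc = 0L, hrc = "AAAA", smc = "AAAA", tmc = 4L,
                   tic = 4L))
  sigs <- rankSignatures(groupSignatures(rows))
  picked <- selectRepresentatives(sigs, mode = "per_omic_feature")
  # the protein signature ranks at the floor yet is still selected
  expect_setequal(picked$layer, c("mrna", "protein"))
  expect_identical(picked$layer[1], "mrna")  # descending rank order
})

test_that("selection is stable under shuffling and falls back deterministically", {
  rows <- do.call(rbind, lapply(1:4, function(i)
    makeAnnotation(feature = paste0("F", i), gene = "A",
                   phenotype = c("TMB", "MSI")[(i %% 2) + 1])))
  sigs <- rankSignatures(groupSignatures(rows))
  a <- selectRepresentatives(sigs, mode = "per_rcd_form")
  b <- selectRepresentatives(sigs[withr::with_seed(1, sample(nrow(sigs))), ],
                             mode = "per_rcd_form")
  expect_identical(a$members, b$members)
  # two signatures identical on every criterion: fallback must be logged
  expect_true(all(a$tie_fallback))
})

test_that("signature meta-Z takes medians and counts exclusions", {
  tab <- data.frame(gene = c("g1", "g2", "g3"), cancer = "ACC",
                    meta_z = c(2.0, 4.5, 3.5))
  one <- signatureMetaZ("g2", "ACC", tab)
  expect_identical(one$metaZ, 4.5)
  med <- signatureMetaZ(c("g1", "g2", "g3"), "ACC", tab)
  expect_identical(med$metaZ, 3.5)
  part <- signatureMetaZ(c("g1", "zz"), "ACC", tab)
  expect_identical(part$nExcluded, 1L)
  none <- signatureMetaZ(c("aa", "bb"), "ACC", tab)
  expect_true(is.na(none$metaZ))
  expect_identical(none$nExcluded, 2L)
})

test_that("meta-Z validation needs magnitude and matching direction", {
  expect_identical(validateSignature(4.2, "poor"), "validated")
  expect_identical(validateSignature(2.5, "poor"), "not_validated")
  expect_identical(validateSignature(-4.0, "poor"), "not_validated")
  expect_identical(validateSignature(-4.0, "favorable"), "validated")
  expect_identical(validateSignature(NA_real_, "poor"), "missing")
  # antisymmetry: negating the score and flipping direction preserves it
  for (z in c(-5, -2, 2, 5)) {
    expect_identical(validateSignature(z, "poor"),
                     validateSignature(-z, "favorable"))
  }
})

test_that("HRC arrays map to expected prognosis directions", {
  expect_identical(hrcDirection("AAAB"), "poor")
  expect_identical(hrcDirection("BBBC"), "favorable")  # OS protective wins
  expect_identical(hrcDirection("BBAA"), "poor")       # majority B
  expect_identical(hrcDirection("BCAA"), NA_character_)
  expect_identical(hrcDirection("AAAA"), NA_character_)
})

test_that("validated planted signatures separate from a null meta-Z table", {
  sigs <- rankSignatures(groupSignatures(rbind(
    makeAnnotation(feature = "F1", gene = "A", hrc = "BBBB"),
    makeAnnotation(feature = "F2", gene = "D", forms = "necrosis",
                   hrc = "BBBB"))))
  tab <- data.frame(gene = c("A", "D"), cancer = "ACC",
                    meta_z = c(5.0, 0.3))
  out <- validateSignatures(sigs, tab)
  expect_identical(out$verdict[out$member_genes == "A"], "validated")
  expect_identical(out$verdict[out$member_genes == "D"], "not_validated")
})
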