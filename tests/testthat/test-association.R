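test_that("Holm adjustment matches the hand-computed step-down", {
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(0.2), 0.2)
  expect_equal(holmAdjust(c(1, 1)), c(1, 1))
  expect_error(holmAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.5, 0.01, 0.2)
  expect_true(all(holmAdjust(p) >= p))
})

test_that("the Spearman screen reproduces hand values and handles degeneracy", {
  y <- c(2, 1, 4, 3, 5)
  m <- rbind(F1 = 1:5,                # perfect monotone
             F2 = c(2, 1, 4, 3, 5),   # identical to phenotype
             K = rep(7, 5))           # constant, must be excluded
  colnames(m) <- paste0("s", 1:5)
  scr <- spearmanScreen(m, setNames(y, colnames(m)))
  expect_setequal(scr$feature, c("F1", "F2"))
  expect_equal(scr$rho[scr$feature == "F1"], 0.8)  # 1 - 6*4/(5*24)
  expect_equal(scr$rho[scr$feature == "F2"], 1)
  expect_equal(scr$p[scr$feature == "F2"], 0)
  excl <- attr(scr, "excluded")
  expect_identical(excl$feature, "K")
  expect_match(excl$reason, "zero variance")
  expect_identical(scr$scs, c("P", "P"))
})

test_that("perfect monotone features are genome-wide significant at n >= 8", {
  n <- 8
  m <- matrix(1:n, 1, dimnames = list("F", paste0("s", 1:n)))
  scr <- spearmanScreen(m, setNames(as.numeric(1:n), colnames(m)))
  expect_true(scr$significant)
})

test_that("screen errors on misaligned samples and all-constant input", {
  m <- matrix(1:6, 2, 3,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_error(spearmanScreen(m, c(x1 = 1, x2 = 2, x3 = 3)), "cover")
  k <- matrix(1, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_warning(out <- spearmanScreen(k, setNames(1:5, colnames(k))),
                 "no testable")
  expect_identical(nrow(out), 0L)
})

test_that("TNC coding follows polarity, significance and no-data rules", {
  expect_identical(classifyTNC(1:10, NULL), 0L)
  x <- withr::with_seed(1, rnorm(30))
  expect_identical(classifyTNC(x, x), 1L)
  normal <- withr::with_seed(2, rnorm(20))
  expect_identical(classifyTNC(normal + 3, normal), 3L)
  expect_identical(classifyTNC(normal - 3, normal), 2L)
  # significant p but identical medians -> unchanged
  expect_identical(classifyTNC(c(1, 1, 2, 5, 5), c(1, 2, 2, 2, 5),
                               padj = 0.01), 1L)
  expect_error(classifyTNC(numeric(), 1:3), "empty")
})

test_that("rank-sum p-values agree with exact enumeration at small n", {
  # brute-force oracle: exact two-sided rank-sum p over all assignments
  exactP <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    r <- rank(c(x, y))
    wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    all <- utils::combn(n, n1)
    ws <- apply(all, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(ws <= wObs), mean(ws >= wObs)))
  }
  withr::with_seed(7, {
    for (rep in 1:3) {
      x <- rnorm(6); y <- rnorm(5) + rep - 2
      pw <- wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(pw, exactP(x, y), tolerance = 1e-12)
    }
  })
})

test_that("TNC is antisymmetric under swapping tumor and normal", {
  withr::with_seed(3, {
    for (shift in c(-2, 0, 2)) {
      a <- rnorm(25); b <- rnorm(25) + shift
      ab <- classifyTNC(a, b)
      ba <- classifyTNC(b, a)
      if (ab %in% c(0L, 1L)) expect_identical(ba, ab)
      else expect_identical(ba, c(`2` = 3L, `3` = 2L)[[as.character(ab)]])
    }
  })
})

test_that("HRC coding recovers planted hazard directions", {
  x <- withr::with_seed(11, rnorm(500))
  names(x) <- paste0("s", 1:500)
  mk <- function(beta) {
    st <- generateSurvival(beta * x, 0.1, censoringRate = 0, seed = 12)
    survListFromDF(data.frame(sample = names(x), time = st$time,
                              event = st$event))
  }
  risky <- fitHRC(x, mk(0.7))
  expect_identical(unname(risky$letters), rep("B", 4))
  expect_true(all(risky$fits$hr > 1))
  protective <- fitHRC(x, mk(-0.7))
  expect_identical(unname(protective$letters), rep("C", 4))
  # permuted covariate: null
  xp <- setNames(withr::with_seed(13, sample(x)), names(x))
  null <- fitHRC(xp, mk(0.7))
  expect_identical(unname(null$letters), rep("A", 4))
})

test_that("HRC degenerate inputs are coded A with a flag, not dropped", {
  x <- setNames(rnorm(20), paste0("s", 1:20))
  few <- survListFromDF(data.frame(sample = names(x),
                                   time = seq_len(20),
                                   event = c(1, rep(0, 19))))
  out <- fitHRC(x, few)
  expect_identical(unname(out$letters), rep("A", 4))
  expect_true(all(out$fits$flag == "fit-skipped"))
  bad <- survListFromDF(data.frame(sample = names(x), time = c(-1, 2:20),
                                   event = rep(1, 20)))
  expect_error(fitHRC(x, bad), "non-positive")
})

test_that("SMC letters follow the layer-specific group tables", {
  n <- 400
  ids <- paste0("s", 1:n)
  withr::with_seed(21, {
    mut <- rbinom(n, 1, 0.3)
    st <- generateSurvival(1.2 * mut, 0.1, 0, seed = 22)
    tabs <- survListFromDF(data.frame(sample = ids, time = st$time,
                                      event = st$event))
    out <- fitSMC(setNames(mut, ids), "mutation", tabs)
    expect_identical(unname(out$letters), rep("B", 4))   # MT poorer

    # protective mutation: wild type poorer
    st2 <- generateSurvival(-1.2 * mut, 0.1, 0, seed = 23)
    tabs2 <- survListFromDF(data.frame(sample = ids, time = st2$time,
                                       event = st2$event))
    out2 <- fitSMC(setNames(mut, ids), "mutation", tabs2)
    expect_identical(unname(out2$letters), rep("C", 4))

    # continuous feature independent of survival
    x <- rnorm(n)
    out3 <- fitSMC(setNames(x, ids), "mrna", tabs)
    expect_identical(unname(out3$letters), rep("A", 4))

    # CNV: hazard raised only in the deleted states
    cnv <- sample(c(-2, -1, 0, 1, 2), n, replace = TRUE,
                  prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
    st3 <- generateSurvival(1.5 * (cnv < 0), 0.1, 0, seed = 24)
    tabs3 <- survListFromDF(data.frame(sample = ids, time = st3$time,
                                       event = st3$event))
    out4 <- fitSMC(setNames(cnv, ids), "cnv", tabs3)
    expect_identical(unname(out4$letters), rep("B", 4))  # Deleted poorer

    # CNV: hazard raised in all non-neutral states -> pooled letter D
    st4 <- generateSurvival(1.5 * (cnv != 0), 0.1, 0, seed = 25)
    tabs4 <- survListFromDF(data.frame(sample = ids, time = st4$time,
                                       event = st4$event))
    out5 <- fitSMC(setNames(cnv, ids), "cnv", tabs4)
    expect_true(all(out5$letters %in% c("B", "D")))
    expect_true(any(out5$letters == "D"))
  })
})

test_that("SMC empty groups are coded A with a flag", {
  ids <- paste0("s", 1:50)
  st <- generateSurvival(rep(0, 50), 0.1, 0, seed = 31)
  tabs <- survListFromDF(data.frame(sample = ids, time = st$time,
                                    event = st$event))
  out <- fitSMC(setNames(rep(0, 50), ids), "mutation", tabs)
  expect_identical(unname(out$letters), rep("A", 4))
  expect_true(all(out$detail$flag == "group-empty"))
})
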