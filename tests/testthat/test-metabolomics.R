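test_that("missingness filter removes strictly above the threshold", {
  counts <- matrix(NA_real_, 3, 10,
                   dimnames = list(c("seven_missing", "six_missing", "full"),
                                   paste0("s", 1:10)))
  counts["seven_missing", 1:3] <- c(5, 6, 7)        # 7/10 missing -> removed
  counts["six_missing", 1:4] <- c(5, 6, 7, 8)       # exactly 6/10 -> retained
  counts["full", ] <- 1:10
  ae <- abundanceExperiment(counts, c(rep("blank", 5), rep("trt", 5)))
  filtered <- suppressMessages(filterMissing(ae))
  expect_setequal(rownames(filtered), c("six_missing", "full"))
  expect_equal(S4Vectors::metadata(filtered)$n_filtered, 1L)
  expect_equal(processingStage(filtered), "filtered")
})

test_that("imputation fills half the per-metabolite minimum", {
  counts <- matrix(c(NA, 4, 8,
                     1, 2, 3,
                     NA, 10, NA), 3, 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  ae <- abundanceExperiment(counts, c("blank", "trt", "trt"))
  imp <- imputeHalfMin(ae)   # runs on the raw stage when no filter is wanted
  a <- SummarizedExperiment::assay(imp)
  expect_equal(unname(a["a", ]), c(2, 4, 8))
  expect_equal(unname(a["b", ]), c(1, 2, 3))    # untouched
  expect_equal(unname(a["c", ]), c(5, 10, 5))   # the n = 2 rule
})

test_that("imputation refuses all-missing rows", {
  counts <- matrix(c(NA, NA, 1, 2), 2, 2, byrow = TRUE,
                   dimnames = list(c("gone", "ok"), c("s1", "s2")))
  ae <- abundanceExperiment(counts, c("blank", "trt"))
  expect_error(imputeHalfMin(ae), "no observed value")
})

test_that("normalization matches closed forms and zeroes the row center", {
  b <- 3
  counts <- rbind(geom = c(1, b, b^2), flat = c(7, 7, 7),
                  two = c(1, 8, NA))
  colnames(counts) <- c("s1", "s2", "s3")
  counts["two", 3] <- 64   # no missing for this test
  ae <- abundanceExperiment(counts, c("blank", "trt", "trt"))
  ae <- imputeHalfMin(suppressMessages(filterMissing(ae)))
  nb <- normalizeAbundance(ae, log_base = b)
  a <- SummarizedExperiment::assay(nb)
  expect_equal(unname(a["geom", ]), c(-1, 0, 1))
  expect_equal(unname(a["flat", ]), c(0, 0, 0))
  expect_lt(max(abs(rowMeans(a))), 1e-12)

  # log2 of c(1, 8) mean-centers to +-1.5
  counts2 <- rbind(x = c(1, 8))
  colnames(counts2) <- c("s1", "s2")
  ae2 <- abundanceExperiment(counts2, c("blank", "trt"))
  ae2 <- imputeHalfMin(suppressMessages(filterMissing(ae2)))
  a2 <- SummarizedExperiment::assay(normalizeAbundance(ae2, log_base = 2))
  expect_equal(unname(a2["x", ]), c(-1.5, 1.5))

  # median centering zeroes the row median instead
  ae3 <- abundanceExperiment(rbind(y = c(1, 4, 32)),
                             c("blank", "trt", "trt"))
  ae3 <- imputeHalfMin(suppressMessages(filterMissing(ae3)))
  a3 <- SummarizedExperiment::assay(normalizeAbundance(ae3, center = "median"))
  expect_equal(unname(a3["y", 2]), 0)
})

test_that("the processing chain enforces its stage order", {
  ae <- toyAbundance()
  expect_error(normalizeAbundance(ae), "impute|missing")
  imp <- imputeHalfMin(suppressMessages(filterMissing(ae)))
  norm <- normalizeAbundance(imp)
  expect_error(normalizeAbundance(norm), "twice")
  expect_error(suppressMessages(filterMissing(norm)), "stage")
  expect_error(classifyMetabolites(imp), "normalized")
})

test_that("exact Mann-Whitney handles perfect separation and symmetry", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  # label swap is symmetric
  r2 <- mannWhitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p, r$p)
  expect_equal(r2$U, 9)
  # degenerate identical constant samples
  expect_equal(mannWhitney(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_error(mannWhitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney equals brute-force enumeration with ties", {
  set.seed(31)
  for (i in 1:200) {
    nx <- sample(1:5, 1)
    ny <- sample(1:5, 1)
    x <- sample(0:6, nx, replace = TRUE)   # integer values force ties
    y <- sample(0:6, ny, replace = TRUE)
    got <- mannWhitney(x, y, mode = "exact")
    want <- oracleMannWhitney(x, y)
    expect_equal(got$U, want$U, label = paste("U case", i))
    expect_equal(got$p, want$p, label = paste("p case", i))
  }
})

test_that("the smallest attainable exact two-sided p at n=3 vs 3 is 0.1", {
  # the study design: n = 3 per group; even perfect separation can only
  # just clear an FDR threshold of 0.1
  ps <- replicate(50, {
    x <- sort(runif(3))
    y <- sort(runif(3)) + 2
    mannWhitney(x, y)$p
  })
  expect_true(all(ps >= 0.1 - 1e-12))
  expect_equal(min(ps), 0.1)
})

test_that("asymptotic mode agrees with the normal-approximation reference", {
  set.seed(5)
  x <- rnorm(12)
  y <- rnorm(15, 0.8)
  got <- mannWhitney(x, y, mode = "asymptotic")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value)
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  want <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bhAdjust(p), want)
  # order invariance
  idx <- c(3, 1, 4, 2, 8, 6, 7, 5)
  expect_equal(bhAdjust(p[idx]), want[idx])
  # q >= p elementwise
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # discoveries never increase as alpha decreases
  q <- bhAdjust(p)
  expect_true(sum(q < 0.05) <= sum(q < 0.1))
})

test_that("planted produced/consumed metabolites are classified correctly", {
  sim <- simulateAbundances(seed = 4, missing_rate = 0.05)
  ae <- sim$abundances
  ae <- suppressMessages(filterMissing(ae))
  # engineered high-missingness rows were removed by the 60% rule
  expect_false(any(sim$truth$high_missing %in% rownames(ae)))
  ae <- normalizeAbundance(imputeHalfMin(ae))
  cls <- classifyMetabolites(ae, condition_pairs = list(c("treated", "control")))
  classes <- setNames(cls$classes$class, cls$classes$metabolite)

  # consumed in both conditions vs blank -> consumed_only
  expect_equal(unname(classes["C00031"]), "consumed_only")
  # produced in both conditions -> produced_or_consumed
  expect_equal(unname(classes["C00186"]), "produced_or_consumed")
  # consumed in treated only: still only-consumed among significant calls,
  # and the treated-vs-control contrast sees it as lower
  expect_equal(unname(classes["C00106"]), "consumed_only")
  pair_row <- cls$tests[cls$tests$metabolite == "C00106" &
                          cls$tests$type == "pair", ]
  expect_equal(pair_row$call, "lower")
  # a secreted product above blank in both groups
  expect_equal(unname(classes["X001"]), "produced_or_consumed")
  # planted secretion in the control group only
  expect_equal(unname(classes["X007"]), "produced_or_consumed")
  ctl_row <- cls$tests[cls$tests$metabolite == "X007" &
                         cls$tests$contrast == "control_vs_blank", ]
  expect_equal(ctl_row$call, "produced")
  # an unplanted metabolite equal to blank everywhere stays unchanged
  expect_equal(unname(classes["X011"]), "unchanged")

  expect_error(classifyMetabolites(ae, condition_pairs = list(c("treated", "nope"))),
               "unknown condition")
})

test_that("classification calls are consistent with their class rules", {
  sim <- simulateAbundances(seed = 9)
  ae <- normalizeAbundance(imputeHalfMin(suppressMessages(
    filterMissing(sim$abundances))))
  cls <- classifyMetabolites(ae, condition_pairs = list(c("treated", "control")))
  for (met in cls$classes$metabolite) {
    rows <- cls$tests[cls$tests$metabolite == met, ]
    blank_sig <- rows$call[rows$type == "vs_blank" & rows$call != "unchanged"]
    klass <- cls$classes$class[cls$classes$metabolite == met]
    if (klass == "consumed_only") {
      expect_true(length(blank_sig) >= 1 && all(blank_sig == "consumed"))
    } else if (klass == "produced_or_consumed") {
      expect_true(any(blank_sig == "produced"))
    } else if (klass == "differential_without_blank_significance") {
      expect_equal(length(blank_sig), 0L)
      expect_true(any(rows$call[rows$type == "pair"] != "unchanged"))
    }
  }
})
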