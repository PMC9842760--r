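test_that("size factors reproduce hand-computed median-of-ratios", {
  set.seed(4)
  base <- matrix(rpois(50, 100) + 1L, 50, 1)
  counts <- cbind(base, 2L * base)
  rownames(counts) <- paste0("g", 1:50)
  colnames(counts) <- c("s1", "s2")
  expect_equal(unname(size_factors(counts)), c(1 / sqrt(2), sqrt(2)))
  # single gene, counts (4, 16)
  one <- matrix(c(4L, 16L), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(size_factors(one)), c(0.5, 2))
  # identical samples
  same <- cbind(base, base, base)
  expect_equal(unname(size_factors(same)), rep(1, 3))
})

test_that("size factors match DESeq2's median-of-ratios on random data", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  counts <- matrix(rnbinom(200 * 6, mu = 200, size = 5), 200, 6)
  counts <- round(sweep(counts, 2, c(1, 2, 0.5, 1.5, 0.8, 1.2), "*"))
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("g", 1:200)
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # same estimator up to the geometric-mean-1 rescaling
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-10)
})

test_that("size factor invariances hold", {
  set.seed(14)
  counts <- matrix(rnbinom(100 * 4, mu = 150, size = 10) + 1L, 100, 4)
  rownames(counts) <- paste0("g", 1:100)
  f <- size_factors(counts)
  # rescaling one sample by k multiplies its factor by k (up to the
  # geometric-mean rescale applied to all factors)
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 3L
  f2 <- size_factors(counts2)
  expect_equal(unname((f2 / f)[2] / exp(mean(log(f2 / f)))),
               3 / exp(mean(log(c(1, 3, 1, 1)))), tolerance = 1e-10)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2, 2)), "reference")
})

test_that("dispersion estimation clips Poisson-like genes and recovers alpha", {
  # identical counts everywhere -> variance 0 -> floor
  counts <- matrix(5L, 3, 6, dimnames = list(paste0("g", 1:3), NULL))
  cond <- rep(c("A", "B"), each = 3)
  a <- estimate_dispersion(counts, rep(1, 6), cond)
  expect_equal(unname(as.numeric(a)), rep(1e-8, 3))
  # all-zero gene flagged at floor
  counts[2, ] <- 0L
  counts[1, 1] <- 6L
  a2 <- estimate_dispersion(counts, rep(1, 6), cond)
  expect_equal(unname(a2[["g2"]]), 1e-8)
  expect_equal(attr(a2, "flagged"), "g2")
  # recovery: true alpha 0.1, 4 conditions x 50 replicates
  set.seed(5)
  n <- 1000
  mu <- exp(runif(n, log(20), log(2000)))
  big <- sapply(1:200, function(j) rnbinom(n, mu = mu, size = 10))
  rownames(big) <- paste0("g", 1:n)
  cond4 <- rep(c("a", "b", "c", "d"), each = 50)
  ahat <- estimate_dispersion(big, size_factors(big), cond4)
  expect_gt(median(ahat), 0.08)
  expect_lt(median(ahat), 0.12)
})

test_that("Wald contrast is null on identical groups and antisymmetric", {
  counts <- matrix(rep(c(10L, 40L, 7L), each = 6), 3, 6, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), NULL))
  cond <- rep(c("A", "B"), each = 3)
  r <- wald_contrast(counts, cond, contrast_spec("t", "B", "A"),
                     factors = rep(1, 6),
                     dispersions = uniform_disp(counts, 0.1))
  expect_equal(r$log2fc, rep(0, 3))
  expect_equal(r$wald_z, rep(0, 3))
  expect_equal(r$pvalue, rep(1, 3))
  # antisymmetry on real data
  tg <- two_group_counts(50, mu0 = 100, lfc = 1.5, seed = 8)
  d <- uniform_disp(tg$counts, 0.1)
  fwd <- wald_contrast(tg$counts, tg$condition, contrast_spec("f", "B", "A"),
                       factors = rep(1, 6), dispersions = d)
  rev_ <- wald_contrast(tg$counts, tg$condition, contrast_spec("r", "A", "B"),
                        factors = rep(1, 6), dispersions = d)
  expect_equal(fwd$log2fc, -rev_$log2fc)
  expect_equal(fwd$wald_z, -rev_$wald_z)
  expect_equal(fwd$pvalue, rev_$pvalue)
})

test_that("Wald test is calibrated under the null NB model", {
  set.seed(210)
  mu0 <- exp(runif(5000, log(20), log(2000)))
  tg <- two_group_counts(5000, mu0 = mu0, lfc = 0, seed = 21)
  r <- wald_contrast(tg$counts, tg$condition, contrast_spec("t", "B", "A"),
                     dispersions = uniform_disp(tg$counts, 0.1))
  frac <- mean(r$pvalue < 0.05, na.rm = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / 5000)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("planted log2 effects are recovered", {
  set.seed(120)
  mu0 <- exp(runif(1000, log(50), log(1000)))
  tg <- two_group_counts(1000, mu0 = mu0, lfc = 2, seed = 12)
  r <- wald_contrast(tg$counts, tg$condition, contrast_spec("t", "B", "A"),
                     factors = rep(1, 6),
                     dispersions = uniform_disp(tg$counts, 0.1))
  expect_gt(median(r$log2fc), 1.8)
  expect_lt(median(r$log2fc), 2.2)
})

test_that("all-zero genes are excluded from testing and the BH family", {
  tg <- two_group_counts(20, mu0 = 100, seed = 3)
  tg$counts[5, ] <- 0L
  r <- wald_contrast(tg$counts, tg$condition, contrast_spec("t", "B", "A"),
                     dispersions = uniform_disp(tg$counts, 0.1))
  expect_true(is.na(r$pvalue[5]) && is.na(r$padj[5]))
  tested <- !is.na(r$pvalue)
  expect_equal(r$padj[tested], enum_bh(r$pvalue[tested]))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))^2
    expect_equal(bh_adjust(p), enum_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("regulation calls use strict thresholds in raw and adjusted mode", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    base_mean = 10, log2fc = c(1.2, 1.0, 0.6, -1.4),
                    se_log2fc = 0.1, wald_z = 1,
                    pvalue = c(0.001, 0.0001, 0.004, 0.001),
                    padj = c(0.01, 0.001, 0.04, 0.01),
                    up = NA, down = NA)
  class(res) <- c("contrast_result", "data.frame")
  raw1 <- call_regulated(res, call_thresholds(lfc_min = 1, p_max = 0.005,
                                              padj_max = NULL,
                                              use_adjusted = FALSE))
  expect_equal(raw1$up, c(TRUE, FALSE, FALSE, FALSE))  # 1.0 exactly fails ">"
  expect_equal(raw1$down, c(FALSE, FALSE, FALSE, TRUE))
  raw05 <- call_regulated(res, call_thresholds(lfc_min = 0.5, p_max = 0.005,
                                               padj_max = NULL,
                                               use_adjusted = FALSE))
  expect_true(raw05$up[3])  # volcano-style: |lfc| > 0.5, p < 0.005
  adj <- call_regulated(res, call_thresholds(lfc_min = 1, padj_max = 0.05))
  expect_equal(adj$up, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(adj$up & adj$down))
  expect_error(call_thresholds(lfc_min = 1, p_max = NULL, padj_max = NULL),
               "at least one")
})
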