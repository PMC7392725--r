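test_that("Diff/Sum values and the combined-count filter follow the definition", {
  sig <- tibble::tibble(ct = c(3, 1, 3, 1), kd = c(3, 3, 0, 1))
  rec <- compute_diff_sum(sig, min_combined = 3)
  # (1,1) is excluded: combined signal 2 < 3
  expect_equal(rec$diff_sum, c(0, 0.5, -1))
  expect_equal(rec$state, c("none", "GoM", "LoM"))
})

test_that("swapping CT and KD negates every Diff/Sum value", {
  set.seed(1)
  sig <- tibble::tibble(ct = rpois(500, 10), kd = rpois(500, 10))
  a <- compute_diff_sum(sig)
  b <- compute_diff_sum(dplyr::rename(sig, ct = kd, kd = ct))
  expect_equal(b$diff_sum, -a$diff_sum)
})

test_that("the Diff/Sum histogram has symmetric layout and conserves mass", {
  set.seed(2)
  rec <- compute_diff_sum(tibble::tibble(ct = rpois(400, 8),
                                         kd = rpois(400, 8)))
  h <- diffsum_histogram(rec, width = 0.1)
  expect_equal(sum(h$freq), nrow(rec))
  expect_equal(h$mid, seq(-1, 1, 0.1))
})

test_that("the mirrored expectation averages sign pairs, fixes symmetric input, and is idempotent", {
  h <- tibble::tibble(mid = round(seq(-1, 1, 0.1), 10), freq = 0)
  h$freq[h$mid == 0.3] <- 10
  h$freq[h$mid == -0.3] <- 20
  h$freq[h$mid == 0] <- 7
  e <- mirrored_expected(h)
  expect_equal(e$freq[e$mid == 0.3], 15)
  expect_equal(e$freq[e$mid == -0.3], 15)
  expect_equal(e$freq[e$mid == 0], 7) # center unchanged
  expect_equal(sum(e$freq), sum(h$freq)) # mass preserved
  expect_equal(mirrored_expected(e), e) # idempotent
  sym <- tibble::tibble(mid = seq(-1, 1, 0.1), freq = rep(3, 21))
  expect_equal(mirrored_expected(sym), sym) # fixed point
})

test_that("observed-vs-expected comparison reports zero deviation at identity", {
  h <- tibble::tibble(mid = seq(-1, 1, 0.1),
                      freq = c(1:10, 11, 10:1))
  cmp <- compare_observed_expected(h, h)
  expect_equal(cmp$mean_diff_freq, 0)
  expect_equal(cmp$mean_shift, 0)
  expect_equal(cmp$ks_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("KS statistic matches hand-computed CDFs on the one-sided case", {
  obs <- tibble::tibble(mid = seq(-1, 1, 0.5), freq = c(0, 4, 0, 0, 0))
  exp_ <- mirrored_expected(obs)
  expect_equal(exp_$freq, c(0, 2, 0, 2, 0))
  cmp <- compare_observed_expected(obs, exp_)
  # CDFs at the -0.5 bin: 1.0 observed vs 0.5 expected
  expect_equal(cmp$ks_statistic, 0.5)
  # left shift: weighted mean moves toward negative Diff/Sum
  expect_lt(cmp$mean_shift, 0)
  expect_equal(cmp$mean_shift, -0.5)
  # disjoint supports give the maximal statistic
  left <- tibble::tibble(mid = c(-1, 0, 1), freq = c(5, 0, 0))
  right <- tibble::tibble(mid = c(-1, 0, 1), freq = c(0, 0, 5))
  expect_equal(compare_observed_expected(left, right)$ks_statistic, 1)
})

test_that("tidy and glance expose the comparison as tibbles", {
  h <- tibble::tibble(mid = seq(-1, 1, 0.1), freq = rep(2, 21))
  cmp <- compare_observed_expected(h, mirrored_expected(h))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_named(glance(cmp), c("mean_diff_freq", "mean_shift",
                              "ks_statistic", "p_value", "n_bins"))
})

test_that("entropy calibration: equal split gives 1 bit, exclusivity 0, quarter split 0.8113", {
  equal <- tibble::tibble(ct = rep(c(2, 6), 20), kd = rep(c(6, 2), 20))
  prof <- shannon_entropy_profile(compute_diff_sum(equal))
  expect_equal(prof$entropy, 1)
  expect_equal(prof$p_gom, 0.5)

  excl <- tibble::tibble(ct = rep(2, 10), kd = rep(6, 10))
  prof2 <- shannon_entropy_profile(compute_diff_sum(excl))
  expect_equal(prof2$entropy, 0)

  quarter <- tibble::tibble(ct = c(rep(2, 1), rep(6, 3)),
                            kd = c(rep(6, 1), rep(2, 3)))
  prof3 <- shannon_entropy_profile(compute_diff_sum(quarter))
  expect_equal(prof3$p_gom, 0.25)
  expect_equal(prof3$entropy, -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(prof3$entropy, 0.8112781, tolerance = 1e-6)
})

test_that("entropy filters require 3 combined and 2 in either sample; ties carry no state", {
  rec <- compute_diff_sum(tibble::tibble(ct = c(2, 1, 2), kd = c(1, 1, 2)),
                          min_combined = 3)
  prof <- shannon_entropy_profile(rec)
  # (2,1): combined 3 and max 2 -> kept; (2,2): diff 0, no GoM/LoM state
  expect_equal(sum(prof$n), 1)
  expect_equal(sum(prof$n_total), 2)
  # a record with max(ct, kd) < 2 is excluded even at combined >= 3
  rec2 <- tibble::tibble(ct = 1.5, kd = 1.5, diff_sum = 0)
  expect_equal(nrow(shannon_entropy_profile(rec2)), 0)
})

test_that("methylation bin density tiers split at 5 and exclude levels above 30", {
  counts <- tibble::tibble(sample = "CT", count = c(0, 5, 5, 30, 31))
  d <- methylation_bin_density(counts)
  expect_equal(d$level, c(5, 30))
  expect_equal(d$n_bins, c(2L, 1L))
  expect_equal(d$tier, c("main", "main"))
  low <- methylation_bin_density(tibble::tibble(sample = "CT",
                                                count = c(1, 4, 2)))
  expect_equal(unique(low$tier), "low")
  empty <- methylation_bin_density(tibble::tibble(sample = "CT",
                                                  count = rep(0, 10)))
  expect_equal(nrow(empty), 0)
  # order invariance
  shuffled <- counts[sample.int(5), ]
  expect_equal(methylation_bin_density(shuffled), d)
})

test_that("multiscale correlation is 1 for identical reads and near 0 for independent reads", {
  set.seed(3)
  gt <- tibble::tibble(chrom = "chr1", length = 1000000L)
  start <- sample.int(999850, 4000) - 1L
  reads <- tibble::tibble(chrom = "chr1", start = start, end = start + 150L)
  same <- multiscale_correlation(reads, reads, gt, bin_sizes = c(10000, 200))
  expect_equal(same$rho, c(1, 1))
  start2 <- sample.int(999850, 4000) - 1L
  other <- tibble::tibble(chrom = "chr1", start = start2, end = start2 + 150L)
  indep <- multiscale_correlation(reads, other, gt, bin_sizes = 200)
  expect_equal(indep$n_bins, 5000)
  expect_lt(abs(indep$rho), 0.1)
})

test_that("sample PCA matches an eigendecomposition oracle and its fractions sum to 1", {
  mat <- matrix(c(1, 2, 3,
                  2, 4, 5,
                  0, 1, 1,
                  7, 0, 2), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  p <- pca_samples(mat)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # oracle: eigenvalues of the sample covariance of centered rows
  cen <- scale(mat, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cen) / (nrow(mat) - 1))$values
  expect_equal(unname(p$prcomp$sdev^2), ev[seq_along(p$prcomp$sdev)],
               tolerance = 1e-9)
  # identical samples: no between-sample scatter, one trivial dimension
  twin <- matrix(rep(c(1, 2, 3), each = 2), nrow = 2,
                 dimnames = list(c("a", "b"), NULL))
  pt <- pca_samples(twin)
  expect_equal(max(abs(pt$prcomp$x)), 0, tolerance = 1e-12)
  expect_equal(unname(pt$variance_fraction[1]), 1)
  expect_error(pca_samples(matrix(0, 2, 3)), "zero")
})
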