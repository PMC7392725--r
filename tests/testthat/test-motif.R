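random_pfm <- function(width, seed) {
  withr::with_seed(seed, {
    m <- matrix(rpois(4 * width, 20), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(sample.int(4, width, replace = TRUE), seq_len(width))] <-
      m[1] + 60 # give each column a preferred base
    m
  })
}

test_that("PFM to PWM conversion normalizes columns with the per-cell pseudocount", {
  p0 <- pwm_from_pfm(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(p0$prob[, 1], c(A = 1, C = 0, G = 0, T = 0))
  uni <- pwm_from_pfm(matrix(5, 4, 3), pseudocount = 0.1)
  expect_equal(unname(uni$log_odds), matrix(0, 4, 3))
  p <- pwm_from_pfm(matrix(c(8, 2, 0, 0), 4, 1), pseudocount = 0.1)
  expect_equal(unname(p$prob[1, 1]), 8.1 / 10.4)
  expect_equal(colSums(p$prob), 1)
  expect_error(pwm_from_pfm(matrix(0, 4, 2)), "all-zero")
})

test_that("p-value table on a width-1 PWM reproduces single-base probabilities", {
  pwm <- pwm_from_pfm(matrix(c(10, 5, 3, 2), 4, 1), pseudocount = 0.1)
  tbl <- score_pvalue_table(pwm)
  # best base (A): p = P(score >= max) = background probability of A
  expect_equal(pwm_score_pvalue(tbl, max(pwm$log_odds)), 0.25)
  # worst score has p = 1
  expect_equal(pwm_score_pvalue(tbl, min(pwm$log_odds)), 1)
  expect_true(all(diff(tbl$pvalue) <= 1e-12))
})

test_that("p-value table equals exhaustive word enumeration for small widths", {
  for (w in c(2L, 3L, 5L)) {
    pwm <- pwm_from_pfm(random_pfm(w, seed = w), pseudocount = 0.1)
    tbl <- score_pvalue_table(pwm)
    lo_int <- round(pwm$log_odds / tbl$granularity)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(matrix(lo_int[cbind(as.vector(words),
                                          rep(seq_len(w), each = nrow(words)))],
                             nrow = nrow(words)))
    bgp <- apply(matrix(0.25, nrow(words), w), 1, prod)
    for (s in sort(unique(scores))) {
      expect_equal(pwm_score_pvalue(tbl, s * tbl$granularity),
                   sum(bgp[scores >= s]), tolerance = 1e-12)
    }
  }
})

test_that("the maximum attainable score has p at least the consensus word probability", {
  pwm <- pwm_from_pfm(random_pfm(6, seed = 9))
  tbl <- score_pvalue_table(pwm)
  pmax_score <- pwm_score_pvalue(tbl, max(tbl$scores) * tbl$granularity)
  expect_gte(pmax_score, 0.25^6 - 1e-12)
  expect_gt(pmax_score, 0)
})

test_that("scanning finds a planted consensus, skips N windows, and is strand symmetric", {
  pwm <- pwm_from_pfm(random_pfm(8, seed = 4), tf_name = "toy")
  cons <- pwm_consensus(pwm)
  seq1 <- paste0("ACGTACGTAC", cons, "GGTTGGTTGG")
  hits <- scan_sequences(c(chr1 = seq1), pwm, threshold = 1e-2,
                         background = "uniform")
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$start == 10 & hits$end == 18 & hits$strand == "+"))

  expect_equal(nrow(scan_sequences(c(chr1 = strrep("N", 60)), pwm,
                                   threshold = 1)), 0)
  expect_equal(nrow(scan_sequences(c(chr1 = "ACG"), pwm, threshold = 1)), 0)

  # reverse-complement planting scores identically on the minus strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  seq2 <- paste0("ACGTACGTAC", rc, "GGTTGGTTGG")
  hits2 <- scan_sequences(c(chr1 = seq2), pwm, threshold = 1e-2,
                          background = "uniform")
  minus <- dplyr::filter(hits2, start == 10, strand == "-")
  plus <- dplyr::filter(hits, start == 10, strand == "+")
  expect_equal(minus$score, plus$score)
  expect_equal(minus$pvalue, plus$pvalue)
})

test_that("interval shuffling preserves lengths, is seeded, and places uniformly", {
  gt <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(10000L, 5000L))
  iv <- tibble::tibble(chrom = "chr1", start = c(0L, 500L, 1200L),
                       end = c(300L, 700L, 1250L))
  s1 <- shuffle_intervals(iv, gt, seed = 5)
  s2 <- shuffle_intervals(iv, gt, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(s1$end - s1$start), sort(iv$end - iv$start))
  expect_true(all(s1$start >= 0))
  # uniformity of a single 200 bp interval on a 10 kb chromosome
  one <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  gt1 <- tibble::tibble(chrom = "chr1", length = 10000L)
  starts <- withr::with_seed(6, {
    vapply(seq_len(1000),
           function(i) shuffle_intervals(one, gt1)$start, integer(1))
  })
  bins <- cut(starts, breaks = seq(0, 9801, length.out = 11),
              include.lowest = TRUE)
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("enrichment chi-square matches the worked 2x2 example and null cases", {
  counts <- tibble::tibble(tf = "TF1", observed_hit_bins = 30,
                           n_differential_bins = 1000,
                           background_hit_bins = 100,
                           n_background_bins = 10000)
  res <- tfbs_enrichment(counts)
  expect_equal(res$chi2, 31.14, tolerance = 1e-3)
  expect_equal(res$direction, "enriched")
  # observed rate equal to background rate: no association
  null <- tfbs_enrichment(tibble::tibble(
    tf = "TF0", observed_hit_bins = 10, n_differential_bins = 100,
    background_hit_bins = 100, n_background_bins = 1000))
  expect_equal(null$chi2, 0)
  # zero-margin table is reported as no association, not NaN
  zero <- tfbs_enrichment(tibble::tibble(
    tf = "TFz", observed_hit_bins = 0, n_differential_bins = 100,
    background_hit_bins = 0, n_background_bins = 1000))
  expect_equal(zero$chi2, 0)
  expect_equal(zero$p_value, 1)
})

test_that("the per-TF Diff/Sum matrix is the Diff/Sum of average signals", {
  tf_bins <- tibble::tibble(tf = c("a", "a", "b", "b"), bin = c(1L, 2L, 3L, 4L))
  sig <- tibble::tibble(bin = 1:4, ct = c(2, 2, 3, 3), kd = c(6, 6, 3, 3))
  m <- tf_diffsum_matrix(tf_bins, list(cellA = sig))
  expect_equal(m$diff_sum[m$tf == "a"], 0.5) # (6-2)/(6+2)
  expect_equal(m$diff_sum[m$tf == "b"], 0)
})
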