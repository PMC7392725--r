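#' Shannon-entropy profile of methylation-change stochasticity
#'
#' At each |Diff/Sum| magnitude bin, the binary Shannon entropy of the
#' gain-versus-loss (GoM/LoM) state quantifies how stochastic the
#' methylation change of that magnitude is: an equal presence of regions in
#' GoM and LoM gives entropy 1 bit, an exclusive presence in one state
#' gives 0. Bins are filtered for a minimum combined CT+KD read count and a
#' minimum count in at least one sample; regions at Diff/Sum exactly 0 carry
#' no GoM/LoM state and are excluded from the probability.
#'
#' @param records Output of [compute_diff_sum()] (must retain `ct`, `kd`).
#' @param magnitude_bin_width Width of the |Diff/Sum| magnitude bins
#'   (default 0.1; values rounded to the nearest multiple).
#' @param min_combined Minimum `ct + kd` (default 3).
#' @param min_either Minimum `max(ct, kd)` (default 2).
#' @return Tibble with one row per populated magnitude bin: `magnitude`,
#'   `n_gom`, `n_lom`, `n` (= GoM + LoM), `p_gom`, and `entropy` (bits;
#'   `NA` when `n` is 0).
#' @examples
#' rec <- compute_diff_sum(tibble::tibble(ct = c(1, 3), kd = c(3, 1)))
#' shannon_entropy_profile(rec) # equal GoM/LoM at |Diff/Sum| 0.5 -> 1 bit
#' @export
shannon_entropy_profile <- function(records, magnitude_bin_width = 0.1,
                                    min_combined = 3, min_either = 2) {
  need <- c("ct", "kd", "diff_sum")
  if (!all(need %in% names(records))) {
    abort("records needs ct, kd and diff_sum columns")
  }
  w <- magnitude_bin_width
  records %>%
    filter(.data$ct + .data$kd >= min_combined,
           pmax(.data$ct, .data$kd) >= min_either) %>%
    mutate(magnitude = round(round(abs(.data$diff_sum) / w) * w, 10)) %>%
    group_by(magnitude = .data$magnitude) %>%
    summarise(
      n_gom = sum(.data$diff_sum > 0),
      n_lom = sum(.data$diff_sum < 0),
      n_total = dplyr::n(),
      .groups = "drop") %>%
    mutate(
      n = .data$n_gom + .data$n_lom,
      p_gom = ifelse(.data$n > 0, .data$n_gom / .data$n, NA_real_),
      entropy = binary_entropy(.data$p_gom)) %>%
    arrange(.data$magnitude)
}

#' Bin-wise methylation read-density distribution
#'
#' Histograms genomic bins by their integer MeDIP read count ("methylation
#' signal level"): the low tier (levels 1-4, rarely captured methylation),
#' the main analysis tier (levels 5-30), and exclusion of levels above 30.
#' Zero-count bins are in neither tier.
#'
#' @param counts Tibble with a `count` column of raw integer per-bin read
#'   counts and a `sample` column (one row per genomic bin per sample).
#' @param low_range,main_range Integer level ranges for the two tiers
#'   (defaults 1:4 and 5:30).
#' @return Tibble with `sample`, `level`, `tier` (`"low"`/`"main"`) and
#'   `n_bins`, populated levels only.
#' @export
methylation_bin_density <- function(counts, low_range = 1:4,
                                    main_range = 5:30) {
  if (!all(c("sample", "count") %in% names(counts))) {
    abort("counts needs sample and count columns")
  }
  counts %>%
    filter(.data$count %in% c(low_range, main_range)) %>%
    count(.data$sample, level = .data$count, name = "n_bins") %>%
    mutate(tier = ifelse(.data$level %in% low_range, "low", "main")) %>%
    select("sample", "level", "tier", "n_bins") %>%
    arrange(.data$sample, .data$level)
}

#' Spearman correlation of two MeDIP signals across bin sizes
#'
#' Bins both read sets at each scale and correlates the paired per-bin
#' counts. Under bin-level stochastic methylation change, correlation is
#' high at coarse scales (10 kb) and decays toward the 0.2 kb analysis
#' scale.
#'
#' @param reads_ct,reads_kd Read interval tibbles.
#' @param genome_table Tibble with `chrom` and `length`.
#' @param bin_sizes Integer vector of scales (default
#'   `c(10000, 5000, 1000, 200)`).
#' @param method Correlation method (default `"spearman"`).
#' @return Tibble with `bin_size`, `n_bins`, `rho` (`NA` when either signal
#'   is constant).
#' @export
multiscale_correlation <- function(reads_ct, reads_kd, genome_table,
                                   bin_sizes = c(10000, 5000, 1000, 200),
                                   method = "spearman") {
  purrr::map_dfr(bin_sizes, function(bs) {
    grid <- make_windows(genome_table, bs)
    ct <- coverage_fractional(reads_ct, grid)$count
    kd <- coverage_fractional(reads_kd, grid)$count
    rho <- if (sd(ct) == 0 || sd(kd) == 0) NA_real_ else
      cor(ct, kd, method = method)
    tibble(bin_size = bs, n_bins = nrow(grid), rho = rho)
  })
}

#' Principal component analysis of MeDIP samples
#'
#' Covariance PCA of the sample-by-bin signal matrix (bins centered, not
#' scaled), as used to separate stochastic from deterministic
#' methylation-change variance across datasets.
#'
#' @param mat Numeric matrix, samples in rows (rownames = sample labels),
#'   bins in columns.
#' @return Object of class `medip_pca`: list with the `prcomp` fit,
#'   `variance_fraction` (descending, sums to 1; for identical samples the
#'   single informative dimension carries fraction 1 by convention), and a
#'   `scores` tibble.
#' @export
pca_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) abort("need >= 2 samples and >= 2 bins")
  if (all(mat == 0)) abort("signal matrix is all zero")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sample", seq_len(nrow(mat)))
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  frac <- if (sum(v) > 1e-12) {
    v / sum(v)
  } else {
    # identical samples: no between-sample variance; by convention the
    # single informative dimension carries all of it
    c(1, rep(0, length(v) - 1))
  }
  names(frac) <- colnames(fit$x)
  scores <- as_tibble(fit$x, rownames = "sample")
  structure(list(prcomp = fit, variance_fraction = frac, scores = scores,
                 n_samples = nrow(mat), n_bins = ncol(mat)),
            class = "medip_pca")
}

#' @export
print.medip_pca <- function(x, ...) {
  cat(sprintf("MeDIP sample PCA: %d samples x %d bins\n",
              x$n_samples, x$n_bins))
  vf <- x$variance_fraction
  cat("  variance fractions:",
      paste(sprintf("%s %.1f%%", names(vf), 100 * vf), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_samples
#' @param x A `medip_pca` object.
#' @param ... Unused.
#' @export
tidy.medip_pca <- function(x, ...) x$scores

#' @rdname pca_samples
#' @export
glance.medip_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble(n_samples = x$n_samples, n_bins = x$n_bins,
         pc1_fraction = vf[1],
         pc2_fraction = if (length(vf) >= 2) vf[2] else NA_real_)
}
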