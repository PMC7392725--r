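#' Per-bin Diff/Sum methylation-change statistic
#'
#' For each genomic bin with paired normalized MeDIP counts, computes
#' `(kd - ct) / (kd + ct)`, bounded in \[-1, 1\]. Bins below the combined
#' read-count filter are dropped. A positive value is a gain of methylation
#' (GoM) in the knockdown, a negative value a loss (LoM).
#'
#' @param signals Tibble with `ct` and `kd` count columns (other columns,
#'   e.g. bin coordinates, are carried through).
#' @param min_combined Minimum `ct + kd` for a bin to be retained
#'   (default 3).
#' @return Tibble of retained bins with `diff_sum` and `state`
#'   (`"GoM"`, `"LoM"`, or `"none"` at exactly 0) appended.
#' @examples
#' compute_diff_sum(tibble::tibble(ct = c(3, 1, 2, 1), kd = c(3, 3, 0, 1)))
#' @export
compute_diff_sum <- function(signals, min_combined = 3) {
  if (!all(c("ct", "kd") %in% names(signals))) {
    abort("signals needs ct and kd columns")
  }
  signals %>%
    filter(.data$ct + .data$kd >= min_combined) %>%
    mutate(
      diff_sum = (.data$kd - .data$ct) / (.data$kd + .data$ct),
      state = dplyr::case_when(
        .data$diff_sum > 0 ~ "GoM",
        .data$diff_sum < 0 ~ "LoM",
        TRUE ~ "none"))
}

#' Frequency histogram of Diff/Sum values
#'
#' Bins Diff/Sum values onto a symmetric grid of centers
#' `-1, -1+width, ..., 0, ..., 1` (values are rounded to the nearest
#' center), matching a frequency interval of `width`.
#'
#' @param records Output of [compute_diff_sum()] (or any tibble with a
#'   `diff_sum` column).
#' @param width Histogram interval (default 0.1).
#' @return Tibble with `mid` (bin center) and `freq`; every grid center is
#'   present (zero frequencies included). Attributes: `width`, `n_records`.
#' @export
diffsum_histogram <- function(records, width = 0.1) {
  if (!"diff_sum" %in% names(records)) abort("records needs a diff_sum column")
  if (width <= 0 || width > 2) abort("width must be in (0, 2]")
  k <- round(records$diff_sum / width)
  kmax <- round(1 / width)
  grid <- seq(-kmax, kmax)
  freq <- as.integer(table(factor(k, levels = grid)))
  out <- tibble(mid = round(grid * width, 10), freq = freq)
  attr(out, "width") <- width
  attr(out, "n_records") <- nrow(records)
  out
}

#' Mirrored expected Diff/Sum distribution
#'
#' The expected distribution under methylation disturbance with no net
#' change: the frequency at each pair of centers `+b` / `-b` is replaced by
#' their mean (the frequency at 0 is unchanged). Mass-preserving and
#' idempotent; a symmetric observed histogram is a fixed point.
#'
#' @param observed Histogram from [diffsum_histogram()].
#' @return Histogram tibble of the same layout with mirrored frequencies.
#' @export
mirrored_expected <- function(observed) {
  if (!all(c("mid", "freq") %in% names(observed))) {
    abort("observed must have mid and freq columns")
  }
  mid <- observed$mid
  freq <- observed$freq
  # pair each center with its negation; layout must be symmetric about 0
  partner <- match(round(-mid, 10), round(mid, 10))
  if (any(is.na(partner))) abort("histogram layout is not symmetric about 0")
  out <- observed
  out$freq <- (freq + freq[partner]) / 2
  out
}

#' Compare observed and expected Diff/Sum histograms
#'
#' Quantifies the deviation of the observed Diff/Sum distribution from its
#' mirrored expectation: a frequency-difference summary, a net-shift summary
#' in Diff/Sum units, and a Kolmogorov-Smirnov comparison of the two
#' bin-ordered CDFs (asymptotic two-sample p-value with effective sample
#' size equal to the number of histogram bins — approximate, as the
#' histogram pairing does not define a sample size).
#'
#' @param observed,expected Histograms on the same layout (see
#'   [diffsum_histogram()], [mirrored_expected()]).
#' @return Object of class `diffsum_ks`: `mean_diff_freq` (mean over
#'   histogram bins of observed - expected frequency; zero whenever total
#'   mass is preserved), `mean_shift` (frequency-difference-weighted mean
#'   Diff/Sum, in Diff/Sum units; negative = left shift / net LoM),
#'   `ks_statistic`, `p_value`, `n_bins`, and the per-bin `table`.
#' @export
compare_observed_expected <- function(observed, expected) {
  if (!identical(round(observed$mid, 10), round(expected$mid, 10))) {
    abort("observed and expected must share one histogram layout")
  }
  to <- sum(observed$freq)
  te <- sum(expected$freq)
  if (to == 0 || te == 0) abort("histogram has zero total mass")
  d <- observed$freq - expected$freq
  cdf_o <- cumsum(observed$freq) / to
  cdf_e <- cumsum(expected$freq) / te
  D <- max(abs(cdf_o - cdf_e))
  n_bins <- nrow(observed)
  p <- ks_asymptotic_p(D, n_bins, n_bins)
  structure(list(
    mean_diff_freq = mean(d),
    mean_shift = sum(observed$mid * d) / to,
    ks_statistic = D,
    p_value = p,
    n_bins = n_bins,
    table = tibble(mid = observed$mid, observed = observed$freq,
                   expected = expected$freq, difference = d)
  ), class = "diffsum_ks")
}

# asymptotic two-sample Kolmogorov p-value
ks_asymptotic_p <- function(D, n1, n2) {
  en <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(en) * D
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.diffsum_ks <- function(x, ...) {
  cat("Observed vs mirrored-expected Diff/Sum comparison\n")
  cat(sprintf("  mean shift (Diff/Sum units): %.4f\n", x$mean_shift))
  cat(sprintf("  mean frequency difference:   %.4g\n", x$mean_diff_freq))
  cat(sprintf("  KS D = %.4f, p = %.4g (over %d histogram bins)\n",
              x$ks_statistic, x$p_value, x$n_bins))
  invisible(x)
}

#' @rdname compare_observed_expected
#' @param x A `diffsum_ks` object.
#' @param ... Unused.
#' @export
tidy.diffsum_ks <- function(x, ...) x$table

#' @rdname compare_observed_expected
#' @export
glance.diffsum_ks <- function(x, ...) {
  tibble(mean_diff_freq = x$mean_diff_freq, mean_shift = x$mean_shift,
         ks_statistic = x$ks_statistic, p_value = x$p_value,
         n_bins = x$n_bins)
}
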