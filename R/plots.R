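#' Plot observed versus mirrored-expected Diff/Sum distributions
#'
#' @param comparison A [compare_observed_expected()] result.
#' @return A ggplot.
#' @export
plot_diffsum_distribution <- function(comparison) {
  stopifnot(inherits(comparison, "diffsum_ks"))
  df <- tidy(comparison) %>%
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "distribution", values_to = "freq")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$freq,
                                   colour = .data$distribution)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Diff/Sum [(KD - CT)/(KD + CT)]", y = "Frequency",
                  colour = NULL,
                  subtitle = sprintf("mean shift %.3f, KS D = %.3f",
                                     comparison$mean_shift,
                                     comparison$ks_statistic)) +
    ggplot2::theme_minimal()
}

#' Plot a Shannon-entropy profile over |Diff/Sum| magnitude
#'
#' @param profile A [shannon_entropy_profile()] tibble.
#' @param min_n Mask magnitude bins with fewer than this many GoM+LoM
#'   regions (default 1).
#' @return A ggplot.
#' @export
plot_entropy_profile <- function(profile, min_n = 1L) {
  df <- filter(profile, .data$n >= min_n, !is.na(.data$entropy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$magnitude, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "regions") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "|Diff/Sum| magnitude",
                  y = "GoM/LoM Shannon entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Plot the average flank meta-profile per peak class
#'
#' @param flanks A [flank_profiles()] object.
#' @return A ggplot of the mean signal per position window, by peak class
#'   when classes are present.
#' @export
plot_flank_profile <- function(flanks) {
  stopifnot(inherits(flanks, "flank_profiles"))
  k <- flanks$flank %/% flanks$step
  pos <- c(seq(-k, -1), seq(1, k)) * flanks$step
  df <- as_tibble(flanks$matrix, rownames = "peak_id") %>%
    tidyr::pivot_longer(-"peak_id", names_to = "window",
                        values_to = "signal") %>%
    mutate(position = pos[match(.data$window, colnames(flanks$matrix))])
  cls <- flanks$profiles[, intersect(c("peak_id", "site_class"),
                                     names(flanks$profiles))]
  if ("site_class" %in% names(cls)) {
    df <- left_join(df, cls, by = "peak_id")
  } else {
    df$site_class <- "all"
  }
  df <- df %>%
    group_by(.data$site_class, .data$position) %>%
    summarise(mean_signal = mean(.data$signal), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_signal,
                                   colour = .data$site_class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position relative to peak edge (bp)",
                  y = "Mean MeDIP signal", colour = "class") +
    ggplot2::theme_minimal()
}

#' Scatter of parent-of-origin AIM values with category shading
#'
#' @param poo A [poo_classify()] tibble.
#' @param threshold Bias threshold drawn as guide lines (default 0.5).
#' @return A ggplot of CT versus KD parent-of-origin Diff/Sum values.
#' @export
plot_aim_scatter <- function(poo, threshold = 0.5) {
  ggplot2::ggplot(poo, ggplot2::aes(x = .data$poo_ct, y = .data$poo_kd,
                                    colour = .data$category)) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "CT (Pat - Mat)/(Pat + Mat)",
                  y = "KD (Pat - Mat)/(Pat + Mat)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pca_samples
#' @param object A `medip_pca` object.
#' @export
autoplot.medip_pca <- function(object, ...) {
  vf <- object$variance_fraction
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * vf[i])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$sample)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
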