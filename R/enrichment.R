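#' Randomly relocate intervals within a genome
#'
#' Places each interval at a uniformly random position (length preserved,
#' chromosome chosen with probability proportional to its placeable space),
#' rejecting placements that overlap an already placed interval — the
#' bedtools `shuffle` null model for motif-occurrence backgrounds.
#'
#' @param intervals Tibble of intervals to relocate.
#' @param genome_table Tibble with `chrom` and `length`.
#' @param seed Integer seed (optional).
#' @param max_tries Rejection-sampling attempts per interval before
#'   giving up.
#' @return Tibble of relocated intervals (same lengths, same order).
#' @export
shuffle_intervals <- function(intervals, genome_table, seed = NULL,
                              max_tries = 1000L) {
  check_interval_tbl(intervals, "intervals")
  check_genome_table(genome_table)
  if (nrow(intervals) == 0L) return(as_tibble(intervals))
  lens <- intervals$end - intervals$start
  if (any(lens > max(genome_table$length))) {
    abort("an interval is longer than every chromosome")
  }
  with_seed_or_not(seed, {
    placed <- vector("list", length(lens))
    occupied <- list() # per chrom: matrix of (start, end)
    for (i in seq_along(lens)) {
      L <- lens[i]
      space <- pmax(genome_table$length - L + 1, 0)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(nrow(genome_table), 1L, prob = space)
        chrom <- genome_table$chrom[ci]
        s <- sample.int(space[ci], 1L) - 1L
        occ <- occupied[[chrom]]
        if (!is.null(occ) && any(s < occ[, 2] & s + L > occ[, 1])) next
        occupied[[chrom]] <- rbind(occ, c(s, s + L))
        placed[[i]] <- tibble(chrom = chrom, start = s, end = s + L)
        ok <- TRUE
        break
      }
      if (!ok) abort("could not place interval without overlap; genome too crowded")
    }
    bind_rows(placed)
  })
}

#' Chi-square enrichment of motif-positive bins in differential bins
#'
#' For each transcription factor, tests the 2x2 association between
#' motif positivity (>= 1 hit in a bin) and differential-methylation status
#' (|Diff/Sum| above threshold versus the background bin set), with a
#' 1-degree-of-freedom chi-square (no continuity correction by default).
#'
#' @param counts Tibble with one row per TF: `tf`, `observed_hit_bins`
#'   (motif-positive differential bins), `n_differential_bins`,
#'   `background_hit_bins` (motif-positive background bins),
#'   `n_background_bins`.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @param alpha Significance level; Bonferroni correction across the tested
#'   TFs is applied alongside the uncorrected call.
#' @return Tibble with `tf`, observed/expected rates, `chi2`, `p_value`,
#'   `direction` (`"enriched"`/`"depleted"`/`"none"`), `low_count` flag
#'   (any expected cell < 1), and `significant` / `significant_bonferroni`.
#' @examples
#' tfbs_enrichment(tibble::tibble(tf = "TF1", observed_hit_bins = 30,
#'   n_differential_bins = 1000, background_hit_bins = 100,
#'   n_background_bins = 10000))
#' @export
tfbs_enrichment <- function(counts, yates = FALSE, alpha = 0.05) {
  need <- c("tf", "observed_hit_bins", "n_differential_bins",
            "background_hit_bins", "n_background_bins")
  if (!all(need %in% names(counts))) {
    abort(paste("counts needs columns:", paste(need, collapse = ", ")))
  }
  res <- purrr::pmap_dfr(counts[, need], function(tf, observed_hit_bins,
                                                  n_differential_bins,
                                                  background_hit_bins,
                                                  n_background_bins) {
    o <- c(observed_hit_bins, n_differential_bins - observed_hit_bins,
           background_hit_bins, n_background_bins - background_hit_bins)
    m <- matrix(o, nrow = 2, byrow = TRUE)
    rowt <- rowSums(m); colt <- colSums(m); N <- sum(m)
    e <- outer(rowt, colt) / N
    if (any(rowt == 0) || any(colt == 0)) {
      # degenerate margin: no association testable
      chi2 <- 0
    } else {
      adj <- if (yates) pmax(abs(m - e) - 0.5, 0) else abs(m - e)
      chi2 <- sum(adj^2 / e)
    }
    exp_rate <- colt[1] / N
    obs_rate <- observed_hit_bins / n_differential_bins
    tibble(
      tf = tf,
      observed_hit_bins = observed_hit_bins,
      n_differential_bins = n_differential_bins,
      observed_rate = obs_rate,
      expected_rate = exp_rate,
      chi2 = chi2,
      p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
      direction = dplyr::case_when(
        obs_rate > exp_rate ~ "enriched",
        obs_rate < exp_rate ~ "depleted",
        TRUE ~ "none"),
      low_count = any(e < 1)
    )
  })
  res$significant <- res$p_value <= alpha
  res$significant_bonferroni <- res$p_value <= alpha / nrow(res)
  arrange(res, dplyr::desc(.data$chi2))
}

#' Per-TF Diff/Sum of average MeDIP signal
#'
#' For each transcription factor's motif-positive bin set, computes
#' `(mean_kd - mean_ct) / (mean_kd + mean_ct)` of the normalized signals in
#' each dataset — the matrix behind the TFBS methylation-change heatmap.
#'
#' @param tf_bins Tibble with `tf` and `bin` (bin indices, one row per
#'   motif-positive bin of that TF).
#' @param signals Named list of BinSignal tibbles (one per dataset), each
#'   with `bin`, `ct`, `kd` columns.
#' @return Tibble `tf` x `dataset` with `diff_sum` of average signal
#'   (`NA` when a TF's bin set is empty or both means are zero).
#' @export
tf_diffsum_matrix <- function(tf_bins, signals) {
  stopifnot(is.list(signals), !is.null(names(signals)))
  purrr::imap_dfr(signals, function(sig, dataset) {
    tf_bins %>%
      inner_join(sig, by = "bin") %>%
      group_by(tf = .data$tf) %>%
      summarise(
        n_bins = dplyr::n(),
        mean_ct = mean(.data$ct),
        mean_kd = mean(.data$kd),
        .groups = "drop") %>%
      mutate(
        dataset = dataset,
        diff_sum = ifelse(.data$mean_ct + .data$mean_kd > 0,
                          (.data$mean_kd - .data$mean_ct) /
                            (.data$mean_kd + .data$mean_ct), NA_real_))
  }) %>%
    select("tf", "dataset", "n_bins", "mean_ct", "mean_kd", "diff_sum")
}
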