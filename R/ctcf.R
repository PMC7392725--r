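#' Classify binding-site peaks by motif and repeat content
#'
#' Partitions peaks into the two mutually exclusive classes the flank
#' analysis contrasts — repeat-free motifs (RFM: at least one motif hit, no
#' repeat overlap) and motif-free repeats (MFR: at least one repeat overlap,
#' no motif hit) — plus `mixed` (both) and `neither`. Peak centers are
#' interval midpoints (peaks are unstranded).
#'
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @param motif_hits Tibble of motif-hit intervals.
#' @param repeat_intervals Tibble of repeat-annotation intervals.
#' @return The peak tibble with `center` and `site_class`
#'   (`"RFM"`, `"MFR"`, `"mixed"`, `"neither"`) appended; any pre-existing
#'   `site_class` column is replaced.
#' @export
classify_peaks <- function(peaks, motif_hits, repeat_intervals) {
  check_interval_tbl(peaks, "peaks")
  has_motif <- overlaps_any(peaks, motif_hits)
  has_repeat <- overlaps_any(peaks, repeat_intervals)
  peaks$site_class <- NULL
  peaks %>%
    mutate(
      center = (.data$start + .data$end) %/% 2L,
      site_class = dplyr::case_when(
        has_motif & !has_repeat ~ "RFM",
        !has_motif & has_repeat ~ "MFR",
        has_motif & has_repeat ~ "mixed",
        TRUE ~ "neither"))
}

#' Peak, read and motif occurrence by methylation signal level
#'
#' Relates binding sites to the integer methylation signal level of the
#' genome: for each level `s` (default 5..30), counts (i) reads lying
#' entirely within a bin of signal level `s`, (ii) peaks whose center falls
#' in a level-`s` bin, and (iii) the motif-positive subset of those peaks.
#'
#' @param reads Tibble of binding-site read intervals.
#' @param signal Bin grid with a `count` column (raw integer MeDIP counts;
#'   from [coverage_fractional()]).
#' @param peaks Classified peak tibble (needs `center`; a peak is
#'   motif-positive when `site_class` is `"RFM"` or `"mixed"`).
#' @param levels Signal levels to profile (default 5:30).
#' @return Tibble with `level`, `n_reads`, `n_peaks`, `n_motif_peaks`.
#' @export
peaks_by_methylation_level <- function(reads, signal, peaks,
                                       levels = 5:30) {
  check_interval_tbl(signal, "signal")
  if (!"count" %in% names(signal)) abort("signal needs a count column")
  regions <- signal[signal$count %in% levels, , drop = FALSE]
  # reads entirely overlapped by (contained in) a methylated region
  read_level <- rep(NA_integer_, nrow(reads))
  if (nrow(reads) > 0 && nrow(regions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(reads),
                                        as_granges(regions),
                                        type = "within")
    read_level[S4Vectors::queryHits(hits)] <-
      regions$count[S4Vectors::subjectHits(hits)]
  }
  peak_level <- rep(NA_integer_, nrow(peaks))
  if (nrow(peaks) > 0 && nrow(regions) > 0) {
    centers <- tibble(chrom = peaks$chrom, start = peaks$center,
                      end = peaks$center + 1L)
    hits <- GenomicRanges::findOverlaps(as_granges(centers),
                                        as_granges(regions))
    peak_level[S4Vectors::queryHits(hits)] <-
      regions$count[S4Vectors::subjectHits(hits)]
  }
  motif_pos <- if ("site_class" %in% names(peaks)) {
    peaks$site_class %in% c("RFM", "mixed")
  } else rep(FALSE, nrow(peaks))
  purrr::map_dfr(levels, function(s) {
    tibble(level = s,
           n_reads = sum(read_level == s, na.rm = TRUE),
           n_peaks = sum(peak_level == s, na.rm = TRUE),
           n_motif_peaks = sum(peak_level == s & motif_pos, na.rm = TRUE))
  })
}

#' MeDIP signal in the flanks of peaks
#'
#' Sums read signal in the `flank`-wide windows immediately upstream
#' (`[start - flank, start)`) and downstream (`[end, end + flank)`) of each
#' peak — the windows never overlap the peak itself — and builds the
#' position-wise meta-profile matrix (reads assigned by midpoint to `step`
#' windows). Upstream/downstream are genome-coordinate left/right. Peaks
#' too close to a chromosome end for full flanks are flagged `clipped` and
#' should be excluded from asymmetry statistics.
#'
#' @param peaks Peak tibble with `peak_id`; `site_class` is carried through
#'   when present.
#' @param reads Read interval tibble for one sample.
#' @param genome_table Tibble with `chrom` and `length`.
#' @param flank Flank width in bases (default 10000).
#' @param step Meta-profile window width (default 200).
#' @param scale_factor Multiplicative depth normalization applied to counts
#'   (default 1).
#' @return Object of class `flank_profiles`: `profiles` tibble (`peak_id`,
#'   `upstream`, `downstream`, `asymmetry` = upstream - downstream,
#'   `clipped`) and `matrix`, the peaks x positions meta-profile whose row
#'   sums equal `upstream + downstream`.
#' @export
flank_profiles <- function(peaks, reads, genome_table, flank = 10000L,
                           step = 200L, scale_factor = 1) {
  check_interval_tbl(peaks, "peaks")
  check_genome_table(genome_table)
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- paste0("peak", seq_len(nrow(peaks)))
  }
  if (flank %% step != 0) abort("step must divide flank")
  k <- flank %/% step
  chrlen <- setNames(genome_table$length, genome_table$chrom)
  mid <- (reads$start + reads$end) %/% 2L
  mat <- matrix(0, nrow = nrow(peaks), ncol = 2L * k,
                dimnames = list(peaks$peak_id,
                                c(paste0("u", seq_len(k)),
                                  paste0("d", seq_len(k)))))
  clipped <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    clipped[i] <- p$start - flank < 0 || p$end + flank > chrlen[[p$chrom]]
    on_chrom <- reads$chrom == p$chrom
    up_sel <- on_chrom & mid >= p$start - flank & mid < p$start
    dn_sel <- on_chrom & mid >= p$end & mid < p$end + flank
    if (any(up_sel)) {
      idx <- (mid[up_sel] - (p$start - flank)) %/% step + 1L
      mat[i, seq_len(k)] <- tabulate(idx, nbins = k)
    }
    if (any(dn_sel)) {
      idx <- (mid[dn_sel] - p$end) %/% step + 1L
      mat[i, k + seq_len(k)] <- tabulate(idx, nbins = k)
    }
  }
  mat <- mat * scale_factor
  profiles <- tibble(
    peak_id = peaks$peak_id,
    upstream = unname(rowSums(mat[, seq_len(k), drop = FALSE])),
    downstream = unname(rowSums(mat[, k + seq_len(k), drop = FALSE])),
    clipped = clipped) %>%
    mutate(asymmetry = .data$upstream - .data$downstream)
  if ("site_class" %in% names(peaks)) profiles$site_class <- peaks$site_class
  structure(list(profiles = profiles, matrix = mat, flank = flank,
                 step = step), class = "flank_profiles")
}

#' @export
print.flank_profiles <- function(x, ...) {
  cat(sprintf("<flank_profiles> %d peaks, %d bp flanks in %d bp steps\n",
              nrow(x$profiles), x$flank, x$step))
  invisible(x)
}

#' Correlation of flank asymmetry between two conditions
#'
#' Pearson correlation of per-peak flank asymmetries (CT versus KD),
#' reported per peak class. A low r-squared at RFM against a high one at
#' MFR indicates that the knockdown re-randomizes the asymmetric flank of
#' motif-driven binding sites specifically.
#'
#' @param profiles_ct,profiles_kd [flank_profiles()] objects (or their
#'   `profiles` tibbles) over the same peak set.
#' @param min_peaks Classes with fewer peaks return `NA` (default 3).
#' @return Tibble with `site_class`, `n`, `r`, `r_squared`.
#' @export
asymmetry_correlation <- function(profiles_ct, profiles_kd, min_peaks = 3L) {
  get_tbl <- function(x) if (inherits(x, "flank_profiles")) x$profiles else x
  a <- get_tbl(profiles_ct)
  b <- get_tbl(profiles_kd)
  joined <- inner_join(a, select(b, "peak_id", asym_kd = "asymmetry"),
                       by = "peak_id") %>%
    filter(!.data$clipped)
  if (!"site_class" %in% names(joined)) joined$site_class <- "all"
  joined %>%
    group_by(site_class = .data$site_class) %>%
    summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= min_peaks &&
              sd(.data$asymmetry) > 0 && sd(.data$asym_kd) > 0) {
        cor(.data$asymmetry, .data$asym_kd)
      } else NA_real_,
      .groups = "drop") %>%
    mutate(r_squared = .data$r^2)
}
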