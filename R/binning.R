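#' Tile a genome into fixed-width bins
#'
#' Builds the genome-wide bin grid used for MeDIP signal aggregation
#' (0.2 kb bins by default). The terminal bin of each chromosome is
#' truncated at the chromosome end.
#'
#' @param genome_table Tibble with `chrom` and `length` columns.
#' @param bin_size Bin width in bases (default 200).
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open) and a
#'   global `bin` index.
#' @examples
#' make_windows(tibble::tibble(chrom = "chr1", length = 1000L), 200)
#' @export
make_windows <- function(genome_table, bin_size = 200L) {
  check_genome_table(genome_table)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) abort("bin_size must be >= 1")
  grid <- purrr::pmap_dfr(genome_table[, c("chrom", "length")],
    function(chrom, length) {
      starts <- seq.int(0L, length - 1L, by = bin_size)
      tibble(chrom = chrom, start = starts,
             end = pmin(starts + bin_size, as.integer(length)))
    })
  grid$bin <- seq_len(nrow(grid))
  grid
}

#' Count reads into bins with a fractional-overlap rule
#'
#' A read increments every bin covered by at least `min_overlap_fraction`
#' of the read's length (the bedtools `-f` rule: the boundary case counts).
#' With 150 bp reads on 200 bp bins a read lands in at most one bin except
#' for exact 50/50 splits, which count in both.
#'
#' @param reads Tibble of aligned read intervals (`chrom`, `start`, `end`).
#' @param grid Bin grid from [make_windows()].
#' @param min_overlap_fraction Minimum overlap as a fraction of read length
#'   (default 0.5).
#' @return The grid tibble with a `count` column. Reads on chromosomes
#'   absent from the grid are skipped with a warning; the skip count is
#'   attached as attribute `"n_skipped"`.
#' @export
coverage_fractional <- function(reads, grid, min_overlap_fraction = 0.5) {
  check_interval_tbl(reads, "reads")
  check_interval_tbl(grid, "grid")
  if (!is.numeric(min_overlap_fraction) || min_overlap_fraction <= 0 ||
      min_overlap_fraction > 1) {
    abort("min_overlap_fraction must be in (0, 1]")
  }
  if (!"bin" %in% names(grid)) grid$bin <- seq_len(nrow(grid))
  known <- reads$chrom %in% unique(grid$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warn(sprintf("%d read(s) on chromosomes absent from the grid skipped",
                 n_skipped))
    reads <- reads[known, , drop = FALSE]
  }
  counts <- integer(nrow(grid))
  if (nrow(reads) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(reads), as_granges(grid))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(reads$end[q], grid$end[s]) - pmax(reads$start[q], grid$start[s])
    len <- reads$end[q] - reads$start[q]
    keep <- ov / len >= min_overlap_fraction
    tab <- tabulate(s[keep], nbins = nrow(grid))
    counts <- as.integer(tab)
  }
  out <- grid
  out$count <- counts
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Equalize sequencing depth between two read sets
#'
#' MeDIP signals are compared after removing depth artefacts: either the
#' larger read set is randomly downsampled (without replacement) to the
#' smaller set's size, or a multiplicative scale factor is returned.
#'
#' @param reads_a,reads_b Tibbles of read intervals.
#' @param mode `"subsample"` (default) or `"scale"`.
#' @param seed Integer seed for the random subsample (optional).
#' @return For `"subsample"`: a list with `a` and `b` read tibbles of equal
#'   size. For `"scale"`: a list with `factor_a` and `factor_b`, the
#'   multiplicative factors that downscale the larger set to the smaller.
#' @export
normalize_depth <- function(reads_a, reads_b,
                            mode = c("subsample", "scale"), seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(reads_a) == 0L || nrow(reads_b) == 0L) {
    abort("both read sets must be non-empty")
  }
  na <- nrow(reads_a); nb <- nrow(reads_b)
  if (mode == "scale") {
    smaller <- min(na, nb)
    return(list(factor_a = smaller / na, factor_b = smaller / nb))
  }
  target <- min(na, nb)
  with_seed_or_not(seed, {
    a <- if (na > target) reads_a[sample.int(na, target), , drop = FALSE] else reads_a
    b <- if (nb > target) reads_b[sample.int(nb, target), , drop = FALSE] else reads_b
    list(a = as_tibble(a), b = as_tibble(b))
  })
}
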