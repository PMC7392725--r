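# Internal helpers shared across modules. All genomic coordinates in the
# package are 0-based, half-open (BED convention).

# tibble of intervals -> GRanges; GRanges is 1-based closed, so shift start.
as_granges <- function(x, genome_table = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  seqlengths <- NULL
  if (!is.null(genome_table)) {
    seqlengths <- setNames(genome_table$length, genome_table$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = seqlengths
  )
}

# indices of `x` intervals overlapping any interval in `y` (>= 1 bp)
overlaps_any <- function(x, y) {
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  if (nrow(x) == 0L) return(logical(0))
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y))
  seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
}

check_interval_tbl <- function(x, what = "interval table") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must be a data frame with chrom/start/end columns"))
  }
  if (nrow(x) > 0 && any(x$end <= x$start)) {
    abort(paste0(what, " has intervals with end <= start"))
  }
  invisible(x)
}

check_genome_table <- function(genome_table) {
  if (!is.data.frame(genome_table) ||
      !all(c("chrom", "length") %in% names(genome_table)) ||
      nrow(genome_table) == 0L) {
    abort("genome_table must be a non-empty data frame with chrom and length")
  }
  if (any(genome_table$length < 1)) abort("chromosome lengths must be >= 1")
  invisible(genome_table)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1)) {
    abort(paste0(name, " must be a probability in [0, 1]"))
  }
  invisible(x)
}

# binary Shannon entropy in bits, with 0*log2(0) := 0
binary_entropy <- function(p) {
  h <- numeric(length(p))
  for (i in seq_along(p)) {
    pi <- p[i]
    if (is.na(pi)) { h[i] <- NA_real_; next }
    terms <- c(pi, 1 - pi)
    terms <- terms[terms > 0]
    h[i] <- -sum(terms * log2(terms))
  }
  h
}

# run `expr` under a fixed RNG state without disturbing the caller's
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
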