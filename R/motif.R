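#' Build a position weight matrix from a position frequency matrix
#'
#' Converts JASPAR-style base counts to column-normalized probabilities with
#' an additive pseudocount per cell, and to log2-odds scores against a
#' background base composition.
#'
#' @param pfm 4 x width numeric count matrix with rows A, C, G, T.
#' @param tf_name Transcription factor name attached to hits.
#' @param pseudocount Added to every cell before normalization (default 0.1).
#' @param background Length-4 background probabilities (A, C, G, T);
#'   default uniform.
#' @return An object of class `pwm`: a list with `tf_name`, `width`,
#'   `prob`, `log_odds` (both 4 x width) and `background`.
#' @examples
#' pwm_from_pfm(matrix(c(8, 2, 0, 0), 4, 1,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)), "toy")
#' @export
pwm_from_pfm <- function(pfm, tf_name = "motif", pseudocount = 0.1,
                         background = rep(0.25, 4)) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L || ncol(pfm) < 1L) abort("pfm must be 4 x width")
  if (any(pfm < 0)) abort("pfm counts must be non-negative")
  if (any(colSums(pfm) == 0)) abort("pfm has an all-zero column")
  check_probability(background, "background")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    abort("background must be 4 probabilities summing to 1")
  }
  prob <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(
    tf_name = tf_name,
    width = ncol(prob),
    prob = prob,
    log_odds = log2(prob / background),
    background = setNames(background, c("A", "C", "G", "T"))
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_name, ", width ", x$width,
      ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm A [pwm_from_pfm()] object.
#' @return Single string: the most probable base at each position.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$prob, 2, which.max)], collapse = "")
}

# reverse-complement PWM: scanning the forward strand with it scores the
# reverse strand
pwm_revcomp <- function(pwm) {
  flip <- function(m) m[c(4, 3, 2, 1), rev(seq_len(ncol(m))), drop = FALSE]
  out <- pwm
  out$prob <- flip(pwm$prob)
  out$log_odds <- flip(pwm$log_odds)
  rownames(out$prob) <- rownames(out$log_odds) <- c("A", "C", "G", "T")
  out
}

# log2-odds scores rounded onto the integer lattice used by both the
# p-value table and the scanner, so the two agree exactly
pwm_int_scores <- function(pwm, granularity) {
  round(pwm$log_odds / granularity)
}

#' Exact score-to-p-value table for a PWM
#'
#' Computes the full null distribution of the (discretized) log-odds score
#' under the background model by dynamic programming over positions, as in
#' FIMO. `p(s) = P(score >= s)` for a random background word of the motif's
#' width; monotone non-increasing in `s`.
#'
#' @param pwm A [pwm_from_pfm()] object.
#' @param granularity Score lattice step in log2-odds units (default 0.01).
#'   Scores are rounded to multiples of this step; the scanner uses the same
#'   lattice, so lookups are exact.
#' @return Object of class `pwm_pvalue_table`: list with integer `scores`,
#'   their null probabilities `prob`, tail `pvalue`, and the `granularity`.
#' @export
score_pvalue_table <- function(pwm, granularity = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  lo_int <- pwm_int_scores(pwm, granularity)
  bg <- pwm$background
  w <- pwm$width
  mins <- apply(lo_int, 2, min)
  maxs <- apply(lo_int, 2, max)
  dist <- 1
  offset0 <- 0
  for (j in seq_len(w)) {
    len <- length(dist)
    new <- numeric(len + (maxs[j] - mins[j]))
    for (b in 1:4) {
      shift <- lo_int[b, j] - mins[j]
      idx <- seq_len(len) + shift
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    offset0 <- offset0 + mins[j]
  }
  scores <- offset0 + seq_along(dist) - 1
  keep <- dist > 0
  structure(list(
    scores = scores[keep],
    prob = dist[keep],
    pvalue = rev(cumsum(rev(dist)))[keep],
    granularity = granularity,
    tf_name = pwm$tf_name
  ), class = "pwm_pvalue_table")
}

#' Look up p-values for scores in a p-value table
#'
#' @param table A [score_pvalue_table()] object.
#' @param score Numeric log2-odds scores (rounded onto the table's lattice).
#' @return `P(null score >= score)` for each input score.
#' @export
pwm_score_pvalue <- function(table, score) {
  stopifnot(inherits(table, "pwm_pvalue_table"))
  s <- round(score / table$granularity)
  # pvalue is non-increasing in score; find the smallest table score >= s
  idx <- findInterval(s - 1, table$scores) + 1L
  out <- numeric(length(s))
  out[idx > length(table$scores)] <- 0
  inb <- idx <= length(table$scores)
  out[inb] <- table$pvalue[idx[inb]]
  out[s <= table$scores[1]] <- 1
  out
}

# symmetrize a background over complementary bases so one p-value table
# serves both strands
symmetrize_background <- function(bg) {
  at <- (bg[1] + bg[4]) / 2
  cg <- (bg[2] + bg[3]) / 2
  setNames(c(at, cg, cg, at), c("A", "C", "G", "T"))
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# background base frequencies of a sequence set (strand-symmetrized)
sequence_background <- function(sequences) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in sequences) {
    v <- encode_dna(s)
    tab <- tabulate(v, nbins = 4)
    counts <- counts + tab
  }
  if (sum(counts) == 0) return(setNames(rep(0.25, 4), c("A", "C", "G", "T")))
  symmetrize_background(counts / sum(counts))
}

#' Scan sequences for PWM matches (FIMO-style)
#'
#' Scores every window on both strands against the PWM and keeps windows
#' whose exact null p-value is at or below `threshold`. Windows containing
#' non-ACGT characters are skipped. Hit coordinates are reported on the
#' forward strand, 0-based half-open.
#'
#' @param sequences Named character vector (chromosome name -> sequence).
#' @param pwm A [pwm_from_pfm()] object.
#' @param threshold Hit p-value threshold; 1e-4 is the permissive default,
#'   1e-6 the stringent genome-wide setting.
#' @param background `"sequence"` (0-order composition estimated from the
#'   scanned sequences, strand-symmetrized; default), `"uniform"`, or
#'   `"pwm"` (keep the PWM's own background).
#' @param granularity Score lattice step passed to [score_pvalue_table()].
#' @return Tibble of hits: `chrom`, `start`, `end`, `tf`, `strand`,
#'   `score` (log2-odds), `pvalue`.
#' @export
scan_sequences <- function(sequences, pwm, threshold = 1e-4,
                           background = c("sequence", "uniform", "pwm"),
                           granularity = 0.01) {
  stopifnot(inherits(pwm, "pwm"), is.character(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  background <- match.arg(background)
  bg <- switch(background,
    sequence = sequence_background(sequences),
    uniform = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
    pwm = symmetrize_background(pwm$background))
  pwm <- structure(modifyList(pwm, list(
    background = bg, log_odds = log2(pwm$prob / bg))), class = "pwm")
  tbl <- score_pvalue_table(pwm, granularity)
  lo_f <- pwm_int_scores(pwm, granularity)
  lo_r <- pwm_int_scores(pwm_revcomp(pwm), granularity)
  w <- pwm$width
  hits <- purrr::imap(sequences, function(seq, chrom) {
    v <- encode_dna(seq)
    n <- length(v) - w + 1L
    if (n < 1L) return(NULL)
    sc_f <- numeric(n)
    sc_r <- numeric(n)
    for (j in seq_len(w)) {
      idx <- v[j:(j + n - 1L)]
      sc_f <- sc_f + lo_f[cbind(idx, j)]
      sc_r <- sc_r + lo_r[cbind(idx, j)]
    }
    per_strand <- function(sc, strand) {
      ok <- !is.na(sc)
      p <- rep(NA_real_, length(sc))
      p[ok] <- pwm_score_pvalue(tbl, sc[ok] * tbl$granularity)
      keep <- which(ok & p <= threshold)
      if (length(keep) == 0L) return(NULL)
      tibble(chrom = chrom, start = keep - 1L, end = keep - 1L + w,
             tf = pwm$tf_name, strand = strand,
             score = sc[keep] * tbl$granularity, pvalue = p[keep])
    }
    bind_rows(per_strand(sc_f, "+"), per_strand(sc_r, "-"))
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  tf = character(), strand = character(),
                  score = numeric(), pvalue = numeric())
  }
  arrange(out, .data$chrom, .data$start, .data$strand)
}
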