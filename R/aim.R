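#' Tally reference and alternate alleles at SNP sites
#'
#' Counts, per site and per sample, the reads carrying the reference and
#' alternate base at the SNP position. Bases matching neither allele
#' (sequencing-error analog) are tallied separately and excluded from both
#' counts. Sites below the minimum informative coverage
#' (`n_ref + n_alt < min_coverage`) are dropped for that sample.
#'
#' @param bases Tibble of observed bases per read per site: `sample`,
#'   `chrom`, `pos`, `base`.
#' @param sites Tibble of variant sites: `chrom`, `pos`, `ref`, `alt`.
#' @param min_coverage Minimum informative reads per sample per site
#'   (default 5).
#' @return Tibble with `chrom`, `pos`, `sample`, `n_ref`, `n_alt`,
#'   `n_other`, `coverage` (= n_ref + n_alt).
#' @export
pileup_allele_counts <- function(bases, sites, min_coverage = 5L) {
  need <- c("sample", "chrom", "pos", "base")
  if (!all(need %in% names(bases))) {
    abort("bases needs sample, chrom, pos and base columns")
  }
  bases %>%
    inner_join(select(sites, "chrom", "pos", "ref", "alt"),
               by = c("chrom", "pos")) %>%
    group_by(.data$chrom, .data$pos, .data$sample) %>%
    summarise(
      n_ref = sum(.data$base == .data$ref),
      n_alt = sum(.data$base == .data$alt),
      n_other = sum(.data$base != .data$ref & .data$base != .data$alt),
      .groups = "drop") %>%
    mutate(coverage = .data$n_ref + .data$n_alt) %>%
    filter(.data$coverage >= min_coverage)
}

#' Allelic imbalance in methylation (AIM) per SNP
#'
#' For each site covered in both conditions, computes the Diff/Sum of
#' allele counts, `(n_ref - n_alt) / (n_ref + n_alt)`, in CT and KD.
#' When the maternal/paternal identity of the alleles is known, the
#' parent-of-origin value `(pat - mat) / (pat + mat)` is computed by
#' relabeling.
#'
#' @param counts Output of [pileup_allele_counts()] with samples `"CT"` and
#'   `"KD"`.
#' @param sites Variant sites; if `maternal` and `paternal` allele columns
#'   are present, parent-of-origin values are added.
#' @param sign_order `"ref_minus_alt"` (default) or `"alt_minus_ref"`; the
#'   source data do not fix the order, and the two choices give
#'   mirror-image distributions. Recorded in the `sign_order` attribute.
#' @return Tibble with `chrom`, `pos`, per-sample counts, `aim_ct`,
#'   `aim_kd` and (when phased) `poo_ct`, `poo_kd`; one row per site
#'   covered in both samples.
#' @export
aim_values <- function(counts, sites, sign_order = c("ref_minus_alt",
                                                     "alt_minus_ref")) {
  sign_order <- match.arg(sign_order)
  s <- if (sign_order == "ref_minus_alt") 1 else -1
  wide <- counts %>%
    filter(.data$sample %in% c("CT", "KD")) %>%
    select("chrom", "pos", "sample", "n_ref", "n_alt") %>%
    tidyr::pivot_wider(names_from = "sample",
                       values_from = c("n_ref", "n_alt")) %>%
    tidyr::drop_na()
  out <- wide %>%
    mutate(
      aim_ct = s * (.data$n_ref_CT - .data$n_alt_CT) /
        (.data$n_ref_CT + .data$n_alt_CT),
      aim_kd = s * (.data$n_ref_KD - .data$n_alt_KD) /
        (.data$n_ref_KD + .data$n_alt_KD))
  if (all(c("maternal", "paternal") %in% names(sites))) {
    out <- out %>%
      inner_join(select(sites, "chrom", "pos", "ref", "alt", "maternal",
                        "paternal"),
                 by = c("chrom", "pos")) %>%
      mutate(
        # (pat - mat) / (pat + mat): +aim when the paternal allele is ref
        flip = ifelse(.data$paternal == .data$ref, 1, -1) * s,
        poo_ct = .data$flip * (.data$n_ref_CT - .data$n_alt_CT) /
          (.data$n_ref_CT + .data$n_alt_CT),
        poo_kd = .data$flip * (.data$n_ref_KD - .data$n_alt_KD) /
          (.data$n_ref_KD + .data$n_alt_KD)) %>%
      select(-"flip")
  }
  attr(out, "sign_order") <- sign_order
  out
}

#' Obligate-heterozygous loci from parental genotypes
#'
#' Retains loci where the two parents are homozygous for different alleles,
#' so the child can only be heterozygous and every read's parent of origin
#' is identified by its allele. Loci where a parental allele matches
#' neither `ref` nor `alt` are flagged inconsistent and dropped.
#'
#' @param genotypes Tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `maternal_gt`, `paternal_gt` (genotypes like `"A/A"` or `"AG"`).
#' @return Tibble of retained sites with `maternal` and `paternal` allele
#'   columns. Inconsistent-call sites are reported in attribute
#'   `"n_inconsistent"`.
#' @export
obligate_het_loci <- function(genotypes) {
  alleles <- function(gt) {
    stringr::str_split_fixed(gsub("[/|]", "", gt), "", 3)[, 1:2, drop = FALSE]
  }
  m <- alleles(genotypes$maternal_gt)
  p <- alleles(genotypes$paternal_gt)
  m_hom <- m[, 1] == m[, 2]
  p_hom <- p[, 1] == p[, 2]
  keep <- m_hom & p_hom & m[, 1] != p[, 1]
  out <- genotypes[keep, , drop = FALSE] %>%
    mutate(maternal = m[keep, 1], paternal = p[keep, 1])
  consistent <- (out$maternal == out$ref | out$maternal == out$alt) &
    (out$paternal == out$ref | out$paternal == out$alt)
  n_bad <- sum(!consistent)
  if (n_bad > 0) {
    warn(sprintf("%d obligate-het locus/loci with parental alleles outside ref/alt dropped",
                 n_bad))
  }
  out <- out[consistent, , drop = FALSE]
  attr(out, "n_inconsistent") <- n_bad
  out
}

#' Classify parent-of-origin methylation categories
#'
#' Maps each locus's CT and KD parent-of-origin Diff/Sum values onto the
#' five mutually exclusive, exhaustive categories. Values within
#' `[-threshold, +threshold]` (inclusive) are heterozygous/biallelic; a
#' value beyond the threshold is a monoallelic bias toward the paternal
#' (positive) or maternal (negative) allele.
#'
#' * `biallelic_stable`: biallelic in CT and KD
#' * `monoallelic_stable`: same parental bias in CT and KD
#' * `loss_of_monoallelic`: biased in CT, biallelic in KD
#' * `gain_of_monoallelic`: biallelic in CT, biased in KD
#' * `allelic_flip`: opposite parental bias in CT and KD
#'
#' @param records Tibble with `poo_ct` and `poo_kd` (see [aim_values()]).
#' @param threshold Bias threshold (default 0.5, inclusive interval).
#' @return `records` with `category` and `biased_parent` appended
#'   (`"maternal"`/`"paternal"` for biased categories, a `"x_to_y"` label
#'   for flips, `NA` for stable biallelic).
#' @export
poo_classify <- function(records, threshold = 0.5) {
  if (!all(c("poo_ct", "poo_kd") %in% names(records))) {
    abort("records needs poo_ct and poo_kd columns")
  }
  m <- function(x) ifelse(abs(x) > threshold, sign(x), 0)
  parent <- function(s) ifelse(s > 0, "paternal", "maternal")
  mct <- m(records$poo_ct)
  mkd <- m(records$poo_kd)
  records %>%
    mutate(
      category = dplyr::case_when(
        mct == 0 & mkd == 0 ~ "biallelic_stable",
        mct != 0 & mct == mkd ~ "monoallelic_stable",
        mct != 0 & mkd == 0 ~ "loss_of_monoallelic",
        mct == 0 & mkd != 0 ~ "gain_of_monoallelic",
        TRUE ~ "allelic_flip"),
      biased_parent = dplyr::case_when(
        .data$category %in% c("monoallelic_stable", "loss_of_monoallelic") ~
          parent(mct),
        .data$category == "gain_of_monoallelic" ~ parent(mkd),
        .data$category == "allelic_flip" ~
          paste0(parent(mct), "_to_", parent(mkd)),
        TRUE ~ NA_character_))
}

#' Shift in parental allele contributions between conditions
#'
#' Per locus and sample, computes the percent-maternal minus
#' percent-paternal contribution to the methylation-enriched reads
#' (in \[-100, +100\]), histograms each sample, and reports the bin-wise
#' difference of normalized frequencies (KD - CT). Peaks at the extremes of
#' the difference indicate an increase of fully monoallelic methylation
#' after knockdown.
#'
#' @param records [aim_values()] output with parental phase (`poo_ct`,
#'   `poo_kd` present imply `maternal`/`paternal` columns exist).
#' @param width Histogram bin width in percentage points (default 20).
#' @return Tibble with `mid`, `freq_ct`, `freq_kd` (normalized), `delta`.
#' @export
parental_contribution_delta <- function(records, width = 20) {
  if (!all(c("poo_ct", "poo_kd") %in% names(records))) {
    abort("records needs parent-of-origin values (poo_ct, poo_kd)")
  }
  # %Mat - %Pat = -100 * poo
  pct_ct <- -100 * records$poo_ct
  pct_kd <- -100 * records$poo_kd
  kmax <- round(100 / width)
  grid <- seq(-kmax, kmax)
  h <- function(x) {
    f <- as.integer(table(factor(round(x / width), levels = grid)))
    f / sum(f)
  }
  tibble(mid = round(grid * width, 10), freq_ct = h(pct_ct),
         freq_kd = h(pct_kd)) %>%
    mutate(delta = .data$freq_kd - .data$freq_ct)
}

#' CpG dinucleotides inside versus outside a motif span within a read
#'
#' Counts `"CG"` dinucleotides in the motif substring of each read and in
#' the flanking remainder (left and right pieces counted separately, so a
#' dinucleotide straddling the motif boundary is counted in neither).
#'
#' @param read_seq Character vector of read sequences.
#' @param motif_start,motif_end Motif span within each read, 0-based
#'   half-open.
#' @return Tibble with `inside` and `outside` CpG counts per read.
#' @export
cpg_in_motif <- function(read_seq, motif_start, motif_end) {
  stopifnot(length(motif_start) == length(read_seq),
            length(motif_end) == length(read_seq))
  count_cg <- function(s) {
    if (nchar(s) < 2) return(0L)
    stringr::str_count(s, stringr::fixed("CG"))
  }
  inside <- purrr::pmap_int(list(read_seq, motif_start, motif_end),
    function(s, a, b) count_cg(substr(s, a + 1L, b)))
  outside <- purrr::pmap_int(list(read_seq, motif_start, motif_end),
    function(s, a, b) {
      count_cg(substr(s, 1L, a)) + count_cg(substr(s, b + 1L, nchar(s)))
    })
  tibble(inside = inside, outside = outside)
}
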