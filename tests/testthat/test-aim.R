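toy_sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                            ref = c("A", "C", "G"), alt = c("G", "T", "A"))

bases_for <- function(pos, sample, bases) {
  tibble::tibble(name = paste0(sample, "_r", seq_along(bases)),
                 sample = sample, chrom = "chr1", pos = pos, base = bases)
}

test_that("pileup counts ref and alt reads and applies the coverage floor", {
  b <- dplyr::bind_rows(
    bases_for(100L, "CT", c(rep("A", 9), "G")),          # 9 ref + 1 alt
    bases_for(200L, "CT", c(rep("C", 3), "T")),          # coverage 4 -> out
    bases_for(300L, "CT", c(rep("G", 5))),               # 5 + 0 -> in
    bases_for(100L, "KD", c(rep("A", 4), "G", "C")))     # other base excluded
  counts <- pileup_allele_counts(b, toy_sites, min_coverage = 5)
  ct100 <- dplyr::filter(counts, pos == 100, sample == "CT")
  expect_equal(c(ct100$n_ref, ct100$n_alt), c(9L, 1L))
  expect_equal(nrow(dplyr::filter(counts, pos == 200)), 0)
  ct300 <- dplyr::filter(counts, pos == 300, sample == "CT")
  expect_equal(c(ct300$n_ref, ct300$n_alt), c(5L, 0L))
  kd100 <- dplyr::filter(counts, pos == 100, sample == "KD")
  expect_equal(c(kd100$n_ref, kd100$n_alt, kd100$n_other), c(4L, 1L, 1L))
})

test_that("AIM is the Diff/Sum of allele counts, relabeled for parent of origin", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = rep(c(100L, 200L), each = 2),
    sample = rep(c("CT", "KD"), 2),
    n_ref = c(9L, 5L, 8L, 2L), n_alt = c(1L, 5L, 2L, 8L))
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                          ref = c("A", "C"), alt = c("G", "T"),
                          maternal = c("G", "C"), paternal = c("A", "T"))
  aim <- aim_values(counts, sites)
  expect_equal(aim$aim_ct, c(0.8, 0.6))
  expect_equal(aim$aim_kd, c(0.0, -0.6))
  # site 100: paternal = ref, so poo = +aim; site 200: paternal = alt
  expect_equal(aim$poo_ct, c(0.8, -0.6))
  expect_equal(aim$poo_kd, c(0.0, 0.6))
  # the opposite sign convention mirrors every value
  aim2 <- aim_values(counts, sites, sign_order = "alt_minus_ref")
  expect_equal(aim2$aim_ct, -aim$aim_ct)
  expect_equal(aim2$poo_ct, -aim$poo_ct)
})

test_that("obligate heterozygous loci require homozygous discordant parents", {
  g <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L, 3L, 4L),
    ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "C"),
    maternal_gt = c("A/A", "A/A", "A/G", "T/T"),
    paternal_gt = c("G/G", "A/A", "G/G", "G/G"))
  expect_warning(het <- obligate_het_loci(g), "outside ref/alt")
  # pos 1: kept with Mat = ref, Pat = alt; pos 2 concordant; pos 3 het
  # mother; pos 4 parental allele T matches neither ref nor alt
  expect_equal(het$pos, 1L)
  expect_equal(het$maternal, "A")
  expect_equal(het$paternal, "G")
  expect_equal(attr(het, "n_inconsistent"), 1L)
})

test_that("parent-of-origin classification is exhaustive and mutually exclusive", {
  grid <- expand.grid(poo_ct = seq(-1, 1, 0.05), poo_kd = seq(-1, 1, 0.05))
  cl <- poo_classify(tibble::as_tibble(grid), threshold = 0.5)
  expect_false(any(is.na(cl$category)))
  expect_setequal(unique(cl$category),
                  c("biallelic_stable", "monoallelic_stable",
                    "loss_of_monoallelic", "gain_of_monoallelic",
                    "allelic_flip"))
  # worked cases, including the inclusive +-0.5 boundary
  one <- function(ct, kd) poo_classify(tibble::tibble(poo_ct = ct,
                                                      poo_kd = kd))
  expect_equal(one(0.2, -0.3)$category, "biallelic_stable")
  expect_equal(one(0.5, -0.5)$category, "biallelic_stable")
  expect_equal(one(0.0, 0.9)$category, "gain_of_monoallelic")
  expect_equal(one(0.0, 0.9)$biased_parent, "paternal")
  expect_equal(one(-0.9, 0.0)$category, "loss_of_monoallelic")
  expect_equal(one(-0.9, 0.0)$biased_parent, "maternal")
  expect_equal(one(0.9, 0.9)$category, "monoallelic_stable")
  expect_equal(one(-0.9, 0.9)$category, "allelic_flip")
  expect_equal(one(-0.9, 0.9)$biased_parent, "maternal_to_paternal")
})

test_that("relabeling maternal and paternal swaps biases but preserves category counts", {
  set.seed(9)
  rec <- tibble::tibble(poo_ct = runif(300, -1, 1),
                        poo_kd = runif(300, -1, 1))
  a <- poo_classify(rec)
  b <- poo_classify(dplyr::mutate(rec, poo_ct = -poo_ct, poo_kd = -poo_kd))
  expect_equal(table(a$category), table(b$category))
  mono <- a$category == "monoallelic_stable"
  expect_true(all(a$biased_parent[mono] != b$biased_parent[mono]))
})

test_that("parental contribution differences histogram to zero for identical conditions", {
  rec <- tibble::tibble(poo_ct = c(0, -1, 0.5), poo_kd = c(0, -1, 0.5))
  d <- parental_contribution_delta(rec, width = 20)
  expect_equal(d$delta, rep(0, nrow(d)))
  expect_equal(sum(d$freq_ct), 1)
  # Mat = 5, Pat = 5 -> %Mat - %Pat = 0; Mat = 10, Pat = 0 -> +100
  rec2 <- tibble::tibble(poo_ct = c(0, -1), poo_kd = c(0, -1))
  d2 <- parental_contribution_delta(rec2, width = 20)
  expect_equal(d2$freq_ct[d2$mid == 0], 0.5)
  expect_equal(d2$freq_ct[d2$mid == 100], 0.5)
})

test_that("CpG counting separates motif-internal from flanking dinucleotides", {
  res <- cpg_in_motif("TTGGTACCAT", 0L, 10L)
  expect_equal(res$inside, 0L)
  res2 <- cpg_in_motif("ACGCGT", 0L, 6L)
  expect_equal(res2$inside, 2L)
  # read CGAA|TTTT|CG with the motif spanning the TTTT block
  res3 <- cpg_in_motif("CGAATTTTCG", 4L, 8L)
  expect_equal(res3$inside, 0L)
  expect_equal(res3$outside, 2L)
})

test_that("planted allelic categories are recovered from simulated reads", {
  cfg <- small_cfg(seed = 31L, n_snps = 120L,
                   n_reads_ct = 40000L, n_reads_kd = 40000L)
  sim <- simulate_medip(cfg)
  het <- obligate_het_loci(sim$genotypes)
  counts <- pileup_allele_counts(sim$bases, het, min_coverage = 5)
  aim <- aim_values(counts, het)
  poo <- poo_classify(aim)
  joined <- dplyr::inner_join(
    poo, dplyr::select(sim$truth$snps, chrom, pos, category_true = category),
    by = c("chrom", "pos"))
  # restrict to well-covered loci where classification noise is negligible
  strong <- dplyr::filter(joined,
                          n_ref_CT + n_alt_CT >= 20,
                          n_ref_KD + n_alt_KD >= 20)
  expect_gt(nrow(strong), 30)
  expect_gt(mean(strong$category == strong$category_true), 0.9)
})
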