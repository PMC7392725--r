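#' Configuration for the end-to-end analysis pipeline
#'
#' Collects the stage parameters: 0.2 kb bins, a minimum combined CT+KD
#' signal of 3 reads, a differential-bin threshold of |Diff/Sum| > 0.2, a
#' stringent motif p-value of 1e-6, a minimum AIM coverage of 5 reads per
#' sample, a parent-of-origin bias threshold of 0.5, and 10 kb flanks.
#'
#' @param sim A [sim_config()] describing the synthetic input (its seed is
#'   overridden by `seed`).
#' @param bin_size Analysis bin width in bases.
#' @param min_combined Minimum combined CT+KD reads per bin.
#' @param min_either Minimum reads in at least one sample (entropy filter).
#' @param diffsum_threshold |Diff/Sum| above which a bin is differential.
#' @param motif_pvalue Motif-hit p-value threshold.
#' @param min_coverage Minimum per-sample informative coverage for AIM.
#' @param poo_threshold Parent-of-origin bias threshold.
#' @param flank Flank width for peak profiles, in bases.
#' @param histogram_width Diff/Sum histogram interval.
#' @param seed Pipeline seed driving every random stage.
#' @param out_dir Output directory for TSV/JSON reports (`NULL` = return
#'   results only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bin_size = 200L,
                            min_combined = 3L,
                            min_either = 2L,
                            diffsum_threshold = 0.2,
                            motif_pvalue = 1e-6,
                            min_coverage = 5L,
                            poo_threshold = 0.5,
                            flank = 10000L,
                            histogram_width = 0.1,
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "sim_config"))
  cfg$sim$seed <- as.integer(seed)
  cfg$sim$bin_size <- as.integer(bin_size)
  cfg$sim$flank <- as.integer(flank)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate, bin and normalize,
#' Diff/Sum statistics, entropy and density profiles, motif scanning and
#' TFBS enrichment, peak classification with flank asymmetry, and allelic
#' imbalance with parent-of-origin classification — and returns every
#' stage's tables plus a manifest of parameters and record counts.
#' Deterministic for a fixed seed. When `out_dir` is set, each table is
#' written as TSV and the manifest as JSON.
#'
#' @param config A [pipeline_config()] object.
#' @param pwms Optional PWM list for scanning (default: bundled synthetic
#'   motif set; the first PWM is the planted TF).
#' @return A list of stage results (`sim`, `signals`, `diffsum`,
#'   `comparison`, `entropy`, `density`, `correlation`, `hits`,
#'   `enrichment`, `tf_matrix`, `peaks`, `flanks_ct`, `flanks_kd`,
#'   `asymmetry`, `aim`, `poo`, `contribution_delta`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), pwms = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pwms <- pwms %||% default_sim_pwms()
  log_stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] %d records in, %d out", name, n_in, n_out))
    tibble(stage = name, n_in = n_in, n_out = n_out)
  }
  stages <- list()

  # 1. simulate
  sim <- simulate_medip(config$sim, pwms)
  grid <- sim$truth$grid
  stages$simulate <- log_stage("simulate",
                               config$sim$n_reads_ct + config$sim$n_reads_kd,
                               nrow(sim$reads_ct) + nrow(sim$reads_kd))

  # 2. depth normalization + binning
  norm <- normalize_depth(sim$reads_ct, sim$reads_kd, mode = "subsample",
                          seed = config$seed + 10L)
  cov_ct <- coverage_fractional(norm$a, grid)
  cov_kd <- coverage_fractional(norm$b, grid)
  signals <- grid %>%
    mutate(ct = cov_ct$count, kd = cov_kd$count)
  stages$binning <- log_stage("binning", nrow(norm$a) + nrow(norm$b),
                              nrow(signals))

  # 3. Diff/Sum
  records <- compute_diff_sum(signals, config$min_combined)
  observed <- diffsum_histogram(records, config$histogram_width)
  expected <- mirrored_expected(observed)
  comparison <- compare_observed_expected(observed, expected)
  stages$diffsum <- log_stage("diffsum", nrow(signals), nrow(records))

  # 4. entropy + density + multiscale correlation
  entropy <- shannon_entropy_profile(records, config$histogram_width,
                                     config$min_combined, config$min_either)
  density <- methylation_bin_density(
    bind_rows(tibble(sample = "CT", count = signals$ct),
              tibble(sample = "KD", count = signals$kd)))
  correlation <- multiscale_correlation(norm$a, norm$b,
                                        sim$truth$genome_table)
  stages$entropy <- log_stage("entropy", nrow(records), nrow(entropy))

  # 5. motif scan + enrichment
  hits <- purrr::map_dfr(pwms, function(pw) {
    scan_sequences(sim$sequences, pw, threshold = config$motif_pvalue)
  })
  covered <- records # bins passing the combined filter
  differential <- filter(records,
                         abs(.data$diff_sum) > config$diffsum_threshold)
  tf_bin_sets <- purrr::map_dfr(unique(hits$tf), function(tfn) {
    h <- filter(hits, .data$tf == tfn)
    tibble(tf = tfn, bin = grid$bin[overlaps_any(grid, h)])
  })
  enrich_counts <- purrr::map_dfr(names(pwms), function(tfn) {
    bins_tf <- tf_bin_sets$bin[tf_bin_sets$tf == tfn]
    tibble(tf = tfn,
           observed_hit_bins = sum(differential$bin %in% bins_tf),
           n_differential_bins = nrow(differential),
           background_hit_bins = sum(covered$bin %in% bins_tf),
           n_background_bins = nrow(covered))
  })
  enrichment <- tfbs_enrichment(enrich_counts)
  tf_matrix <- tf_diffsum_matrix(
    filter(tf_bin_sets, .data$bin %in% covered$bin),
    list(simulated = select(records, "bin", "ct", "kd")))
  stages$motif_enrichment <- log_stage("motif_enrichment", nrow(hits),
                                       nrow(enrichment))

  # 6. peak classes + flank asymmetry
  peaks <- classify_peaks(sim$truth$peaks, hits, sim$truth$repeats)
  flanks_ct <- flank_profiles(peaks, norm$a, sim$truth$genome_table,
                              flank = config$flank)
  flanks_kd <- flank_profiles(peaks, norm$b, sim$truth$genome_table,
                              flank = config$flank)
  asymmetry <- asymmetry_correlation(flanks_ct, flanks_kd)
  stages$ctcf_sites <- log_stage("ctcf_sites", nrow(peaks), nrow(asymmetry))

  # 7. allelic imbalance + parent of origin
  norm_names <- c(norm$a$name, norm$b$name)
  bases_kept <- filter(sim$bases, .data$name %in% norm_names)
  het <- obligate_het_loci(sim$genotypes)
  counts <- pileup_allele_counts(bases_kept, het, config$min_coverage)
  aim <- aim_values(counts, het)
  poo <- poo_classify(aim, config$poo_threshold)
  contribution_delta <- if (nrow(poo) > 0) {
    parental_contribution_delta(poo)
  } else NULL
  stages$allelic_imbalance <- log_stage("allelic_imbalance", nrow(counts),
                                        nrow(poo))

  manifest <- list(
    package = "stochmeth",
    version = as.character(utils::packageVersion("stochmeth")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    sim_parameters = unclass(config$sim),
    stages = bind_rows(stages))

  result <- list(sim = sim, signals = signals, diffsum = records,
                 observed = observed, expected = expected,
                 comparison = comparison, entropy = entropy,
                 density = density, correlation = correlation, hits = hits,
                 enrichment = enrichment, tf_matrix = tf_matrix,
                 peaks = peaks, flanks_ct = flanks_ct, flanks_kd = flanks_kd,
                 asymmetry = asymmetry, aim = aim, poo = poo,
                 contribution_delta = contribution_delta,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  invisible(result)
}

# write each tabular stage result as TSV plus the JSON manifest
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    diffsum = result$diffsum,
    diffsum_histogram = tidy(result$comparison),
    entropy_profile = result$entropy,
    bin_density = result$density,
    correlation = result$correlation,
    motif_hits = result$hits,
    enrichment = result$enrichment,
    tf_diffsum_matrix = result$tf_matrix,
    peak_classes = result$peaks,
    flank_asymmetry_ct = result$flanks_ct$profiles,
    flank_asymmetry_kd = result$flanks_kd$profiles,
    asymmetry_correlation = result$asymmetry,
    poo_records = result$poo,
    parental_contribution_delta = result$contribution_delta)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  jsonlite::write_json(
    c(result$manifest[c("package", "version", "seed", "parameters",
                        "sim_parameters")],
      list(stages = result$manifest$stages,
           summary = list(
             mean_shift = result$comparison$mean_shift,
             ks_statistic = result$comparison$ks_statistic,
             category_counts = as.list(table(result$poo$category))))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
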