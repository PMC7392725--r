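#' Configuration for the synthetic MeDIP simulator
#'
#' Bundles every parameter of the diploid two-condition (CT/KD) MeDIP
#' simulation. The defaults define the reference simulation used throughout
#' the package's tests: a dominant symmetric stochastic gain/loss component,
#' a deterministic directional component restricted to planted TFBS bins,
#' peaks of two classes (repeat-free motif, RFM; motif-free repeat, MFR)
#' with planted flank-methylation asymmetry, and phased heterozygous SNPs
#' with planted allelic-methylation categories.
#'
#' @param genome_length Length of each chromosome in bases; must be a
#'   multiple of `bin_size`.
#' @param n_chromosomes Number of chromosomes.
#' @param bin_size Methylation-model resolution in bases (default 200).
#' @param read_length Fixed single-end read length (default 150).
#' @param n_reads_ct,n_reads_kd Reads sampled per condition.
#' @param baseline_range Per-bin baseline methylation probability range
#'   (uniform draw), before the domain multiplier.
#' @param domain_size Length of methylation domains; each domain gets one
#'   multiplier so baseline methylation covaries at the multi-kilobase
#'   scale, as in real methylomes.
#' @param domain_range Uniform range of the domain multiplier.
#' @param stochastic_flip_prob Per-bin probability that the KD methylation
#'   level flips stochastically (default 0.3).
#' @param stochastic_fold_range Fold-change range of a stochastic flip. A
#'   flipped bin's two levels `(m, m * f)` are assigned to (CT, KD) in
#'   random order — an exchangeable reassignment, so gains and losses of
#'   methylation are symmetric at every Diff/Sum magnitude.
#' @param deterministic_shift Signed methylation-probability delta added to
#'   KD at planted TFBS bins (default +0.4).
#' @param n_tfbs_planted Number of bins carrying an embedded motif consensus
#'   and the deterministic shift (default 50).
#' @param n_rfm_peaks,n_mfr_peaks Peak counts per class (default 10 each).
#' @param peak_width Peak width in bases (default 400).
#' @param flank Flank length for the planted asymmetry, in bases
#'   (default 10000).
#' @param flank_asymmetry_delta Methylation-probability increment applied to
#'   one randomly chosen flank (upstream or downstream) of every peak; the
#'   chosen side is recorded in the ground truth.
#' @param rfm_flank_rerandomize_kd If `TRUE` (default), the asymmetric side
#'   of RFM peaks is re-drawn independently in KD, decorrelating CT and KD
#'   flank asymmetry at RFM but not MFR.
#' @param n_snps Number of heterozygous SNPs (one per bin, at bin centers).
#' @param snp_methylation Methylation probability of a methylated allele at
#'   a SNP bin (unmethylated alleles sit at 0.01).
#' @param fraction_monoallelic_ct,fraction_gain_kd,fraction_loss_kd,fraction_flip_kd
#'   Fractions of SNPs planted as stable-monoallelic, gain-of-monoallelic
#'   (biallelic CT, monoallelic KD), loss-of-monoallelic, and allelic-flip;
#'   the remainder is stable biallelic. Must sum to at most 1.
#' @param seed Integer seed; all three simulation stages derive their RNG
#'   streams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 350000L,
                       n_chromosomes = 2L,
                       bin_size = 200L,
                       read_length = 150L,
                       n_reads_ct = 80000L,
                       n_reads_kd = 80000L,
                       baseline_range = c(0.05, 0.15),
                       domain_size = 10000L,
                       domain_range = c(0.5, 2),
                       stochastic_flip_prob = 0.3,
                       stochastic_fold_range = c(1.25, 2),
                       deterministic_shift = 0.4,
                       n_tfbs_planted = 50L,
                       n_rfm_peaks = 10L,
                       n_mfr_peaks = 10L,
                       peak_width = 400L,
                       flank = 10000L,
                       flank_asymmetry_delta = 0.3,
                       rfm_flank_rerandomize_kd = TRUE,
                       n_snps = 300L,
                       snp_methylation = 0.3,
                       fraction_monoallelic_ct = 0.2,
                       fraction_gain_kd = 0.15,
                       fraction_loss_kd = 0.15,
                       fraction_flip_kd = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  check_probability(cfg$stochastic_flip_prob, "stochastic_flip_prob")
  check_probability(cfg$flank_asymmetry_delta, "flank_asymmetry_delta")
  check_probability(cfg$snp_methylation, "snp_methylation")
  fracs <- c(fraction_monoallelic_ct, fraction_gain_kd, fraction_loss_kd,
             fraction_flip_kd)
  check_probability(fracs, "allelic category fractions")
  if (sum(fracs) > 1) abort("allelic category fractions must sum to <= 1")
  if (abs(deterministic_shift) > 1) {
    abort("deterministic_shift must be in [-1, 1]")
  }
  if (genome_length %% bin_size != 0) {
    abort("bin_size must divide genome_length")
  }
  if (bin_size < read_length) {
    abort("bin_size must be >= read_length so reads nest in bins")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d x %d kb, %d bp bins, %d+%d reads, seed %d\n",
    x$n_chromosomes, x$genome_length %/% 1000, x$bin_size,
    x$n_reads_ct, x$n_reads_kd, x$seed))
  invisible(x)
}

# bundled synthetic motif set (first entry is the planted TF)
default_sim_pwms <- function() {
  path <- system.file("extdata", "synthetic_motifs.jaspar",
                      package = "stochmeth")
  pfms <- read_jaspar_pfm(path)
  purrr::imap(pfms, ~ pwm_from_pfm(.x, tf_name = .y))
}

#' Simulate a diploid genome with planted features
#'
#' Generates random nucleotide sequences per chromosome and lays out the
#' planted structure: TFBS bins (each carrying an embedded consensus of the
#' planted motif), RFM peaks (motif consensus at the peak center, no repeat
#' annotation) and MFR peaks (repeat annotation covering the peak, no
#' motif), plus heterozygous SNP sites with maternal/paternal phase.
#' Peaks are placed with non-overlapping `flank`-wide territories; TFBS and
#' SNP bins are drawn from the remaining background bins.
#'
#' @param config A [sim_config()] object.
#' @param pwms Named list of [pwm_from_pfm()] objects; the first is the
#'   planted TF. Defaults to the package's bundled synthetic motif set.
#' @return A list: `sequences` (named character vector) and `truth`, a
#'   ground-truth skeleton (genome table, bin grid, peaks, repeats, TFBS
#'   bins, SNP table, planted TF name).
#' @export
simulate_genome <- function(config, pwms = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pwms <- pwms %||% default_sim_pwms()
  genome_table <- tibble(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    length = as.integer(config$genome_length))
  grid <- make_windows(genome_table, config$bin_size)

  n_peaks <- config$n_rfm_peaks + config$n_mfr_peaks
  territory <- 2L * config$flank + config$peak_width
  per_chrom_cap <- config$genome_length %/% territory
  if (n_peaks > per_chrom_cap * config$n_chromosomes) {
    abort("genome too short to host the requested peaks with their flanks")
  }

  with_seed_or_not(config$seed, {
    sequences <- setNames(purrr::map_chr(genome_table$chrom, function(ch) {
      paste(sample(c("A", "C", "G", "T"), config$genome_length,
                   replace = TRUE), collapse = "")
    }), genome_table$chrom)

    # non-overlapping peak territories, round-robin across chromosomes
    peaks <- NULL
    if (n_peaks > 0) {
      chrom_of <- rep(genome_table$chrom,
                      length.out = config$n_chromosomes *
                        ceiling(n_peaks / config$n_chromosomes))[seq_len(n_peaks)]
      peaks <- purrr::map_dfr(genome_table$chrom, function(ch) {
        k <- sum(chrom_of == ch)
        if (k == 0) return(NULL)
        slack <- config$genome_length - k * territory
        gaps <- sort(floor(runif(k, 0, slack + 1)))
        tstart <- gaps + (seq_len(k) - 1L) * territory
        tibble(chrom = ch,
               start = as.integer(tstart + config$flank),
               end = as.integer(tstart + config$flank + config$peak_width))
      })
      cls <- sample(c(rep("RFM", config$n_rfm_peaks),
                      rep("MFR", config$n_mfr_peaks)))
      peaks$site_class <- cls
      peaks$peak_id <- paste0("peak", seq_len(n_peaks))
      peaks$center <- (peaks$start + peaks$end) %/% 2L
    } else {
      peaks <- tibble(chrom = character(), start = integer(),
                      end = integer(), site_class = character(),
                      peak_id = character(), center = integer())
    }
    repeats <- peaks %>%
      filter(.data$site_class == "MFR") %>%
      select("chrom", "start", "end") %>%
      mutate(name = paste0("repeat", row_number()))

    # background bins: outside every peak territory
    territory_tbl <- peaks %>%
      mutate(start = .data$start - config$flank,
             end = .data$end + config$flank) %>%
      select("chrom", "start", "end")
    free <- grid[!overlaps_any(grid, territory_tbl), , drop = FALSE]
    need <- config$n_tfbs_planted + config$n_snps
    if (nrow(free) < need) {
      abort("genome too short to host the requested TFBS bins and SNPs")
    }
    picked <- free[sample.int(nrow(free), need), , drop = FALSE]
    tfbs_bins <- head(picked, config$n_tfbs_planted)
    snp_bins <- tail(picked, config$n_snps)

    # embed the planted TF consensus at TFBS bin centers and RFM peak centers
    planted <- pwms[[1]]
    cons <- pwm_consensus(planted)
    embed_at <- bind_rows(
      tibble(chrom = tfbs_bins$chrom,
             at = (tfbs_bins$start + tfbs_bins$end) %/% 2L -
               planted$width %/% 2L),
      tibble(chrom = peaks$chrom[peaks$site_class == "RFM"],
             at = peaks$center[peaks$site_class == "RFM"] -
               planted$width %/% 2L))
    for (i in seq_len(nrow(embed_at))) {
      ch <- embed_at$chrom[i]
      at <- embed_at$at[i] # 0-based
      substr(sequences[[ch]], at + 1L, at + planted$width) <- cons
    }

    # phased heterozygous SNPs at bin centers; both parents homozygous for
    # different alleles, so the child is an obligate heterozygote
    snps <- NULL
    if (config$n_snps > 0) {
      pos <- snp_bins$start + config$bin_size %/% 2L
      ref <- purrr::map2_chr(snp_bins$chrom, pos,
                             ~ substr(sequences[[.x]], .y + 1L, .y + 1L))
      alt <- purrr::map_chr(ref, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
      ref_is_maternal <- runif(config$n_snps) < 0.5
      snps <- tibble(
        chrom = snp_bins$chrom, pos = as.integer(pos),
        ref = ref, alt = alt,
        maternal = ifelse(ref_is_maternal, ref, alt),
        paternal = ifelse(ref_is_maternal, alt, ref),
        bin = snp_bins$bin) %>%
        arrange(.data$chrom, .data$pos)
    } else {
      snps <- tibble(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), maternal = character(),
                     paternal = character(), bin = integer())
    }

    truth <- list(
      genome_table = genome_table,
      grid = grid,
      peaks = select(peaks, "peak_id", "chrom", "start", "end", "center",
                     "site_class"),
      repeats = repeats,
      tfbs_bins = select(tfbs_bins, "bin", "chrom", "start", "end"),
      snps = snps,
      planted_tf = planted$tf_name)
    list(sequences = sequences, truth = truth)
  })
}

# bins of the grid within [center - flank, peak start) / (peak end,
# center + flank], per side; used for planting and recovery
flank_bins <- function(grid, peak, flank) {
  g <- grid[grid$chrom == peak$chrom, , drop = FALSE]
  up <- g$bin[g$start >= peak$start - flank & g$end <= peak$start]
  down <- g$bin[g$start >= peak$end & g$end <= peak$end + flank]
  list(up = up, down = down)
}

#' Assign per-allele methylation probabilities and allelic categories
#'
#' Completes the ground truth: a domain-structured baseline methylation
#' probability per bin; symmetric stochastic fold flips in KD; the
#' deterministic shift added at planted TFBS bins; the flank-asymmetry
#' increment on one recorded side of each peak (re-randomized in KD at RFM
#' when configured); and per-SNP allelic methylation states drawn in the
#' configured category fractions. SNP bins keep their planted allelic state
#' and are exempt from the stochastic/deterministic perturbations so the
#' planted categories stay exact.
#'
#' @param config A [sim_config()] object.
#' @param truth Ground-truth skeleton from [simulate_genome()].
#' @return The completed ground truth, with `methylation` (tibble: `bin`,
#'   `ct_mat`, `ct_pat`, `kd_mat`, `kd_pat`), per-peak flank sides
#'   (`flank_side_ct`, `flank_side_kd`), and per-SNP `category` and
#'   `methylated_parent_ct` / `methylated_parent_kd`.
#' @export
simulate_methylation_states <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  grid <- truth$grid
  nb <- nrow(grid)
  with_seed_or_not(config$seed + 1L, {
    domain <- grid$start %/% config$domain_size
    dkey <- paste(grid$chrom, domain)
    dlev <- setNames(runif(length(unique(dkey)), config$domain_range[1],
                           config$domain_range[2]), unique(dkey))
    m0 <- pmin(runif(nb, config$baseline_range[1], config$baseline_range[2]) *
                 dlev[dkey], 0.95)

    # a stochastic flip is an exchangeable reassignment: the bin's two
    # levels (m, m*f) go to (CT, KD) in random order, so gains and losses
    # are symmetric at every Diff/Sum magnitude, including sampling tails
    ct <- m0
    kd <- m0
    flip <- runif(nb) < config$stochastic_flip_prob
    fold <- runif(nb, config$stochastic_fold_range[1],
                  config$stochastic_fold_range[2])
    hi_level <- pmin(m0 * fold, 0.99)
    up <- runif(nb) < 0.5
    kd[flip & up] <- hi_level[flip & up]
    ct[flip & !up] <- hi_level[flip & !up]

    is_tfbs <- grid$bin %in% truth$tfbs_bins$bin
    kd[is_tfbs] <- pmin(pmax(kd[is_tfbs] + config$deterministic_shift, 0), 1)

    # planted flank asymmetry: one side per peak, per condition
    peaks <- truth$peaks
    side_ct <- character(nrow(peaks))
    side_kd <- character(nrow(peaks))
    ct_add <- numeric(nb)
    kd_add <- numeric(nb)
    for (i in seq_len(nrow(peaks))) {
      fb <- flank_bins(grid, peaks[i, ], config$flank)
      side_ct[i] <- sample(c("up", "down"), 1)
      side_kd[i] <- if (peaks$site_class[i] == "RFM" &&
                        config$rfm_flank_rerandomize_kd) {
        sample(c("up", "down"), 1)
      } else side_ct[i]
      ct_add[fb[[side_ct[i]]]] <- config$flank_asymmetry_delta
      kd_add[fb[[side_kd[i]]]] <- config$flank_asymmetry_delta
    }
    ct <- pmin(ct + ct_add, 1)
    kd <- pmin(kd + kd_add, 1)

    meth <- tibble(bin = grid$bin, ct_mat = ct, ct_pat = ct,
                   kd_mat = kd, kd_pat = kd)

    # allelic categories at SNP bins (independent draws per SNP)
    snps <- truth$snps
    if (nrow(snps) > 0) {
      fr <- c(monoallelic_stable = config$fraction_monoallelic_ct,
              gain_of_monoallelic = config$fraction_gain_kd,
              loss_of_monoallelic = config$fraction_loss_kd,
              allelic_flip = config$fraction_flip_kd)
      category <- sample(c(names(fr), "biallelic_stable"), nrow(snps),
                         replace = TRUE, prob = c(fr, 1 - sum(fr)))
      parent_a <- sample(c("mat", "pat"), nrow(snps), replace = TRUE)
      hi <- config$snp_methylation
      lo <- 0.01
      both <- c(hi, hi)
      one <- function(p) if (p == "mat") c(hi, lo) else c(lo, hi)
      other <- function(p) if (p == "mat") "pat" else "mat"
      st <- purrr::map2_dfr(category, parent_a, function(cat, pa) {
        ctv <- switch(cat,
          biallelic_stable = both,
          monoallelic_stable = one(pa),
          gain_of_monoallelic = both,
          loss_of_monoallelic = one(pa),
          allelic_flip = one(pa))
        kdv <- switch(cat,
          biallelic_stable = both,
          monoallelic_stable = one(pa),
          gain_of_monoallelic = one(pa),
          loss_of_monoallelic = both,
          allelic_flip = one(other(pa)))
        tibble(ct_mat = ctv[1], ct_pat = ctv[2],
               kd_mat = kdv[1], kd_pat = kdv[2])
      })
      idx <- match(snps$bin, meth$bin)
      meth[idx, c("ct_mat", "ct_pat", "kd_mat", "kd_pat")] <- st
      snps$category <- category
      snps$methylated_parent_ct <- dplyr::case_when(
        category %in% c("monoallelic_stable", "loss_of_monoallelic",
                        "allelic_flip") ~ parent_a,
        TRUE ~ "both")
      snps$methylated_parent_kd <- dplyr::case_when(
        category %in% c("monoallelic_stable", "gain_of_monoallelic") ~ parent_a,
        category == "allelic_flip" ~ ifelse(parent_a == "mat", "pat", "mat"),
        TRUE ~ "both")
    }

    truth$methylation <- meth
    truth$peaks$flank_side_ct <- side_ct
    truth$peaks$flank_side_kd <- side_kd
    truth$snps <- snps
    truth
  })
}

#' Sample MeDIP reads from the completed ground truth
#'
#' Draws fixed-length single-end reads with per-bin, per-allele sampling
#' weight proportional to the methylation probability (the MeDIP capture
#' model: read density follows local methylcytosine density). Reads nest
#' entirely within their source bin; a read from a SNP-bearing bin carries
#' the base of its allele of origin at the SNP position. Allele-of-origin
#' tags live only in the ground-truth sidecar.
#'
#' @param config A [sim_config()] object.
#' @param truth Completed ground truth from [simulate_methylation_states()].
#' @return A list: `reads_ct` / `reads_kd` (tibbles `chrom`, `start`, `end`,
#'   `name`, `sample`), `bases` (observed base per read per overlapped SNP:
#'   `name`, `sample`, `chrom`, `pos`, `base`), `genotypes` (SNP table with
#'   parental genotypes, e.g. `"A/A"`), and `sidecar` (read name, sample,
#'   bin, allele of origin).
#' @export
sample_medip_reads <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$methylation)) {
    abort("ground truth is not completed; run simulate_methylation_states()")
  }
  grid <- truth$grid
  meth <- truth$methylation
  with_seed_or_not(config$seed + 2L, {
    draw <- function(sample_label, n_reads, w_mat, w_pat) {
      w <- c(w_mat, w_pat) # first nb entries maternal, then paternal
      if (n_reads > 0 && sum(w) <= 0) {
        abort("all sampling weights are zero; cannot place reads")
      }
      if (n_reads == 0) {
        return(list(
          reads = tibble(chrom = character(), start = integer(),
                         end = integer(), name = character(),
                         sample = character()),
          sidecar = tibble(name = character(), sample = character(),
                           bin = integer(), allele = character())))
      }
      nb <- nrow(grid)
      pick <- sample.int(2L * nb, n_reads, replace = TRUE, prob = w)
      bin_i <- (pick - 1L) %% nb + 1L
      allele <- ifelse(pick <= nb, "mat", "pat")
      jitter <- sample.int(config$bin_size - config$read_length + 1L,
                           n_reads, replace = TRUE) - 1L
      start <- grid$start[bin_i] + jitter
      name <- paste0(sample_label, "_read", seq_len(n_reads))
      list(
        reads = tibble(chrom = grid$chrom[bin_i], start = as.integer(start),
                       end = as.integer(start + config$read_length),
                       name = name, sample = sample_label),
        sidecar = tibble(name = name, sample = sample_label,
                         bin = grid$bin[bin_i], allele = allele))
    }
    ct <- draw("CT", config$n_reads_ct, meth$ct_mat, meth$ct_pat)
    kd <- draw("KD", config$n_reads_kd, meth$kd_mat, meth$kd_pat)

    sidecar <- bind_rows(ct$sidecar, kd$sidecar)
    snps <- truth$snps
    bases <- sidecar %>%
      inner_join(select(snps, "bin", "chrom", "pos", "maternal", "paternal"),
                 by = "bin") %>%
      mutate(base = ifelse(.data$allele == "mat", .data$maternal,
                           .data$paternal)) %>%
      select("name", "sample", "chrom", "pos", "base")

    genotypes <- snps %>%
      mutate(maternal_gt = paste(.data$maternal, .data$maternal, sep = "/"),
             paternal_gt = paste(.data$paternal, .data$paternal, sep = "/")) %>%
      select("chrom", "pos", "ref", "alt", "maternal", "paternal",
             "maternal_gt", "paternal_gt")

    list(reads_ct = ct$reads, reads_kd = kd$reads, bases = bases,
         genotypes = genotypes, sidecar = sidecar)
  })
}

#' Run the full synthetic MeDIP simulation
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_methylation_states()] and [sample_medip_reads()].
#'
#' @inheritParams simulate_genome
#' @return A list with `sequences`, the completed `truth`, and the read-set
#'   elements of [sample_medip_reads()].
#' @export
simulate_medip <- function(config = sim_config(), pwms = NULL) {
  gen <- simulate_genome(config, pwms)
  truth <- simulate_methylation_states(config, gen$truth)
  reads <- sample_medip_reads(config, truth)
  c(list(sequences = gen$sequences, truth = truth), reads)
}

#' Write a simulation to standard-format files
#'
#' Emits FASTA (genome), BED6 (reads per sample, peaks, repeats, planted
#' TFBS bins), the genome size table, the SNP TSV with parental alleles and
#' a JSON ground-truth sidecar. All coordinates 0-based half-open.
#'
#' @param sim Result of [simulate_medip()].
#' @param dir Output directory (created if absent).
#' @return Named vector of written file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta(sim$sequences, p("genome.fa"))
  write_genome_table(sim$truth$genome_table, p("genome.tsv"))
  bed6 <- function(x, name) {
    tibble(chrom = x$chrom, start = x$start, end = x$end,
           name = name, score = 0, strand = ".")
  }
  write_bed(bed6(sim$reads_ct, sim$reads_ct$name), p("reads_ct.bed"))
  write_bed(bed6(sim$reads_kd, sim$reads_kd$name), p("reads_kd.bed"))
  write_bed(bed6(sim$truth$peaks, sim$truth$peaks$peak_id), p("peaks.bed"))
  if (nrow(sim$truth$repeats) > 0) {
    write_bed(bed6(sim$truth$repeats, sim$truth$repeats$name),
              p("repeats.bed"))
  }
  write_bed(bed6(sim$truth$tfbs_bins,
                 paste0("tfbs_bin", seq_len(nrow(sim$truth$tfbs_bins)))),
            p("tfbs_bins.bed"))
  write_snp_table(sim$genotypes, p("snps.tsv"))
  truth_json <- list(
    planted_tf = sim$truth$planted_tf,
    peaks = sim$truth$peaks,
    snps = sim$truth$snps,
    methylation = sim$truth$methylation,
    sidecar = sim$sidecar)
  jsonlite::write_json(truth_json, p("ground_truth.json"), digits = NA)
  invisible(c(genome = p("genome.fa"), snps = p("snps.tsv"),
              truth = p("ground_truth.json")))
}
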