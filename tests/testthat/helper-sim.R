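# Shared small simulation configurations for module tests. Peak territories
# use short flanks here so the genome stays small and fast; the acceptance
# suite runs the full-size reference conditions.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 60000L, n_chromosomes = 2L,
         n_reads_ct = 15000L, n_reads_kd = 15000L,
         n_tfbs_planted = 10L, n_rfm_peaks = 2L, n_mfr_peaks = 2L,
         flank = 2000L, n_snps = 50L),
    list(...))
  do.call(sim_config, args)
}

# per-bin CT/KD signal tibble from a simulation
sim_signals <- function(sim) {
  grid <- sim$truth$grid
  dplyr::mutate(grid,
    ct = coverage_fractional(sim$reads_ct, grid)$count,
    kd = coverage_fractional(sim$reads_kd, grid)$count)
}
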