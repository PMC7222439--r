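# Compact generator configs for fast unit tests. The full-scale study
# conditions (200 samples, 1000 genes, three 30-gene regions) live in
# sim_config()'s defaults and are exercised in test-acceptance.R.

small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed, n_samples = 40, n_genes = 150,
    genome = data.frame(chrom = c("chr1", "chr2"),
                        length = c(50e6, 40e6)),
    planted_regions = data.frame(
      chrom = "chr1", start = 10e6, end = 16e6,
      dosage_slope = 0.8, n_genes = 25),
    planted_hubs = data.frame(chrom = c("chr2", "chr2"),
                              start = c(5e6, 25e6), end = c(7e6, 27e6)),
    n_noise_peaks = 40, n_events_per_sample = 15)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(sim_config, args)
}

random_events <- function(n, chroms = c("chr1", "chr2", "chr3"),
                          len = 50e6, score_range = c(40, 99)) {
  data.frame(
    sample = sample(sprintf("S%02d", 1:5), n, replace = TRUE),
    chrom1 = sample(chroms, n, replace = TRUE),
    pos1 = floor(runif(n) * len), orient1 = "+",
    chrom2 = sample(chroms, n, replace = TRUE),
    pos2 = floor(runif(n) * len), orient2 = "-",
    type = "CTX", size = 0,
    score = sample(score_range[1]:score_range[2], n, replace = TRUE),
    num_reads = 5L, stringsAsFactors = FALSE)
}
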