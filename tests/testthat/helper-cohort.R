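# Small cohort configurations shared across test files. The full-size
# default configuration is exercised in the acceptance tests; unit tests
# use these lighter variants.

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

tiny_regions <- function() {
  list(
    planted_region(1, 150000, 300000, "amplification", 0.9, 0.35,
                   driver_gene = "DRV1", n_targets = 30L),
    planted_region(2, 100000, 260000, "amplification", 1.1, 0.30,
                   driver_gene = "DRV2", n_targets = 30L),
    planted_region(3, 200000, 300000, "deletion", -0.7, 0.20)
  )
}

tiny_config <- function(seed = 1L, planted_regions = tiny_regions(),
                        n_histology_genes = 10L, ...) {
  sim_config(n_subjects = 40L, n_chromosomes = 3L,
             probes_per_chromosome = 40L, n_genes = 200L, n_mirnas = 20L,
             planted_regions = planted_regions,
             n_histology_genes = n_histology_genes, seed = seed, ...)
}

# One noiseless amplification for exactness checks.
noiseless_config <- function(seed = 1L, ...) {
  sim_config(n_subjects = 20L, n_chromosomes = 2L,
             probes_per_chromosome = 40L, n_genes = 80L, n_mirnas = 10L,
             planted_regions = list(
               planted_region(1, 100000, 200000, "amplification", 0.8, 0.5,
                              driver_gene = "DRV1", n_targets = 10L)),
             n_histology_genes = 4L, noise_sd_probe = 0, seed = seed, ...)
}
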