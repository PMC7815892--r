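# Shared fixtures: all synthetic, generated at test time.

# A scaled-down spike-in benchmark (same design as the full one).
tiny_benchmark <- function(n = c(ecoli = 30L, yeast = 25L, human = 80L),
                           reps = 4L, cv = 0.05, noise_sd = 0.3, seed = 1L) {
  generate_benchmark(benchmark_design(replicates_per_group = reps,
                                      intragroup_cv = cv),
                     n_proteins = n, noise_sd = noise_sd, seed = seed)
}

tiny_masked <- function(alpha = 0.2, beta = 0.5, seed = 1L, ...) {
  simulate_missingness(log2_transform(tiny_benchmark(...)),
                       missingness_spec(alpha, beta, seed = seed))
}

# Build a masked dataset directly from a matrix and a logical mask.
masked_from <- function(truth, mask) {
  obs <- truth
  obs[mask] <- NA_real_
  list(observed = obs, mask = mask, truth = truth)
}

all_methods <- c("LOD", "ND", "KNN", "LLS", "RF", "SVD", "BPCA")
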