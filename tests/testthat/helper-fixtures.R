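# Shared fixtures: all synthetic, generated in code under fixed seeds.

# a lighter pipeline configuration for tests that refit many times;
# coarser lattices, same algorithm
fast_config <- function(...) {
  analysis_config(n_mu = 7L, n_sigma = 7L, n_mu_refine = 7L,
                  n_sigma_refine = 7L, n_lambda_refine = 5L, levels = 2L,
                  n_p = 5L, n_p_final = 21L,
                  histogram_args = list(n_starts = 50L), ...)
}

# clean Box-Cox normal sample
bcn_sample <- function(lam, mu, sigma, n, seed) {
  simulate_dataset(simulation_spec(bcn_model(lam, mu, sigma), n = n),
                   seed = seed)
}

# histogram + expected counts under a known model, for fit-level tests
model_histogram <- function(model, n = 50000L, seed = 1L,
                            overlap_factor = 2L) {
  x <- bcn_sample(model$lam, model$mu, model$sigma, n, seed)
  regions <- select_lambda_and_roi(x)
  build_overlap_histogram(x, regions, overlap_factor = overlap_factor)
}
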