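# small shared fixtures built in code

toy_grm <- function(n, seed = 42, m = 4 * n) {
  g <- simulate_genotypes(n, m, maf_range = c(0.1, 0.5), seed = seed)
  # small n can leave sampled-monomorphic SNPs; drop them as QC would
  poly <- apply(g$dosages, 2, function(d) length(unique(d)) > 1)
  compute_grm(genotype_matrix(g$dosages[, poly, drop = FALSE],
                              sample_ids = g$sample_ids))
}

# simulate + fit the four nested models in one go (small-n test helper)
fit_four <- function(n, m, vc, seed, control = rnm_control()) {
  sim <- simulate_rnm_data(n, m, vc, seed = seed)
  K <- compute_grm(sim$genotypes)
  cs <- standardize_covariate(sim$covariate)
  fits <- rnm_nested(sim$y, K, cs, control = control)
  list(fits = fits, sim = sim, K = K, c_std = cs)
}
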