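# Shared fixtures: small simulations and hand-built graphs, all generated in
# code under fixed seeds.

small_sim <- function(n = 200, noise = 0.25, seed = 42, frac_de = 0.2,
                      frac_cr = 0.5, effect = 2) {
  simulate_expression(sim_config(
    n_transcripts = n, probes_per_transcript = 5,
    frac_de = frac_de, frac_counterreg = frac_cr,
    effect_log2fc = effect, noise_sd = noise, rng_seed = seed))
}

zero_noise_sim <- function(n = 100, seed = 7) {
  simulate_expression(sim_config(
    n_transcripts = n, probes_per_transcript = 3,
    frac_de = 0.2, frac_counterreg = 0.5, effect_log2fc = 2,
    noise_sd = 0, probe_effect_sd = 0, rng_seed = seed))
}

# expression matrix built directly from per-transcript group means (no probes)
toy_expression <- function(values, groups) {
  expression_matrix(values, groups)
}

# star graph: center connected to each leaf
star_network <- function(center = "C", leaves = paste0("L", 1:9)) {
  interaction_network(cbind(center, leaves))
}

run_small_pipeline <- function(dir, seed = 11, n = 150) {
  sim <- small_sim(n = n, seed = seed)
  write_probe_matrix(sim$probes, file.path(dir, "probes.tsv"),
                     file.path(dir, "design.tsv"))
  ns <- simulate_network(sim$truth$counterreg_sets[[1]],
                         net_sim_config(n_background_nodes = 80,
                                        hub_target_fraction = 0.5,
                                        rng_seed = seed))
  write_network_sif(ns$network, file.path(dir, "network.sif"))
  cfg <- pipeline_config(expression = file.path(dir, "probes.tsv"),
                         design = file.path(dir, "design.tsv"),
                         network = file.path(dir, "network.sif"),
                         output_dir = file.path(dir, "out"),
                         n_permutations = 30, n_bins = 8,
                         min_network_score = 2, rng_seed = seed)
  list(cfg = cfg, sim = sim, net = ns)
}

# independent median-polish oracle: plain iterated median sweeps mirroring the
# textbook algorithm (rows first, re-centering effects), kept separate from
# the implementation path
oracle_medpolish_summary <- function(x, eps = 1e-6, maxiter = 20L) {
  t0 <- 0; r <- numeric(nrow(x)); cc <- numeric(ncol(x)); z <- x
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rdelta <- apply(z, 1, median)
    z <- z - rdelta; r <- r + rdelta
    delta <- median(cc); cc <- cc - delta; t0 <- t0 + delta
    cdelta <- apply(z, 2, median)
    z <- sweep(z, 2, cdelta); cc <- cc + cdelta
    delta <- median(r); r <- r - delta; t0 <- t0 + delta
    newsum <- sum(abs(z))
    converged <- newsum == 0 || abs(newsum - oldsum) < eps * newsum
    if (converged) break
    oldsum <- newsum
  }
  t0 + cc
}

# exhaustive rank-product oracle for k = 1: the pooled permutation null over
# all G! equally likely rankings collapses to the uniform distribution on
# ranks 1..G, so p(rank r) = r / G exactly
oracle_exhaustive_p_k1 <- function(G, obs_rank) obs_rank / G
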