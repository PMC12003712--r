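# shared fixtures, built in code

# a small cohort with one deletion region and one duplication region plus a
# planted metabolite effect; used across the preprocessing/HMM/association
# tests
small_cohort <- function(seed = 42, n_samples = 60, n_probes = 400,
                         n_metabolites = 12, del_freq = 0.3, dup_freq = 0.25,
                         beta = 0.4, del_probes = 110:130,
                         dup_probes = 250:265, ...) {
  cfg <- sim_config(n_samples = n_samples, n_probes = n_probes,
                    n_metabolites = n_metabolites, seed = seed, ...)
  pm <- simulate_probe_map(cfg)   # deterministic: same map rebuilt below
  regions <- data.frame(
    chrom = "1",
    start = pm$pos[c(min(del_probes), min(dup_probes))],
    end = pm$pos[c(max(del_probes), max(dup_probes))],
    state = c(1, 3), freq = c(del_freq, dup_freq))
  cfg <- sim_config(
    n_samples = n_samples, n_probes = n_probes,
    n_metabolites = n_metabolites, regions = regions,
    effect_table = data.frame(probe_index = 120, metabolite_index = 3,
                              beta = beta),
    seed = seed, ...)
  simulate_cohort(cfg)
}

# random HMM parameter draws that respect the hmm_params invariants
random_hmm_params <- function() {
  mu <- sort(c(-3.5, -0.66, 0, 0.4, 0.68) + stats::rnorm(5, sd = 0.05))
  hmm_params(
    lrr_mean = mu,
    lrr_sd = stats::runif(5, 0.1, 0.6),
    stationary_prior = {
      p <- stats::runif(5, 0.05, 1); p / sum(p)
    },
    switch_rate_per_bp = 10^stats::runif(1, -7, -5),
    max_switch_prob = stats::runif(1, 0.1, 0.9))
}

# brute-force HMM oracle: enumerate all 5^n state paths of a short chain
# directly from prior, distance-aware transitions and emission densities
enumerate_hmm <- function(lrr, baf, pos, params) {
  n <- length(lrr)
  E <- exp(cnvmetabo:::emission_matrix(lrr, baf, params))
  trans <- lapply(diff(pos), transition_matrix, params = params)
  paths <- as.matrix(expand.grid(rep(list(1:5), n)))
  jp <- apply(paths, 1L, function(s) {
    p <- params$stationary_prior[s[1L]] * E[1L, s[1L]]
    if (n > 1L) for (t in 2:n)
      p <- p * trans[[t - 1L]][s[t - 1L], s[t]] * E[t, s[t]]
    p
  })
  gamma <- matrix(0, n, 5L)
  for (t in seq_len(n)) for (s in 1:5)
    gamma[t, s] <- sum(jp[paths[, t] == s])
  list(gamma = gamma / sum(jp), loglik = log(sum(jp)),
       best_path = paths[which.max(jp), ] - 1L,
       best_logprob = log(max(jp)))
}
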