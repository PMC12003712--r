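params_default <- hmm_params()

tiny_map <- function(pos, chrom = "1") {
  pm <- data.frame(probe_id = sprintf("p%d", seq_along(pos)), chrom = chrom,
                   pos = as.integer(pos),
                   gc_fraction = 0.4, stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

test_that("transition matrices are stochastic, identity at 0, prior at infinity", {
  p0 <- hmm_params(min_switch_prob = 1e-300)
  expect_equal(transition_matrix(0, p0), diag(5), tolerance = 1e-12)

  pinf <- hmm_params(max_switch_prob = 1 - 1e-12)
  Tinf <- transition_matrix(1e12, pinf)
  for (s in 1:5)
    expect_equal(unname(Tinf[s, ]), pinf$stationary_prior, tolerance = 1e-9)

  set.seed(1)
  for (d in sample.int(1e7, 100))
    expect_equal(rowSums(transition_matrix(d, params_default)), rep(1, 5),
                 tolerance = 1e-12)
  expect_error(transition_matrix(-1, params_default), ">= 0")
})

test_that("emission log-likelihoods match the density formula", {
  # unimodal in LRR: the state mean beats a 3-SD displacement
  for (s in 0:4) {
    mu <- params_default$lrr_mean[s + 1]
    sd <- params_default$lrr_sd[s + 1]
    expect_gt(emission_loglik(mu, 0.5, s, params_default),
              emission_loglik(mu + 3 * sd, 0.5, s, params_default))
  }
  # heterozygous BAF at 0.5 favours copy 2 over copy 1
  expect_gt(emission_loglik(0, 0.5, 2, params_default),
            emission_loglik(0, 0.5, 1, params_default))

  # direct recomputation of Gaussian x truncated-Gaussian mixture
  set.seed(2)
  for (i in 1:20) {
    lrr <- rnorm(1); baf <- runif(1); s <- sample(0:4, 1)
    bc <- params_default$baf_components[[s + 1]]
    bdens <- if (is.null(bc)) 1 else
      sum(bc$weight * dnorm(baf, bc$mean, bc$sd) /
            (pnorm(1, bc$mean, bc$sd) - pnorm(0, bc$mean, bc$sd)))
    manual <- dnorm(lrr, params_default$lrr_mean[s + 1],
                    params_default$lrr_sd[s + 1], log = TRUE) + log(bdens)
    expect_equal(emission_loglik(lrr, baf, s, params_default), manual,
                 tolerance = 1e-12)
  }
  # missing BAF drops to the LRR term only
  expect_equal(emission_loglik(0.1, NA, 2, params_default),
               dnorm(0.1, 0, params_default$lrr_sd[3], log = TRUE))
  expect_error(emission_loglik(Inf, 0.5, 2, params_default), "non-finite")
})

test_that("forward-backward matches first principles on short chains", {
  pm1 <- tiny_map(1000)
  # single probe: posterior proportional to prior x emission
  fb <- forward_backward(-0.6, 0.1, pm1, params_default)
  e <- exp(vapply(0:4, function(s)
    emission_loglik(-0.6, 0.1, s, params_default), 0))
  expect_equal(fb$gamma[1, ],
               params_default$stationary_prior * e /
                 sum(params_default$stationary_prior * e),
               tolerance = 1e-12)
  expect_equal(rowSums(fb$gamma), 1, tolerance = 1e-9)

  # uninformative emissions leave the stationary prior untouched
  pm3 <- tiny_map(c(1000, 6000, 60000))
  fbu <- forward_backward(rep(NA_real_, 3), rep(NA_real_, 3), pm3,
                          suppressWarnings(params_default)) |>
    suppressWarnings()
  for (t in 1:3)
    expect_equal(fbu$gamma[t, ], params_default$stationary_prior,
                 tolerance = 1e-9)
})

test_that("posteriors and Viterbi agree with exhaustive path enumeration", {
  set.seed(7)
  for (rep in 1:100) {
    par <- random_hmm_params()
    pos <- sort(sample.int(5e5, 3))
    lrr <- rnorm(3, sample(par$lrr_mean, 3, replace = TRUE), 0.4)
    baf <- runif(3)
    pm <- tiny_map(pos)
    oracle <- enumerate_hmm(lrr, baf, pos, par)
    fb <- forward_backward(lrr, baf, pm, par)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    vit <- cnvmetabo:::viterbi_chrom(lrr, baf, pos, par)
    expect_equal(vit$logprob, oracle$best_logprob, tolerance = 1e-10)
    expect_equal(vit$path, unname(oracle$best_path))
  }
})

test_that("segments recover planted CNV regions and stay empty under the null", {
  # all-neutral, low-noise panel: no segments at all
  cfg0 <- sim_config(n_probes = 200, n_samples = 6, n_metabolites = 3,
                     lrr_noise_sd = 0.05, wave_amplitude = 0,
                     gc_coefficient = 0, seed = 21)
  sim0 <- simulate_cohort(cfg0)
  calls0 <- call_cnvs(sim0$panel, sim0$probe_map)
  expect_equal(nrow(calls0$segments), 0L)

  # one planted 21-probe deletion: exactly one segment per carrier,
  # boundaries within two probes of the truth
  sim <- small_cohort(seed = 22, n_samples = 30, lrr_noise_sd = 0.08,
                      wave_amplitude = 0, gc_coefficient = 0,
                      dup_freq = 1e-9)
  calls <- call_cnvs(sim$panel, sim$probe_map)
  carriers <- rownames(sim$truth$copy_state)[sim$truth$carriers[[1]]]
  segs <- calls$segments
  expect_setequal(unique(segs$sample_id), carriers)
  expect_true(all(segs$state == 1L))
  pos <- sim$probe_map$pos
  for (sid in carriers) {
    s <- segs[segs$sample_id == sid, ]
    expect_equal(nrow(s), 1L)
    expect_lte(abs(match(s$start_pos, pos) - 110), 2)
    expect_lte(abs(match(s$end_pos, pos) - 130), 2)
  }
})

test_that("expected genotypes implement the posterior-weighted copy number", {
  g <- array(0, c(1, 3, 5))
  g[1, 1, ] <- c(0, 0.7, 0.3, 0, 0)     # 1*0.7 + 2*0.3
  g[1, 2, ] <- c(0, 0, 1, 0, 0)
  g[1, 3, ] <- c(0.5, 0, 0, 0, 0.5)     # symmetric about 2
  d <- expected_genotypes(g)
  expect_equal(d$count_all[1, ], c(1.3, 2, 2))
  expect_true(all(d$count_all >= 0 & d$count_all <= 4))

  # deletion-only / duplication-only renormalised expectations
  g2 <- array(0, c(1, 1, 5))
  g2[1, 1, ] <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  d2 <- expected_genotypes(g2)
  expect_equal(d2$count_all[1, 1], sum(0:4 * g2[1, 1, ]))
  expect_equal(d2$del_only[1, 1],
               sum(0:2 * g2[1, 1, 1:3]) / sum(g2[1, 1, 1:3]))
  expect_equal(d2$dup_only[1, 1],
               sum(2:4 * g2[1, 1, 3:5]) / sum(g2[1, 1, 3:5]))

  bad <- g; bad[1, 1, ] <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(expected_genotypes(bad), "not normalised")
})

test_that("dosage allele frequency follows the folded mean-deviation formula", {
  expect_equal(cnv_allele_frequency(rep(2, 10)), 0)
  expect_equal(cnv_allele_frequency(rep(1, 10)), 0.5)
  expect_equal(cnv_allele_frequency(c(rep(1, 5), rep(2, 5))), 0.25)
  expect_equal(cnv_allele_frequency(c(3, 3, 2, 2)), 0.25)
  expect_error(cnv_allele_frequency(numeric()), "empty")
})

test_that("noisier intensities reduce posterior confidence", {
  conf <- vapply(c(0.08, 0.18, 0.35), function(sd) {
    sim <- small_cohort(seed = 23, n_samples = 10, lrr_noise_sd = sd,
                        wave_amplitude = 0, gc_coefficient = 0)
    calls <- call_cnvs(sim$panel, sim$probe_map)
    mean(apply(calls$gamma, c(1, 2), max))
  }, 0)
  expect_true(all(diff(conf) < 0))
})
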