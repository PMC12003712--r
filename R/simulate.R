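#' Simulate an array probe map
#'
#' Generates an ordered genomic probe map: probes are spread over the
#' configured chromosomes with exponentially distributed gaps and carry a
#' GC fraction drawn from a smooth positional process (latent AR(1) along the
#' probe order), so neighbouring probes have correlated GC as on a real
#' array.
#'
#' @param config a [sim_config()] object.
#' @return a \code{probe_map} data.frame with columns
#'   \code{probe_id, chrom, pos, gc_fraction}; positions are 1-based and
#'   strictly increasing within each chromosome.
#' @export
simulate_probe_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "probe_map"))
  n <- config$n_probes
  chroms <- config$chroms
  per <- diff(round(seq(0, n, length.out = length(chroms) + 1L)))
  if (any(per < 2L) && length(chroms) > 1L)
    stop("too few probes to cover ", length(chroms), " chromosomes")
  chrom <- rep(chroms, per)
  pos <- integer(n)
  for (cc in chroms) {
    idx <- which(chrom == cc)
    gaps <- 1 + stats::rexp(length(idx), rate = 1 / config$mean_spacing_bp)
    pos[idx] <- 1e6 + cumsum(round(gaps))
  }
  # latent AR(1) -> correlated GC along the probe order, centred near 0.42
  phi <- 0.9
  z <- numeric(n)
  z[1L] <- stats::rnorm(1L)
  innov <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
  for (i in 2:n) z[i] <- phi * z[i - 1L] + innov[i - 1L]
  gc <- pmin(1, pmax(0, 0.42 + 0.07 * z))
  pm <- data.frame(
    probe_id = sprintf("probe_%05d", seq_len(n)),
    chrom = chrom, pos = as.integer(pos), gc_fraction = gc,
    stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Simulate CNV ground truth
#'
#' Assigns each planted region's copy state to a random carrier subset of
#' samples drawn at the region's population frequency; every other
#' (sample, probe) entry is copy-neutral (state 2).
#'
#' @param probe_map a probe map from [simulate_probe_map()].
#' @param config a [sim_config()]; regions are taken from
#'   \code{config$regions}.
#' @return a \code{cnv_truth} list with \code{copy_state}
#'   (samples x probes integer matrix), \code{carriers} (list of logical
#'   carrier vectors per region) and \code{region_table}.
#' @export
simulate_cnv_truth <- function(probe_map, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "cnv_truth"))
  n <- config$n_samples
  p <- nrow(probe_map)
  cs <- matrix(2L, n, p, dimnames = list(sample_ids(n), probe_map$probe_id))
  regions <- config$regions
  carriers <- list()
  if (!is.null(regions) && nrow(regions) > 0L) {
    probe_sets <- lapply(seq_len(nrow(regions)), function(r) {
      which(probe_map$chrom == regions$chrom[r] &
              probe_map$pos >= regions$start[r] &
              probe_map$pos <= regions$end[r])
    })
    # overlapping regions with different states would write conflicting truth
    for (r in seq_along(probe_sets)) for (s in seq_len(r - 1L)) {
      if (length(intersect(probe_sets[[r]], probe_sets[[s]])) &&
          regions$state[r] != regions$state[s])
        stop("regions ", s, " and ", r,
             " overlap with conflicting states (",
             regions$state[s], " vs ", regions$state[r], ")")
    }
    for (r in seq_len(nrow(regions))) {
      carry <- stats::runif(n) < regions$freq[r]
      carriers[[r]] <- carry
      if (length(probe_sets[[r]]))
        cs[carry, probe_sets[[r]]] <- as.integer(regions$state[r])
    }
  }
  out <- list(copy_state = cs, carriers = carriers,
              region_table = regions)
  class(out) <- "cnv_truth"
  out
}

#' Simulate LRR/BAF intensities
#'
#' Builds the observed array signal from the copy-state truth:
#' \deqn{LRR = \mu_{state} + \gamma_{GC}(gc - \bar{gc}) + a\,\sin(2\pi pos/T + \phi_i) + \epsilon}
#' with per-sample wave phase \eqn{\phi_i}. BAF is drawn from the allelic
#' mixture implied by the copy state: each probe gets a population B-allele
#' frequency, each sample draws its B-allele count given its copy number, and
#' BAF is the allelic ratio plus jitter, clipped to [0, 1]; homozygous
#' deletions (no signal) give uniform BAF.
#'
#' @param truth a [simulate_cnv_truth()] result.
#' @param probe_map the matching probe map.
#' @param config a [sim_config()].
#' @return an \code{intensity_panel}: list with \code{lrr}, \code{baf}
#'   (samples x probes), \code{sex} (factor male/female) and
#'   \code{cohort_id}.
#' @export
simulate_intensities <- function(truth, probe_map, config, cohort_id = "cohortA") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cnv_truth"))
  cs <- truth$copy_state
  if (ncol(cs) != nrow(probe_map))
    stop("truth and probe_map disagree on probe count")
  set.seed(stage_seed(config, "intensities"))
  n <- nrow(cs); p <- ncol(cs)
  gc_c <- probe_map$gc_fraction - mean(probe_map$gc_fraction)
  mu <- matrix(config$state_lrr_mean[cs + 1L], n, p)
  phase <- stats::runif(n, 0, 2 * pi)
  wave <- config$wave_amplitude *
    sin(outer(phase, 2 * pi * probe_map$pos / config$wave_period_bp, `+`))
  lrr <- mu +
    matrix(config$gc_coefficient * gc_c, n, p, byrow = TRUE) +
    wave +
    matrix(stats::rnorm(n * p, sd = config$lrr_noise_sd), n, p)
  # allelic composition: per-probe population B-allele frequency
  pb <- stats::runif(p, 0.05, 0.95)
  bcount <- matrix(stats::rbinom(n * p, size = as.vector(cs),
                                 prob = rep(pb, each = n)), n, p)
  baf <- ifelse(cs > 0L, bcount / pmax(cs, 1L), NA_real_)
  baf <- baf + matrix(stats::rnorm(n * p, sd = config$baf_noise_sd), n, p)
  baf[cs == 0L] <- stats::runif(sum(cs == 0L))  # no signal: uniform
  baf[baf < 0] <- 0
  baf[baf > 1] <- 1
  dimnames(lrr) <- dimnames(baf) <- dimnames(cs)
  sex <- factor(ifelse(stats::runif(n) < 0.5, "male", "female"),
                levels = c("female", "male"))
  panel <- list(lrr = lrr, baf = baf, sex = sex, cohort_id = cohort_id)
  class(panel) <- "intensity_panel"
  panel
}

#' Simulate metabolite phenotypes with planted dosage effects
#'
#' The metabolite background is a block-correlated Gaussian field (one latent
#' factor per block of \code{block_size} metabolites, within-block
#' correlation \code{block_rho}); each planted effect adds
#' \code{beta * (copy_state - 2)} of its probe to its metabolite. Sex is
#' simulated independently and returned as a covariate.
#'
#' @param truth a [simulate_cnv_truth()] result.
#' @param config a [sim_config()].
#' @param sex optional sex factor to reuse (e.g. from the intensity panel);
#'   simulated when NULL.
#' @return a \code{phenotype_panel}: list with \code{metabolites}
#'   (samples x M, named columns), \code{metabolite_names} and
#'   \code{covariates} (currently the male-sex indicator).
#' @export
simulate_phenotypes <- function(truth, config, sex = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cnv_truth"))
  set.seed(stage_seed(config, "phenotypes"))
  n <- config$n_samples; m <- config$n_metabolites
  rho <- config$block_rho
  blocks <- rep(seq_len(ceiling(m / config$block_size)),
                each = config$block_size, length.out = m)
  shared <- matrix(stats::rnorm(n * max(blocks)), n)
  met <- sqrt(rho) * shared[, blocks, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
  met <- met * config$met_noise_sd
  if (is.null(sex))
    sex <- factor(ifelse(stats::runif(n) < 0.5, "male", "female"),
                  levels = c("female", "male"))
  if (config$sex_effect != 0)
    met <- met + config$sex_effect * (sex == "male")
  et <- config$effect_table
  if (!is.null(et) && nrow(et) > 0L) {
    if (any(et$probe_index < 1L | et$probe_index > ncol(truth$copy_state)) ||
        any(et$metabolite_index < 1L | et$metabolite_index > m))
      stop("effect_table indices out of range")
    for (k in seq_len(nrow(et))) {
      dose <- truth$copy_state[, et$probe_index[k]] - 2L
      if (all(dose == 0L))
        warning("planted effect on probe ", et$probe_index[k],
                " which carries no CNV region; effect is unidentifiable")
      met[, et$metabolite_index[k]] <-
        met[, et$metabolite_index[k]] + et$beta[k] * dose
    }
  }
  names <- sprintf("met_%03d", seq_len(m))
  dimnames(met) <- list(sample_ids(n), names)
  covs <- matrix(as.numeric(sex == "male"), n, 1L,
                 dimnames = list(sample_ids(n), "sex_male"))
  out <- list(metabolites = met, metabolite_names = names,
              covariates = covs, sex = sex)
  class(out) <- "phenotype_panel"
  out
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper chaining [simulate_probe_map()],
#' [simulate_cnv_truth()], [simulate_intensities()] and
#' [simulate_phenotypes()] with a shared configuration. Two cohorts sharing
#' a common probe subset are obtained by calling this twice with distinct
#' seeds and (optionally) probe maps constructed to overlap.
#'
#' @param config a [sim_config()].
#' @param cohort_id label stored on the intensity panel.
#' @return list with \code{probe_map}, \code{truth}, \code{panel},
#'   \code{phenotypes} and the \code{config} used.
#' @export
simulate_cohort <- function(config, cohort_id = "cohortA") {
  pm <- simulate_probe_map(config)
  truth <- simulate_cnv_truth(pm, config)
  panel <- simulate_intensities(truth, pm, config, cohort_id = cohort_id)
  phen <- simulate_phenotypes(truth, config, sex = panel$sex)
  list(probe_map = pm, truth = truth, panel = panel, phenotypes = phen,
       config = config)
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))
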