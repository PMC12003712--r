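#' Simulation configuration
#'
#' Bundles every knob of the synthetic SNP-array / metabolome generator in one
#' validated object. The defaults describe a typical Illumina-style array
#' experiment: probes spaced a few kilobases apart, LRR noise around 0.18,
#' a low-frequency genomic wave and a linear GC intensity artifact, and a
#' metabolite panel with lipoprotein-like block correlation.
#'
#' @param n_samples number of individuals.
#' @param n_probes number of array probes (>= 2).
#' @param n_metabolites number of metabolite phenotypes (default 228,
#'   the size of a standard NMR lipid/fatty-acid panel).
#' @param chroms chromosome labels over which probes are spread (roughly
#'   equally). Plain "1", "2", ... labels (hg19-style positions).
#' @param mean_spacing_bp mean inter-probe gap in basepairs.
#' @param wave_amplitude amplitude (LRR units) of the smooth positional
#'   "genomic wave" artifact; each sample gets its own random phase.
#' @param wave_period_bp period of the wave in basepairs.
#' @param gc_coefficient linear coefficient of LRR on (centred) probe GC
#'   fraction, shared across samples.
#' @param lrr_noise_sd per-probe Gaussian LRR noise SD.
#' @param baf_noise_sd Gaussian jitter of BAF around its allelic mean
#'   (clipped back to [0, 1]).
#' @param state_lrr_mean length-5 LRR means for copy states 0..4.
#' @param regions data.frame of planted CNV regions with columns
#'   \code{chrom, start, end, state, freq}: carriers (drawn at population
#'   frequency \code{freq}) hold copy \code{state} over every probe in
#'   [start, end]; all other entries are copy-neutral (2).
#' @param effect_table data.frame with columns
#'   \code{probe_index, metabolite_index, beta}: planted linear dosage
#'   effects, \code{beta} per copy deviation from 2.
#' @param block_size metabolite correlation-block size.
#' @param block_rho within-block correlation in [0, 1).
#' @param met_noise_sd marginal SD of the metabolite background field.
#' @param sex_effect additive effect of male sex on every metabolite
#'   (0 by default: sex is a covariate, not a signal).
#' @param seed integer master seed; a fixed seed makes every generator
#'   output byte-identical across calls.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_samples = 500L,
                       n_probes = 1000L,
                       n_metabolites = 228L,
                       chroms = "1",
                       mean_spacing_bp = 5000,
                       wave_amplitude = 0.05,
                       wave_period_bp = 2e6,
                       gc_coefficient = 0.2,
                       lrr_noise_sd = 0.18,
                       baf_noise_sd = 0.03,
                       state_lrr_mean = c(-3.5, -0.66, 0, 0.4, 0.68),
                       regions = NULL,
                       effect_table = NULL,
                       block_size = 12L,
                       block_rho = 0.5,
                       met_noise_sd = 1,
                       sex_effect = 0,
                       seed = 1L) {
  if (!is.numeric(n_probes) || n_probes < 2)
    stop("n_probes must be an integer >= 2")
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer")
  if (!is.numeric(n_metabolites) || n_metabolites < 1)
    stop("n_metabolites must be a positive integer")
  if (block_rho < 0 || block_rho >= 1)
    stop("block_rho must lie in [0, 1)")
  if (length(state_lrr_mean) != 5L || is.unsorted(state_lrr_mean, strictly = TRUE))
    stop("state_lrr_mean must be 5 strictly increasing values for states 0..4")
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    need <- c("chrom", "start", "end", "state", "freq")
    if (!all(need %in% names(regions)))
      stop("regions needs columns: ", paste(need, collapse = ", "))
    if (any(regions$freq <= 0 | regions$freq > 1))
      stop("region frequencies must lie in (0, 1]")
    if (!all(regions$state %in% c(0L, 1L, 3L, 4L)))
      stop("region states must be in {0, 1, 3, 4}")
  }
  if (!is.null(effect_table)) {
    effect_table <- as.data.frame(effect_table)
    need <- c("probe_index", "metabolite_index", "beta")
    if (!all(need %in% names(effect_table)))
      stop("effect_table needs columns: ", paste(need, collapse = ", "))
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_metabolites = as.integer(n_metabolites), chroms = as.character(chroms),
    mean_spacing_bp = mean_spacing_bp, wave_amplitude = wave_amplitude,
    wave_period_bp = wave_period_bp, gc_coefficient = gc_coefficient,
    lrr_noise_sd = lrr_noise_sd, baf_noise_sd = baf_noise_sd,
    state_lrr_mean = as.numeric(state_lrr_mean),
    regions = regions, effect_table = effect_table,
    block_size = as.integer(block_size), block_rho = block_rho,
    met_noise_sd = met_noise_sd, sex_effect = sex_effect,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples x", x$n_probes, "probes x",
      x$n_metabolites, "metabolites; seed", x$seed, "\n")
  cat("  regions:", if (is.null(x$regions)) 0L else nrow(x$regions),
      " planted effects:", if (is.null(x$effect_table)) 0L else nrow(x$effect_table), "\n")
  invisible(x)
}

# stage-specific RNG seeds derived from the master seed so each generator
# stage is reproducible on its own and independent of call order
stage_seed <- function(cfg, stage) {
  offsets <- c(probe_map = 11L, cnv_truth = 23L, intensities = 37L,
               phenotypes = 53L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (cfg$seed %% 2000000000L) + offsets[[stage]]
}
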