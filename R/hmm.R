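#' Copy-number HMM parameters
#'
#' Parameters of the 5-state (copy 0..4) hidden Markov model used to
#' genotype CNVs from LRR and BAF. Emissions follow the usual array model:
#' a Gaussian on LRR per state, and a per-state mixture of [0,1]-truncated
#' Gaussians on BAF placed at the attainable allelic ratios (copy 2 ->
#' {0, 1/2, 1}; copy 1 -> {0, 1}; copy 3 -> {0, 1/3, 2/3, 1}; copy 4 ->
#' fifths of 0..4/4); homozygous deletion carries no allelic signal and is
#' modelled as uniform BAF. Transitions are distance-aware: the chance of
#' leaving the current state grows with the basepair gap and relaxes
#' towards the stationary prior.
#'
#' @param lrr_mean,lrr_sd length-5 numeric: per-state LRR Gaussian
#'   parameters, means strictly increasing in copy number.
#' @param baf_components list of 5 data.frames (\code{mean, sd, weight};
#'   weights summing to 1) or NULL entries for uniform BAF.
#' @param stationary_prior length-5 state prior, summing to 1; the default
#'   encodes that CNV states are rare.
#' @param switch_rate_per_bp rate of the exponential distance kernel.
#' @param min_switch_prob,max_switch_prob clip bounds for the per-gap
#'   switch probability, both in (0, 1).
#' @return an \code{hmm_params} object.
#' @export
hmm_params <- function(lrr_mean = c(-3.5, -0.66, 0, 0.4, 0.68),
                       lrr_sd = c(1.0, 0.25, 0.2, 0.25, 0.3),
                       baf_components = default_baf_components(),
                       stationary_prior = c(0.0005, 0.005, 0.989, 0.005, 0.0005),
                       switch_rate_per_bp = 1e-6,
                       min_switch_prob = 1e-8,
                       max_switch_prob = 0.2) {
  stopifnot(length(lrr_mean) == 5L, length(lrr_sd) == 5L,
            length(stationary_prior) == 5L, length(baf_components) == 5L)
  if (is.unsorted(lrr_mean, strictly = TRUE))
    stop("lrr_mean must be strictly increasing in copy number")
  if (any(lrr_sd <= 0)) stop("lrr_sd must be positive")
  if (abs(sum(stationary_prior) - 1) > 1e-8)
    stop("stationary_prior must sum to 1")
  if (min_switch_prob <= 0 || max_switch_prob >= 1 ||
      min_switch_prob > max_switch_prob)
    stop("switch probabilities must satisfy 0 < min <= max < 1")
  for (s in seq_len(5L)) {
    bc <- baf_components[[s]]
    if (is.null(bc)) next
    if (!all(c("mean", "sd", "weight") %in% names(bc)))
      stop("baf_components[[", s, "]] needs mean, sd, weight")
    if (abs(sum(bc$weight) - 1) > 1e-8)
      stop("baf_components[[", s, "]] weights must sum to 1")
  }
  p <- list(states = 0:4, lrr_mean = as.numeric(lrr_mean),
            lrr_sd = as.numeric(lrr_sd), baf_components = baf_components,
            stationary_prior = stationary_prior / sum(stationary_prior),
            switch_rate_per_bp = switch_rate_per_bp,
            min_switch_prob = min_switch_prob,
            max_switch_prob = max_switch_prob)
  class(p) <- "hmm_params"
  p
}

#' @rdname hmm_params
#' @export
default_baf_components <- function(baf_sd = 0.04) {
  comp <- function(means, weights)
    data.frame(mean = means, sd = baf_sd, weight = weights / sum(weights))
  list(
    NULL,                                        # state 0: uniform, no signal
    comp(c(0, 1), c(1, 1)),                      # state 1
    comp(c(0, 0.5, 1), c(1, 2, 1)),              # state 2
    comp(c(0, 1/3, 2/3, 1), c(1, 3, 3, 1)),      # state 3
    comp(c(0, 0.25, 0.5, 0.75, 1), c(1, 4, 6, 4, 1)))  # state 4
}

#' Distance-aware transition matrix
#'
#' The probability of switching state over a gap of \code{distance_bp} is
#' \code{clip(1 - exp(-rate * distance), min, max)}; switching re-draws the
#' state from the stationary prior, so rows relax towards the prior with
#' distance and the matrix is the identity at distance 0 (when
#' \code{min_switch_prob} is negligible).
#'
#' @param distance_bp non-negative gap in basepairs.
#' @param params an [hmm_params()] object.
#' @return a 5x5 row-stochastic matrix.
#' @export
transition_matrix <- function(distance_bp, params) {
  if (distance_bp < 0) stop("distance_bp must be >= 0")
  p_sw <- min(max(1 - exp(-params$switch_rate_per_bp * distance_bp),
                  params$min_switch_prob), params$max_switch_prob)
  (1 - p_sw) * diag(5L) +
    p_sw * matrix(params$stationary_prior, 5L, 5L, byrow = TRUE)
}

#' Emission log-likelihood
#'
#' Log of the joint emission density of one (LRR, BAF) observation under a
#' copy state: Gaussian LRR density times the state's truncated-Gaussian
#' BAF mixture (uniform for copy 0). A missing BAF contributes the LRR term
#' only; a missing LRR, the BAF term only.
#'
#' @param lrr_value,baf_value observed intensities (scalars; NA = missing).
#' @param state copy state in 0..4.
#' @param params an [hmm_params()] object.
#' @return scalar log-likelihood.
#' @export
emission_loglik <- function(lrr_value, baf_value, state, params) {
  if (!state %in% 0:4) stop("state must be in 0..4")
  if ((!is.na(lrr_value) && !is.finite(lrr_value)) ||
      (!is.na(baf_value) && !is.finite(baf_value)))
    stop("non-finite intensity value")
  emission_matrix(lrr_value, baf_value, params)[1L, state + 1L]
}

# log emission matrix for vectors of observations: (n_probes x 5)
emission_matrix <- function(lrr, baf, params) {
  n <- max(length(lrr), length(baf))
  ll <- matrix(0, n, 5L)
  for (s in seq_len(5L)) {
    if (!all(is.na(lrr))) {
      dl <- stats::dnorm(lrr, params$lrr_mean[s], params$lrr_sd[s], log = TRUE)
      dl[is.na(lrr)] <- 0
      ll[, s] <- ll[, s] + dl
    }
    bc <- params$baf_components[[s]]
    if (is.null(bc)) next                         # uniform on [0,1]: log 1 = 0
    db <- rep(0, length(baf))
    ok <- !is.na(baf)
    if (any(ok)) {
      dens <- 0
      for (c in seq_len(nrow(bc))) {
        z <- stats::pnorm(1, bc$mean[c], bc$sd[c]) -
          stats::pnorm(0, bc$mean[c], bc$sd[c])
        dens <- dens + bc$weight[c] *
          stats::dnorm(baf[ok], bc$mean[c], bc$sd[c]) / z
      }
      db[ok] <- log(dens)
    }
    ll[, s] <- ll[, s] + db
  }
  ll
}

#' Forward-backward smoothing posteriors for one sample
#'
#' Runs scaled forward-backward per chromosome under the distance-aware
#' 5-state HMM, returning the exact posterior state probabilities at every
#' probe and the total log-likelihood of the intensity sequence. Scaling
#' keeps the recursion stable at any chromosome length.
#'
#' @param sample_lrr,sample_baf numeric vectors aligned to \code{probe_map}.
#' @param probe_map the probe map (positions sorted per chromosome).
#' @param params an [hmm_params()] object.
#' @return list with \code{gamma} (probes x 5, rows summing to 1) and
#'   \code{loglik}.
#' @export
forward_backward <- function(sample_lrr, sample_baf, probe_map, params) {
  p <- nrow(probe_map)
  stopifnot(length(sample_lrr) == p, length(sample_baf) == p)
  gamma <- matrix(NA_real_, p, 5L)
  loglik <- 0
  for (cc in unique(probe_map$chrom)) {
    idx <- which(probe_map$chrom == cc)
    if (all(is.na(sample_lrr[idx]) & is.na(sample_baf[idx]))) {
      warning("all intensities missing on chromosome ", cc,
              "; posteriors set to the stationary prior")
      gamma[idx, ] <- matrix(params$stationary_prior, length(idx), 5L,
                             byrow = TRUE)
      next
    }
    fb <- fb_chrom(sample_lrr[idx], sample_baf[idx],
                   probe_map$pos[idx], params)
    gamma[idx, ] <- fb$gamma
    loglik <- loglik + fb$loglik
  }
  list(gamma = gamma, loglik = loglik)
}

fb_chrom <- function(lrr, baf, pos, params) {
  n <- length(lrr)
  E <- exp(emission_matrix(lrr, baf, params))     # densities; scaled below
  trans <- lapply(diff(pos), transition_matrix, params = params)
  alpha <- matrix(0, n, 5L); scale <- numeric(n)
  a <- params$stationary_prior * E[1L, ]
  scale[1L] <- sum(a); alpha[1L, ] <- a / scale[1L]
  if (n > 1L) for (t in 2:n) {
    a <- as.vector(alpha[t - 1L, ] %*% trans[[t - 1L]]) * E[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, n, 5L)
  beta[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    b <- as.vector(trans[[t]] %*% (E[t + 1L, ] * beta[t + 1L, ]))
    beta[t, ] <- b / scale[t + 1L]
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  list(gamma = g, loglik = sum(log(scale)))
}

#' Viterbi CNV segments for one sample
#'
#' Computes the maximum a posteriori state path and reports maximal runs of
#' identical non-neutral states as CNV segments with probe-span coordinates
#' (1-based, inclusive of the first and last probe). \code{mean_posterior}
#' is the average forward-backward posterior of the segment's state over its
#' probes.
#'
#' @inheritParams forward_backward
#' @param sample_id label written into the segment table.
#' @return a data.frame of segments: \code{sample_id, chrom, start_pos,
#'   end_pos, state, n_probes, mean_posterior} (zero rows when the path is
#'   all copy-neutral).
#' @export
viterbi_segments <- function(sample_lrr, sample_baf, probe_map, params,
                             sample_id = "sample") {
  p <- nrow(probe_map)
  stopifnot(length(sample_lrr) == p, length(sample_baf) == p)
  segs <- list()
  for (cc in unique(probe_map$chrom)) {
    idx <- which(probe_map$chrom == cc)
    path <- viterbi_chrom(sample_lrr[idx], sample_baf[idx],
                          probe_map$pos[idx], params)$path
    gam <- fb_chrom(sample_lrr[idx], sample_baf[idx],
                    probe_map$pos[idx], params)$gamma
    r <- rle(path)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != 2L)) {
      span <- starts[k]:ends[k]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = cc,
        start_pos = probe_map$pos[idx][starts[k]],
        end_pos = probe_map$pos[idx][ends[k]],
        state = r$values[k], n_probes = length(span),
        mean_posterior = mean(gam[span, r$values[k] + 1L]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      state = integer(), n_probes = integer(),
                      mean_posterior = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

viterbi_chrom <- function(lrr, baf, pos, params) {
  n <- length(lrr)
  logE <- emission_matrix(lrr, baf, params)
  delta <- log(params$stationary_prior) + logE[1L, ]
  psi <- matrix(0L, n, 5L)
  if (n > 1L) for (t in 2:n) {
    logT <- log(transition_matrix(pos[t] - pos[t - 1L], params))
    cand <- delta + logT                       # cand[i, j] = delta_i + logT_ij
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[t, ], 1:5)] + logE[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  list(path = path - 1L, logprob = max(delta))
}

#' Genotype copy number across a panel
#'
#' Applies [forward_backward()] and [viterbi_segments()] to every sample of
#' an intensity panel.
#'
#' @param panel an \code{intensity_panel} (LRR should be GC/wave corrected).
#' @param probe_map matching probe map.
#' @param params an [hmm_params()] object.
#' @return a \code{cnv_calls} list: \code{gamma} (samples x probes x 5
#'   posterior array), \code{segments} (one data.frame over all samples),
#'   \code{loglik} (per sample).
#' @export
call_cnvs <- function(panel, probe_map, params = hmm_params()) {
  check_panel(panel, probe_map)
  n <- nrow(panel$lrr); p <- ncol(panel$lrr)
  gamma <- array(NA_real_, c(n, p, 5L),
                 dimnames = list(rownames(panel$lrr), colnames(panel$lrr),
                                 paste0("state", 0:4)))
  loglik <- numeric(n)
  segs <- vector("list", n)
  ids <- rownames(panel$lrr)
  for (i in seq_len(n)) {
    fb <- forward_backward(panel$lrr[i, ], panel$baf[i, ], probe_map, params)
    gamma[i, , ] <- fb$gamma
    loglik[i] <- fb$loglik
    segs[[i]] <- viterbi_segments(panel$lrr[i, ], panel$baf[i, ], probe_map,
                                  params, sample_id = ids[i])
  }
  out <- list(gamma = gamma, segments = do.call(rbind, segs), loglik = loglik)
  class(out) <- "cnv_calls"
  out
}

#' Expected CNV genotypes (dosage vectors)
#'
#' Converts state posteriors into the three expected-genotype dosage
#' vectors: \code{count_all}, the posterior-weighted mean copy number
#' \eqn{\sum_s s\,\gamma_s} over all five states (the "mirror model" dosage,
#' in [0, 4]); \code{del_only}, the expectation over states {0, 1, 2}
#' renormalised; and \code{dup_only}, over {2, 3, 4} renormalised. At a
#' probe where, say, heterozygous deletion has posterior 0.7 and
#' copy-neutral 0.3, \code{count_all} is 1*0.7 + 2*0.3 = 1.3.
#'
#' @param posterior either a \code{cnv_calls} object or a samples x probes
#'   x 5 posterior array; every (sample, probe) slice must sum to 1 within
#'   \code{tol}.
#' @param tol normalisation tolerance.
#' @return a \code{dosage_set} list of three samples x probes matrices:
#'   \code{count_all}, \code{del_only}, \code{dup_only}.
#' @export
expected_genotypes <- function(posterior, tol = 1e-6) {
  gamma <- if (inherits(posterior, "cnv_calls")) posterior$gamma else posterior
  if (length(dim(gamma)) != 3L || dim(gamma)[3L] != 5L)
    stop("posterior must be a samples x probes x 5 array")
  tots <- apply(gamma, c(1L, 2L), sum)
  if (any(abs(tots - 1) > tol))
    stop("posterior slices not normalised (max deviation ",
         signif(max(abs(tots - 1)), 3), ")")
  np <- dim(gamma)[1:2]
  slice <- function(s)
    matrix(gamma[, , s + 1L], np[1L], np[2L],
           dimnames = dimnames(gamma)[1:2])
  expect_over <- function(keep) {
    num <- 0; den <- 0
    for (s in keep) {
      num <- num + s * slice(s)
      den <- den + slice(s)
    }
    out <- num / den
    out[den < 1e-12] <- 2       # no mass on the retained states: copy-neutral
    out
  }
  count_all <- expect_over(0:4)
  out <- list(count_all = count_all,
              del_only = expect_over(0:2),
              dup_only = expect_over(2:4))
  class(out) <- "dosage_set"
  out
}

#' CNV allele frequency from dosage
#'
#' Frequency of the non-reference copy dose implied by a countAll column:
#' \eqn{f = \sum_i |d_i - 2| / (2n)}, folded to \eqn{\min(f, 1 - f)} so the
#' result is a minor-allele-style frequency in [0, 0.5].
#'
#' @param count_all numeric vector of expected genotypes (one probe).
#' @return scalar frequency.
#' @export
cnv_allele_frequency <- function(count_all) {
  count_all <- count_all[!is.na(count_all)]
  if (!length(count_all)) stop("empty dosage vector")
  f <- sum(abs(count_all - 2)) / (2 * length(count_all))
  min(f, 1 - f)
}
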