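#' GC-content correction of LRR
#'
#' For each sample, LRR is regressed on probe GC fraction by least squares
#' and replaced by the residuals; the per-sample mean is re-added so the
#' global intensity level is preserved. Removes the linear GC intensity
#' artifact common on array platforms.
#'
#' @param panel an \code{intensity_panel}.
#' @param probe_map matching probe map with \code{gc_fraction}.
#' @return the panel with corrected \code{lrr} and a \code{gc_report}
#'   data.frame (per-sample \code{gc_slope}, \code{variance_before},
#'   \code{variance_after}).
#' @export
gc_correct <- function(panel, probe_map) {
  check_panel(panel, probe_map)
  gc <- probe_map$gc_fraction
  gc_c <- gc - mean(gc)
  ss <- sum(gc_c^2)
  lrr <- panel$lrr
  ids <- rownames(lrr) %||% as.character(seq_len(nrow(lrr)))
  if (ss < .Machine$double.eps * length(gc)) {
    warning("gc_fraction is constant; GC correction skipped")
    panel$gc_report <- data.frame(sample_id = ids, gc_slope = NA_real_,
                                  variance_before = apply(lrr, 1L, stats::var),
                                  variance_after = apply(lrr, 1L, stats::var))
    return(panel)
  }
  slope <- as.vector(lrr %*% gc_c) / ss          # per-sample OLS slope
  fitted <- outer(slope, gc_c)
  corrected <- lrr - fitted                       # residual + intercept term;
  # subtracting the centred fit leaves each sample's mean untouched
  panel$gc_report <- data.frame(
    sample_id = ids, gc_slope = slope,
    variance_before = apply(lrr, 1L, stats::var),
    variance_after = apply(corrected, 1L, stats::var))
  panel$lrr <- corrected
  panel
}

#' Genomic-wave correction of LRR
#'
#' Removes the slow positional intensity wave: per sample and chromosome a
#' local degree-1 regression of LRR on genomic position (tricube weights,
#' bandwidth \code{window_bp}) is fitted and its trend subtracted; the
#' per-sample mean is preserved. Windows with fewer than 3 probes fall back
#' to the window mean.
#'
#' @param panel an \code{intensity_panel} (typically after [gc_correct()]).
#' @param probe_map matching probe map, position-sorted per chromosome.
#' @param window_bp full window width in basepairs (default 500 kb).
#' @return the panel with corrected \code{lrr} and a \code{wave_report}.
#' @export
wave_correct <- function(panel, probe_map, window_bp = 500000) {
  check_panel(panel, probe_map)
  lrr <- panel$lrr
  row_means <- rowMeans(lrr)
  trend <- matrix(0, nrow(lrr), ncol(lrr))
  half <- window_bp / 2
  for (cc in unique(probe_map$chrom)) {
    idx <- which(probe_map$chrom == cc)
    x <- as.numeric(probe_map$pos[idx])
    if (is.unsorted(x, strictly = TRUE))
      stop("probes not position-sorted on chromosome ", cc)
    Y <- lrr[, idx, drop = FALSE]
    trend[, idx] <- local_linear_trend(x, Y, half)
  }
  corrected <- lrr - trend
  corrected <- corrected + (row_means - rowMeans(corrected))
  panel$wave_report <- data.frame(
    sample_id = rownames(lrr) %||% as.character(seq_len(nrow(lrr))),
    variance_before = apply(lrr, 1L, stats::var),
    variance_after = apply(corrected, 1L, stats::var),
    window_bp = as.integer(window_bp))
  panel$lrr <- corrected
  panel
}

# tricube-weighted degree-1 local regression of each row of Y on x,
# evaluated at every x; returns the fitted trend matrix (samples x probes).
local_linear_trend <- function(x, Y, half_bp) {
  p <- length(x)
  fit <- matrix(0, nrow(Y), p)
  lo <- findInterval(x - half_bp, x) + 1L   # first index with x >= x_j - h
  hi <- findInterval(x + half_bp, x)        # last index with x <= x_j + h
  for (j in seq_len(p)) {
    idx <- lo[j]:hi[j]
    xs <- x[idx]
    w <- (1 - pmin(abs(xs - x[j]) / half_bp, 1)^3)^3
    sw <- sum(w)
    xc <- xs - x[j]
    t0 <- as.vector(Y[, idx, drop = FALSE] %*% w)
    s1 <- sum(w * xc); s2 <- sum(w * xc^2)
    det <- sw * s2 - s1^2
    if (length(idx) < 3L || det <= .Machine$double.eps * sw * max(s2, 1)) {
      fit[, j] <- t0 / sw                    # degenerate window: weighted mean
    } else {
      t1 <- as.vector(Y[, idx, drop = FALSE] %*% (w * xc))
      # weighted LS intercept at x_j (centred parametrisation)
      fit[, j] <- (s2 * t0 - s1 * t1) / det
    }
  }
  fit
}

#' LRR principal-component covariates
#'
#' Computes the first \code{k} principal-component scores of the
#' column-centred LRR matrix. These scores capture residual array-wide
#' intensity structure (batch, hybridisation quality) and are the standard
#' technical covariates of the dosage association models.
#'
#' @param panel an \code{intensity_panel} (after GC/wave correction).
#' @param k number of components (default 50); capped at the matrix rank
#'   with a warning.
#' @return samples x k score matrix with columns \code{PC1..PCk} and an
#'   \code{"explained_variance"} attribute (variances, non-increasing).
#' @export
compute_lrr_pcs <- function(panel, k = 50L) {
  lrr <- panel$lrr
  max_k <- min(nrow(lrr) - 1L, ncol(lrr))
  if (k < 1L) stop("k must be >= 1")
  if (k > max_k) {
    warning("k = ", k, " exceeds the available rank; capped at ", max_k)
    k <- max_k
  }
  pc <- stats::prcomp(lrr, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(lrr)
  attr(scores, "explained_variance") <- pc$sdev[seq_len(k)]^2
  scores
}

check_panel <- function(panel, probe_map) {
  if (!inherits(panel, "intensity_panel")) stop("not an intensity_panel")
  if (ncol(panel$lrr) != nrow(probe_map))
    stop("panel has ", ncol(panel$lrr), " probes but probe_map has ",
         nrow(probe_map))
  invisible(TRUE)
}
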