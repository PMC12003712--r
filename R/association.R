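#' Univariate reverse-regression association
#'
#' For each metabolite, fits the reverse regression
#' \code{dosage ~ metabolite + covariates} by least squares and reports the
#' metabolite term. The reverse direction (genetic dosage as outcome) is
#' what makes the multivariate joint test of
#' [multivariate_signature()] possible; for a single phenotype it is
#' t-equivalent to the usual forward regression once covariates are
#' residualised out of both sides.
#'
#' @param dosage numeric vector: expected CNV genotype (countAll) at one
#'   probe, or corrected LRR for the LRR validation model.
#' @param phenotypes a \code{phenotype_panel} or samples x M metabolite
#'   matrix with column names.
#' @param covariates samples x C numeric matrix (LRR PCs, sex indicator);
#'   NULL for none.
#' @param probe_id label for the output records.
#' @param m_effective effective number of tests used for the Sidak-style
#'   adjustment; computed from the metabolite correlation matrix via
#'   [effective_tests()] when NULL.
#' @param model tag stored on the records ("dosage" or "lrr").
#' @param alpha global reporting filter on the adjusted p-value.
#' @return data.frame of association records: \code{probe_id,
#'   metabolite_name, beta, se, p_raw, p_adjusted, n, maf, model,
#'   reportable}.
#' @export
univariate_assoc <- function(dosage, phenotypes, covariates = NULL,
                             probe_id = "probe", m_effective = NULL,
                             model = "dosage", alpha = 0.05) {
  met <- metabolite_matrix(phenotypes)
  n <- length(dosage)
  stopifnot(nrow(met) == n)
  covariates <- check_covariates(covariates, met, n)
  if (is.null(m_effective))
    m_effective <- effective_tests(stats::cor(met))$m_effective
  maf <- if (identical(model, "dosage")) cnv_allele_frequency(dosage) else NA_real_
  recs <- lapply(colnames(met), function(mn) {
    fit <- fit_with_covariates(dosage, met[, mn, drop = FALSE], covariates)
    data.frame(probe_id = probe_id, metabolite_name = mn,
               beta = fit$beta[1L], se = fit$se[1L], p_raw = fit$p[1L],
               p_adjusted = adjust_p(fit$p[1L], m_effective),
               n = n, maf = maf, model = model, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$reportable <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}

#' LRR-based validation association
#'
#' The same reverse-regression model as [univariate_assoc()] with corrected
#' raw LRR at the probe as the outcome, used to validate dosage signatures
#' without any CNV calling step.
#'
#' @param lrr numeric vector: corrected LRR at one probe.
#' @inheritParams univariate_assoc
#' @export
lrr_assoc <- function(lrr, phenotypes, covariates = NULL,
                      probe_id = "probe", m_effective = NULL, alpha = 0.05) {
  univariate_assoc(lrr, phenotypes, covariates, probe_id = probe_id,
                   m_effective = m_effective, model = "lrr", alpha = alpha)
}

#' Multivariate metabolomic signature by backward selection
#'
#' Starts from the joint reverse regression of dosage on all metabolites
#' plus covariates and repeatedly refits after removing the metabolite with
#' the largest p-value, while that p-value exceeds \code{drop_alpha};
#' covariates are never removed. The retained metabolite set is the
#' "metabolomic signature"; its joint p-value is the F-test of the selected
#' metabolite block against the covariate-only model. When the sample size
#' is too small for the full joint fit, metabolites are pre-screened to the
#' top \code{floor(n/10)} by univariate p-value.
#'
#' @inheritParams univariate_assoc
#' @param drop_alpha backward-selection removal threshold (default 0.05).
#' @return a \code{signature_record} list: \code{probe_id,
#'   selected_metabolites, betas, joint_p_raw, joint_p_adjusted, n,
#'   n_iterations}.
#' @export
multivariate_signature <- function(dosage, phenotypes, covariates = NULL,
                                   drop_alpha = 0.05, probe_id = "probe",
                                   m_effective = NULL) {
  met <- metabolite_matrix(phenotypes)
  n <- length(dosage)
  stopifnot(nrow(met) == n)
  covariates <- check_covariates(covariates, met, n)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (is.null(m_effective))
    m_effective <- effective_tests(stats::cor(met))$m_effective
  active <- colnames(met)
  if (n <= ncol(met) + ncov + 2L) {
    keep <- min(ncol(met), max(1L, floor(n / 10)))
    uni <- univariate_assoc(dosage, met, covariates, probe_id = probe_id,
                            m_effective = m_effective)
    active <- uni$metabolite_name[order(uni$p_raw)][seq_len(keep)]
    warning("n too small for the full joint model; pre-screened to ",
            keep, " metabolites by univariate p")
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (!length(active)) break
    fit <- fit_with_covariates(dosage, met[, active, drop = FALSE], covariates)
    worst <- which.max(fit$p)
    if (fit$p[worst] > drop_alpha) {
      active <- active[-worst]
    } else break
    if (iter > ncol(met) + 1L) break     # safety; selection is finite anyway
  }
  if (!length(active)) {
    rec <- list(probe_id = probe_id, selected_metabolites = character(),
                betas = numeric(), joint_p_raw = 1, joint_p_adjusted = 1,
                n = n, n_iterations = iter)
    class(rec) <- "signature_record"
    return(rec)
  }
  fit <- fit_with_covariates(dosage, met[, active, drop = FALSE], covariates)
  jp <- joint_f_test(dosage, met[, active, drop = FALSE], covariates)
  rec <- list(probe_id = probe_id, selected_metabolites = active,
              betas = stats::setNames(fit$beta, active),
              joint_p_raw = jp, joint_p_adjusted = adjust_p(jp, m_effective),
              n = n, n_iterations = iter)
  class(rec) <- "signature_record"
  rec
}

#' @export
print.signature_record <- function(x, ...) {
  cat("metabolomic signature at", x$probe_id, "-", length(x$selected_metabolites),
      "metabolites, joint p (adj.)", format(x$joint_p_adjusted, digits = 3), "\n")
  invisible(x)
}

#' Effective number of independent tests (Sidak-Nyholt)
#'
#' From the eigenvalues \eqn{\lambda} of the phenotype correlation matrix,
#' \deqn{M_{eff} = 1 + (M - 1)\,(1 - Var(\lambda)/M)}
#' with the sample-variance convention (divisor M - 1), so that an identity
#' correlation gives \eqn{M_{eff} = M} and a perfectly correlated panel
#' gives exactly 1.
#'
#' @param corr_matrix symmetric correlation matrix with unit diagonal.
#' @param tol tolerance for the positive-semidefinite / symmetry checks.
#' @return list with \code{m}, \code{var_lambda}, \code{m_effective}.
#' @export
effective_tests <- function(corr_matrix, tol = 1e-8) {
  corr_matrix <- as.matrix(corr_matrix)
  m <- nrow(corr_matrix)
  if (m != ncol(corr_matrix) ||
      max(abs(corr_matrix - t(corr_matrix))) > tol)
    stop("corr_matrix must be symmetric")
  if (max(abs(diag(corr_matrix) - 1)) > tol)
    stop("corr_matrix must have unit diagonal")
  lambda <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6 * m)
    stop("corr_matrix is not positive semidefinite (min eigenvalue ",
         signif(min(lambda), 3), ")")
  var_lambda <- if (m > 1L) stats::var(lambda) else 0
  m_eff <- 1 + (m - 1) * (1 - var_lambda / m)
  list(m = m, var_lambda = var_lambda,
       m_effective = min(max(m_eff, 1), m))
}

#' Sidak-style multiple-testing adjustment
#'
#' Adjusts a raw p-value for \code{m_effective} effective tests:
#' \code{p_adj = 1 - (1 - p)^m_effective}, capped at 1. Evaluated through
#' \code{log1p}/\code{expm1} so it is accurate down to p-values near the
#' double-precision floor.
#'
#' @param p_raw raw p-value in (0, 1].
#' @param m_effective effective number of tests (>= 1).
#' @return adjusted p-value.
#' @export
adjust_p <- function(p_raw, m_effective) {
  if (any(is.na(p_raw)) || any(p_raw <= 0) || any(p_raw > 1))
    stop("p_raw must lie in (0, 1]")
  pmin(1, -expm1(m_effective * log1p(-p_raw)))
}

#' Stratified nonparametric validation of a dosage-phenotype association
#'
#' Stratifies samples by countAll into deletions (< \code{del_cut}),
#' copy-normal, and duplications (> \code{dup_cut}) and compares the
#' phenotype distribution of each CNV group against the copy-normal group
#' with a two-sided Mann-Whitney U test (exact below 25 total samples when
#' there are no ties, normal approximation with tie correction otherwise).
#'
#' @param count_all numeric vector of expected CNV genotypes.
#' @param phenotype numeric vector, same length.
#' @param del_cut,dup_cut stratification thresholds (defaults 1.75, 2.5).
#' @return list with \code{labels} (factor deletion/neutral/duplication)
#'   and \code{tests}, a data.frame with one row per comparison
#'   (\code{group, n_group, n_neutral, statistic, p, status}); a
#'   comparison with fewer than 2 samples in either group is skipped with
#'   status "skipped".
#' @export
stratified_validation <- function(count_all, phenotype,
                                  del_cut = 1.75, dup_cut = 2.5) {
  stopifnot(length(count_all) == length(phenotype))
  labels <- factor(ifelse(count_all < del_cut, "deletion",
                          ifelse(count_all > dup_cut, "duplication", "neutral")),
                   levels = c("deletion", "neutral", "duplication"))
  neutral <- phenotype[labels == "neutral"]
  one <- function(group) {
    x <- phenotype[labels == group]
    if (length(x) < 2L || length(neutral) < 2L)
      return(data.frame(group = group, n_group = length(x),
                        n_neutral = length(neutral), statistic = NA_real_,
                        p = NA_real_, status = "skipped",
                        stringsAsFactors = FALSE))
    exact <- (length(x) + length(neutral)) < 25L
    wt <- suppressWarnings(
      stats::wilcox.test(x, neutral, alternative = "two.sided", exact = exact))
    data.frame(group = group, n_group = length(x),
               n_neutral = length(neutral),
               statistic = unname(wt$statistic), p = wt$p.value,
               status = "tested", stringsAsFactors = FALSE)
  }
  list(labels = labels,
       tests = rbind(one("deletion"), one("duplication")))
}

## ---- internal fitting helpers ----

metabolite_matrix <- function(phenotypes) {
  met <- if (inherits(phenotypes, "phenotype_panel")) phenotypes$metabolites
  else as.matrix(phenotypes)
  if (is.null(colnames(met)))
    colnames(met) <- sprintf("met_%03d", seq_len(ncol(met)))
  if (any(apply(met, 2L, stats::sd) == 0))
    stop("constant metabolite column(s): ",
         paste(colnames(met)[apply(met, 2L, stats::sd) == 0], collapse = ", "))
  met
}

check_covariates <- function(covariates, met, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  # a covariate duplicating a metabolite (or another covariate) makes the
  # design rank-deficient; drop it rather than fail the whole fit. With
  # fewer rows than columns the rank check cannot attribute blame, so it is
  # skipped (the pre-screen handles that regime).
  X <- cbind(met, covariates)
  if (n < ncol(X) + 2L) return(covariates)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)] - 1L     # drop intercept index
    bad <- setdiff(seq_len(ncol(X)), keep_cols)
    bad_cov <- bad[bad > ncol(met)] - ncol(met)
    if (length(bad_cov)) {
      warning("dropping collinear covariate(s): ",
              paste(colnames(covariates)[bad_cov], collapse = ", "))
      covariates <- covariates[, -bad_cov, drop = FALSE]
      if (!ncol(covariates)) covariates <- NULL
    }
  }
  covariates
}

# least-squares fit y ~ terms + covariates (+ intercept); returns beta/se/p
# for the `terms` block
fit_with_covariates <- function(y, terms, covariates) {
  X <- cbind(`(Intercept)` = 1, terms,
             if (!is.null(covariates)) covariates)
  fit <- stats::lm.fit(X, y)
  k <- fit$rank
  df <- length(y) - k
  if (df <= 0) stop("not enough residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  se_all <- rep(NA_real_, ncol(X))
  se_all[fit$qr$pivot[seq_len(k)]] <- sqrt(diag(XtXinv) * sigma2)
  beta_all <- fit$coefficients
  ix <- 1L + seq_len(ncol(terms))
  beta <- beta_all[ix]; se <- se_all[ix]
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = unname(beta), se = unname(se), p = unname(p), df = df,
       rss = rss)
}

# F-test of the metabolite block against the covariate-only model
joint_f_test <- function(y, terms, covariates) {
  full <- fit_with_covariates(y, terms, covariates)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)),
              if (!is.null(covariates)) covariates)
  fit0 <- stats::lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  q <- ncol(terms)
  Fstat <- ((rss0 - full$rss) / q) / (full$rss / full$df)
  stats::pf(Fstat, q, full$df, lower.tail = FALSE)
}
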