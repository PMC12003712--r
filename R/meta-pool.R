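#' Probes common to two cohorts
#'
#' Matches two probe maps on exact genomic location (chrom, pos) — the
#' cross-platform concordance step that makes pooled and meta-analysis over
#' shared probes possible.
#'
#' @param map_a,map_b probe maps ([simulate_probe_map()] or read from BED).
#' @return data.frame with \code{chrom, pos, probe_id_a, probe_id_b},
#'   ordered by chromosome then position.
#' @export
common_probes <- function(map_a, map_b) {
  for (nm in c("a", "b")) {
    m <- if (nm == "a") map_a else map_b
    key <- paste(m$chrom, m$pos)
    if (anyDuplicated(key))
      stop("duplicate positions in map_", nm, ": ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  merged <- merge(
    data.frame(chrom = map_a$chrom, pos = map_a$pos,
               probe_id_a = map_a$probe_id, stringsAsFactors = FALSE),
    data.frame(chrom = map_b$chrom, pos = map_b$pos,
               probe_id_b = map_b$probe_id, stringsAsFactors = FALSE),
    by = c("chrom", "pos"))
  merged[order(merged$chrom, merged$pos), , drop = FALSE]
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines matched (probe, metabolite) association records from two
#' cohorts: with weights \eqn{w = 1/se^2},
#' \eqn{\beta_{meta} = \sum w\beta / \sum w}, \eqn{se_{meta} = 1/\sqrt{\sum w}},
#' two-sided normal p-value, and Cochran's Q for heterogeneity. Records
#' present in only one cohort pass through unchanged (Q = 0); records with
#' a zero standard error are skipped with a warning.
#'
#' @param records_a,records_b data.frames as returned by
#'   [univariate_assoc()] (need \code{probe_id, metabolite_name, beta, se}).
#' @return data.frame with \code{probe_id, metabolite_name, beta_meta,
#'   se_meta, p_meta, n_cohorts, heterogeneity_q}.
#' @export
meta_analyze <- function(records_a, records_b) {
  recs <- rbind(records_a[, c("probe_id", "metabolite_name", "beta", "se")],
                records_b[, c("probe_id", "metabolite_name", "beta", "se")])
  bad <- !is.finite(recs$se) | recs$se <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive or non-finite se skipped")
    recs <- recs[!bad, , drop = FALSE]
  }
  if (!nrow(recs))
    return(data.frame(probe_id = character(), metabolite_name = character(),
                      beta_meta = numeric(), se_meta = numeric(),
                      p_meta = numeric(), n_cohorts = integer(),
                      heterogeneity_q = numeric(), stringsAsFactors = FALSE))
  key <- paste(recs$probe_id, recs$metabolite_name, sep = "\r")
  out <- lapply(split(seq_len(nrow(recs)), key), function(ix) {
    b <- recs$beta[ix]; se <- recs$se[ix]
    w <- 1 / se^2
    bm <- sum(w * b) / sum(w)
    sem <- 1 / sqrt(sum(w))
    z <- bm / sem
    data.frame(probe_id = recs$probe_id[ix[1L]],
               metabolite_name = recs$metabolite_name[ix[1L]],
               beta_meta = bm, se_meta = sem,
               p_meta = 2 * stats::pnorm(-abs(z)),
               n_cohorts = length(ix),
               heterogeneity_q = sum(w * (b - bm)^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$probe_id, out$metabolite_name), , drop = FALSE]
}

#' Pooled (stacked-sample) association across cohorts
#'
#' Concatenates the samples of both cohorts at a common probe and fits the
#' reverse regression on the stacked data with a cohort indicator added to
#' the covariates, so cohort-level phenotype shifts are absorbed rather
#' than biasing the dosage effect. Metabolite columns are harmonised by
#' name and must agree between cohorts.
#'
#' @param dosage_a,dosage_b per-cohort dosage (or LRR) vectors at the
#'   common probe.
#' @param phen_a,phen_b per-cohort metabolite matrices or
#'   \code{phenotype_panel}s with identical column names.
#' @param cov_a,cov_b per-cohort covariate matrices (computed per cohort,
#'   e.g. each cohort's own LRR PCs) with identical column names, or NULL.
#' @inheritParams univariate_assoc
#' @return association records as in [univariate_assoc()] (one per
#'   metabolite), fitted on the pooled samples.
#' @export
pooled_assoc <- function(dosage_a, dosage_b, phen_a, phen_b,
                         cov_a = NULL, cov_b = NULL, probe_id = "probe",
                         m_effective = NULL, model = "dosage", alpha = 0.05) {
  met_a <- metabolite_matrix(phen_a)
  if (!length(dosage_b))
    return(univariate_assoc(dosage_a, met_a, cov_a, probe_id = probe_id,
                            m_effective = m_effective, model = model,
                            alpha = alpha))
  met_b <- metabolite_matrix(phen_b)
  if (!identical(colnames(met_a), colnames(met_b))) {
    diff <- union(setdiff(colnames(met_a), colnames(met_b)),
                  setdiff(colnames(met_b), colnames(met_a)))
    stop("phenotype columns differ between cohorts: ",
         paste(diff, collapse = ", "))
  }
  if (xor(is.null(cov_a), is.null(cov_b)))
    stop("covariates must be supplied for both cohorts or neither")
  if (!is.null(cov_a) && !identical(colnames(cov_a), colnames(cov_b)))
    stop("covariate columns differ between cohorts")
  dosage <- c(dosage_a, dosage_b)
  met <- rbind(met_a, met_b)
  cohort <- c(rep(0, length(dosage_a)), rep(1, length(dosage_b)))
  covs <- cbind(if (!is.null(cov_a)) rbind(as.matrix(cov_a), as.matrix(cov_b)),
                cohort_b = cohort)
  univariate_assoc(dosage, met, covs, probe_id = probe_id,
                   m_effective = m_effective, model = model, alpha = alpha)
}
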