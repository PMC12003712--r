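#' Pipeline configuration
#'
#' Loads and validates the single-document configuration driving
#' [run_pipeline()]: a master seed, an output directory, one or two cohort
#' sections (each a set of [sim_config()] overrides), and per-stage
#' sections for normalisation, CNV calling and association. Unknown
#' top-level keys are rejected so typos fail loudly. The configuration
#' round-trips through YAML unchanged.
#'
#' @param config a named list or a path to a YAML file.
#' @return a validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- c("seed", "out_dir", "cohorts", "normalize", "call_cnv",
               "associate", "annotate")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$cohorts)) config$cohorts <- list(cohortA = list())
  if (is.null(names(config$cohorts)) || any(names(config$cohorts) == ""))
    stop("cohorts must be a named list")
  if (!length(config$cohorts) %in% 1:2)
    stop("one or two cohorts are supported")
  defaults <- list(normalize = list(window_bp = 500000, n_pcs = 50L),
                   call_cnv = list(),
                   associate = list(drop_alpha = 0.05, alpha = 0.05,
                                    max_probes = 20L, min_maf = 0.01),
                   annotate = list(window_bp = 0L, gwas_file = NULL))
  for (nm in names(defaults))
    config[[nm]] <- utils::modifyList(defaults[[nm]],
                                      as.list(config[[nm]]))
  class(config) <- "pipeline_config"
  config
}

#' Run the full analysis pipeline
#'
#' simulate -> normalise (GC + wave correction, LRR PCs) -> call CNVs ->
#' associate (univariate + multivariate signatures, with
#' effective-number-of-tests correction) -> meta/pooled analysis over common
#' probes (two-cohort runs) -> beacon annotation. All stage outputs are
#' written under \code{out_dir} as plain-text TSV/BED and a JSON-like
#' manifest (YAML) records seeds, package version and the MD5 checksum of
#' every output, so a re-run under the same seed is verifiably identical.
#'
#' Association probes are chosen from the called dosages: probes whose CNV
#' allele frequency exceeds \code{associate$min_maf}, capped at
#' \code{associate$max_probes} by descending frequency.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir output directory; overrides \code{config$out_dir}.
#' @return the manifest, invisibly: list with \code{seed, version, outputs}
#'   (data.frame of file names and MD5 checksums) and per-stage summaries.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(unclass(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character()
  emit <- function(writer, obj, file) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  cohort_names <- names(config$cohorts)
  cohorts <- list()
  for (k in seq_along(cohort_names)) {
    cname <- cohort_names[k]
    cohorts[[cname]] <- stage(paste0("simulate:", cname), {
      overrides <- as.list(config$cohorts[[cname]])
      overrides$seed <- overrides$seed %||%
        ((config$seed %% 1000000000L) + 1000L * k)
      for (tab in c("regions", "effect_table"))
        if (!is.null(overrides[[tab]]) && !is.data.frame(overrides[[tab]]))
          overrides[[tab]] <- do.call(
            rbind, lapply(overrides[[tab]], as.data.frame))
      cfg <- do.call(sim_config, overrides)
      sim <- simulate_cohort(cfg, cohort_id = cname)
      emit(write_probe_bed, sim$probe_map, paste0(cname, "_probes.bed"))
      emit(write_matrix_tsv, sim$panel$lrr, paste0(cname, "_lrr.tsv"))
      emit(write_matrix_tsv, sim$panel$baf, paste0(cname, "_baf.tsv"))
      emit(write_matrix_tsv, sim$phenotypes$metabolites,
           paste0(cname, "_metabolites.tsv"))
      sim
    })
  }

  for (cname in cohort_names) {
    cohorts[[cname]] <- stage(paste0("normalize:", cname), {
      sim <- cohorts[[cname]]
      panel <- gc_correct(sim$panel, sim$probe_map)
      panel <- wave_correct(panel, sim$probe_map,
                            window_bp = config$normalize$window_bp)
      pcs <- suppressWarnings(
        compute_lrr_pcs(panel, k = config$normalize$n_pcs))
      sim$panel <- panel
      sim$covariates <- cbind(pcs, sim$phenotypes$covariates)
      emit(write_matrix_tsv, panel$lrr, paste0(cname, "_lrr_corrected.tsv"))
      emit(write_matrix_tsv, sim$covariates, paste0(cname, "_covariates.tsv"))
      sim
    })
  }

  params <- do.call(hmm_params, as.list(config$call_cnv))
  for (cname in cohort_names) {
    cohorts[[cname]] <- stage(paste0("call_cnv:", cname), {
      sim <- cohorts[[cname]]
      calls <- call_cnvs(sim$panel, sim$probe_map, params)
      sim$calls <- calls
      sim$dosages <- expected_genotypes(calls)
      emit(write_segments_bed, calls$segments, paste0(cname, "_segments.bed"))
      emit(write_matrix_tsv, sim$dosages$count_all,
           paste0(cname, "_countall.tsv"))
      sim
    })
  }

  assoc <- list()
  for (cname in cohort_names) {
    assoc[[cname]] <- stage(paste0("associate:", cname), {
      sim <- cohorts[[cname]]
      ca <- sim$dosages$count_all
      freq <- apply(ca, 2L, cnv_allele_frequency)
      sel <- which(freq >= config$associate$min_maf)
      sel <- sel[order(freq[sel], decreasing = TRUE)]
      sel <- utils::head(sel, config$associate$max_probes)
      meff <- effective_tests(stats::cor(sim$phenotypes$metabolites))$m_effective
      uni <- lapply(sel, function(j)
        univariate_assoc(ca[, j], sim$phenotypes, sim$covariates,
                         probe_id = colnames(ca)[j], m_effective = meff,
                         alpha = config$associate$alpha))
      uni <- if (length(uni)) do.call(rbind, uni) else NULL
      sigs <- lapply(sel, function(j)
        multivariate_signature(ca[, j], sim$phenotypes, sim$covariates,
                               drop_alpha = config$associate$drop_alpha,
                               probe_id = colnames(ca)[j],
                               m_effective = meff))
      if (!is.null(uni)) {
        path <- file.path(out_dir, paste0(cname, "_univariate.tsv"))
        utils::write.table(uni, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs <- c(outputs, path)
      }
      list(probes = colnames(ca)[sel], univariate = uni, signatures = sigs,
           m_effective = meff)
    })
  }

  meta <- NULL
  if (length(cohort_names) == 2L) {
    meta <- stage("meta", {
      a <- cohort_names[1L]; b <- cohort_names[2L]
      cp <- common_probes(cohorts[[a]]$probe_map, cohorts[[b]]$probe_map)
      ra <- assoc[[a]]$univariate; rb <- assoc[[b]]$univariate
      if (!is.null(ra) && !is.null(rb)) {
        ra <- ra[ra$probe_id %in% cp$probe_id_a, , drop = FALSE]
        rb <- rb[rb$probe_id %in% cp$probe_id_b, , drop = FALSE]
        # harmonise probe naming across cohorts via genomic position
        rb$probe_id <- cp$probe_id_a[match(rb$probe_id, cp$probe_id_b)]
        mm <- meta_analyze(ra, rb)
        path <- file.path(out_dir, "meta.tsv")
        utils::write.table(mm, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs <- c(outputs, path)
        mm
      } else NULL
    })
  }

  beacon <- stage("annotate", {
    first <- cohort_names[1L]
    gwas <- NULL
    if (!is.null(config$annotate$gwas_file)) {
      if (!file.exists(config$annotate$gwas_file))
        stop("GWAS file not found: ", config$annotate$gwas_file)
      gwas <- utils::read.delim(config$annotate$gwas_file,
                                stringsAsFactors = FALSE)
    }
    matches <- if (!is.null(gwas))
      match_by_position(cohorts[[first]]$probe_map, gwas,
                        window_bp = config$annotate$window_bp) else NULL
    segs <- lapply(cohorts, function(s) s$calls$segments)
    bt <- build_beacon(cohorts[[first]]$probe_map,
                       signatures = assoc[[first]]$univariate,
                       segments = segs, matches = matches)
    path <- file.path(out_dir, "beacon.tsv")
    utils::write.table(bt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, path)
    bt
  })

  manifest <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("cnvmetabo")),
    outputs = data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE),
    n_segments = vapply(cohorts, function(s) nrow(s$calls$segments), 0L),
    association_probes = lapply(assoc, `[[`, "probes"),
    n_meta_records = if (is.null(meta)) 0L else nrow(meta),
    beacon_flag_totals = colSums(beacon[, -(1:3), drop = FALSE]))
  yaml::write_yaml(
    list(seed = manifest$seed, version = manifest$version,
         outputs = stats::setNames(as.list(manifest$outputs$md5),
                                   manifest$outputs$file)),
    file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
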