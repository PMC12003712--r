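#' Match external GWAS records to probes by genomic position
#'
#' Variant-agnostic juxtaposition: a GWAS summary-statistic row matches a
#' probe when both lie on the same chromosome and their positions differ by
#' at most \code{window_bp} (default 0 = exact position). The rsid is
#' carried through but never used for matching. Matching runs as a linear
#' merge over the position-sorted inputs; unsorted inputs are sorted
#' internally with a warning. All matches are returned (many-to-many).
#'
#' @param probes a probe map (\code{probe_id, chrom, pos}).
#' @param gwas data.frame of GWAS records with \code{chrom, pos} and
#'   typically \code{rsid, p, maf, group}.
#' @param window_bp maximum absolute position difference in basepairs.
#' @return data.frame with one row per (probe, record) pair:
#'   \code{probe_id, chrom, probe_pos, gwas_pos, distance} plus the extra
#'   GWAS columns.
#' @export
match_by_position <- function(probes, gwas, window_bp = 0L) {
  stopifnot(window_bp >= 0)
  gwas <- as.data.frame(gwas)
  extra <- setdiff(names(gwas), c("chrom", "pos"))
  out <- list()
  for (cc in intersect(unique(probes$chrom), unique(gwas$chrom))) {
    pp <- probes[probes$chrom == cc, , drop = FALSE]
    gg <- gwas[gwas$chrom == cc, , drop = FALSE]
    if (is.unsorted(pp$pos)) {
      warning("probes not position-sorted on chromosome ", cc,
              "; sorting internally")
      pp <- pp[order(pp$pos), , drop = FALSE]
    }
    if (is.unsorted(gg$pos)) {
      warning("GWAS records not position-sorted on chromosome ", cc,
              "; sorting internally")
      gg <- gg[order(gg$pos), , drop = FALSE]
    }
    # linear merge: for each record, the probe run within the window
    lo <- findInterval(gg$pos - window_bp - 0.5, pp$pos) + 1L
    hi <- findInterval(gg$pos + window_bp + 0.5, pp$pos)
    take <- hi >= lo
    if (!any(take)) next
    reps <- pmax(hi - lo + 1L, 0L)
    gi <- rep(seq_len(nrow(gg)), reps)
    pi <- sequence(reps[take]) + rep(lo[take] - 1L, reps[take])
    m <- data.frame(probe_id = pp$probe_id[pi], chrom = cc,
                    probe_pos = pp$pos[pi], gwas_pos = gg$pos[gi],
                    distance = abs(pp$pos[pi] - gg$pos[gi]),
                    stringsAsFactors = FALSE)
    for (col in extra) m[[col]] <- gg[[col]][gi]
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) {
    m <- data.frame(probe_id = character(), chrom = character(),
                    probe_pos = integer(), gwas_pos = integer(),
                    distance = integer(), stringsAsFactors = FALSE)
    for (col in extra) m[[col]] <- gwas[[col]][0]
    return(m)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the beacon cross-reference table
#'
#' One row per probe with binary evidence flags: reportable metabolomic
#' signature, reportable LRR signature, CNV segment presence per cohort,
#' external GWAS overlap, plus any extra evidence tables supplied as
#' probe-id vectors. Every flag name must be registered in the schema.
#'
#' @param probes a probe map.
#' @param signatures,lrr_signatures association record data.frames
#'   (flagged at probes with any \code{reportable} record), or NULL.
#' @param segments named list of per-cohort segment data.frames from
#'   [viterbi_segments()]/[call_cnvs()]; a probe is flagged for a cohort
#'   when any segment spans its position.
#' @param matches GWAS matches from [match_by_position()], or NULL.
#' @param extra_evidence named list of probe_id character vectors for
#'   additional annotation sources (flag = 1 iff the probe appears).
#' @param flag_schema character vector of permitted flag names; defaults
#'   to exactly the flags implied by the supplied evidence. Any evidence
#'   flag not in the schema is an error.
#' @return data.frame: \code{probe_id, chrom, pos} plus one 0/1 integer
#'   column per flag.
#' @export
build_beacon <- function(probes, signatures = NULL, lrr_signatures = NULL,
                         segments = list(), matches = NULL,
                         extra_evidence = list(), flag_schema = NULL) {
  flags <- list()
  reportable_ids <- function(recs) {
    if (is.null(recs) || !nrow(recs)) return(character())
    unique(recs$probe_id[recs$reportable %in% TRUE])
  }
  flags[["metabolomic_signature"]] <- reportable_ids(signatures)
  flags[["lrr_signature"]] <- reportable_ids(lrr_signatures)
  if (length(segments)) {
    if (is.null(names(segments)) || any(names(segments) == ""))
      stop("segments must be a named list (one entry per cohort)")
    for (cohort in names(segments)) {
      seg <- segments[[cohort]]
      hit <- character()
      if (!is.null(seg) && nrow(seg)) {
        for (k in seq_len(nrow(seg))) {
          inside <- probes$chrom == seg$chrom[k] &
            probes$pos >= seg$start_pos[k] & probes$pos <= seg$end_pos[k]
          hit <- c(hit, probes$probe_id[inside])
        }
      }
      flags[[paste0("cnv_", cohort)]] <- unique(hit)
    }
  }
  flags[["gwas_overlap"]] <-
    if (is.null(matches) || !nrow(matches)) character()
  else unique(matches$probe_id)
  for (nm in names(extra_evidence))
    flags[[nm]] <- unique(as.character(extra_evidence[[nm]]))
  if (is.null(flag_schema)) flag_schema <- names(flags)
  unknown <- setdiff(names(flags), flag_schema)
  if (length(unknown))
    stop("flag name(s) not registered in the schema: ",
         paste(unknown, collapse = ", "))
  beacon <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                       pos = probes$pos, stringsAsFactors = FALSE)
  for (nm in names(flags))
    beacon[[nm]] <- as.integer(probes$probe_id %in% flags[[nm]])
  beacon
}

#' Rank matched GWAS loci
#'
#' Orders position-matched GWAS records by ascending p-value, breaking ties
#' deterministically by (chrom, pos), and adds a \code{rank} column.
#'
#' @param matches data.frame from [match_by_position()] with a \code{p}
#'   column.
#' @return the same rows ordered by significance with \code{rank} prepended.
#' @export
rank_matched_loci <- function(matches) {
  if (is.null(matches) || !nrow(matches)) stop("no matches to rank")
  if (!"p" %in% names(matches)) stop("matches need a p column")
  ord <- order(matches$p, matches$chrom, matches$gwas_pos)
  out <- matches[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
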