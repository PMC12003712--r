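#' Read and write the package's plain-text interchange formats
#'
#' Probe maps travel as BED-like TSV (chrom, start = pos - 1, end = pos,
#' probe_id, gc_fraction; 0-based half-open on disk, 1-based inclusive in
#' memory). Sample-by-feature matrices (LRR, BAF, metabolites, dosages,
#' covariates) travel as TSV with a header row of feature IDs and a first
#' column of sample IDs. CNV segments are written as BED with
#' name = sample:state and score = round(mean_posterior * 1000).
#'
#' @param probe_map,x,segments objects to write.
#' @param path file path.
#' @name cnvmetabo_io
NULL

#' @rdname cnvmetabo_io
#' @export
write_probe_bed <- function(probe_map, path) {
  bed <- data.frame(chrom = probe_map$chrom,
                    start = probe_map$pos - 1L, end = probe_map$pos,
                    probe_id = probe_map$probe_id,
                    gc_fraction = probe_map$gc_fraction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname cnvmetabo_io
#' @export
read_probe_bed <- function(path) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE)
  pm <- data.frame(probe_id = bed$probe_id, chrom = as.character(bed$chrom),
                   pos = as.integer(bed$end), gc_fraction = bed$gc_fraction,
                   stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' @rdname cnvmetabo_io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cnvmetabo_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname cnvmetabo_io
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_pos - 1L, end = segments$end_pos,
                    name = paste0(segments$sample_id, ":", segments$state),
                    score = round(segments$mean_posterior * 1000))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
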