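# Tab-delimited I/O for the pipeline's standard artifacts. Genes as rows,
# first column gene_id (or family_id); UTF-8 throughout.

#' Write a counts object to a directory of TSV files
#'
#' Emits `counts_unique.tsv` (gene x sample), `counts_ambiguous.tsv`
#' (duplicate family x sample) and `samples.tsv` (the sample sheet).
#'
#' @param counts an `iso_counts`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(counts$unique, file.path(dir, "counts_unique.tsv"), "gene_id")
  write_matrix_tsv(counts$ambiguous, file.path(dir, "counts_ambiguous.tsv"),
                   "family_id")
  utils::write.table(counts$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a counts directory written by [write_counts()]
#' @param dir directory containing the TSV files
#' @param annotation the matching `iso_annotation`
#' @return an `iso_counts` (without planted truth)
#' @export
read_counts <- function(dir, annotation) {
  uniq <- read_matrix_tsv(file.path(dir, "counts_unique.tsv"))
  amb <- read_matrix_tsv(file.path(dir, "counts_ambiguous.tsv"))
  samples <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  rownames(samples) <- samples$sample_id
  stopifnot(identical(colnames(uniq), samples$sample_id))
  structure(list(unique = uniq, ambiguous = amb, samples = samples,
                 annotation = annotation, truth = NULL),
            class = "iso_counts")
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an RPKM matrix (and optional levels) as TSV
#' @param expr an `iso_expr`
#' @param path output TSV
#' @param levels_path optional TSV for the 7-level ordinal binning
#' @return `path`, invisibly
#' @export
write_rpkm <- function(expr, path, levels_path = NULL) {
  write_matrix_tsv(round(expr$rpkm, 4), path, "gene_id")
  if (!is.null(levels_path)) {
    write_matrix_tsv(bin_expression(expr$rpkm), levels_path, "gene_id")
  }
  invisible(path)
}
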