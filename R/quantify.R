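#' Resolve duplicate-family ambiguous counts into per-gene assigned counts
#'
#' Reproduces the three alignment-quantification modes:
#' \describe{
#'   \item{unique}{discard the ambiguous component entirely -- the model of
#'     the MQ < 5 filter that keeps only uniquely mapping reads.}
#'   \item{all}{add each family's ambiguous count in full to every member
#'     ("All Alignments" counting).}
#'   \item{best}{split each family's ambiguous count equally among members
#'     (the deterministic expectation of an aligner's arbitrary best-hit
#'     choice); fractional shares are rounded half-to-even on the running
#'     cumulative so totals are conserved exactly.}
#' }
#'
#' @param counts an `iso_counts`
#' @param mode "best" (default), "all" or "unique"
#' @return gene x sample matrix of assigned counts
#' @export
assign_counts <- function(counts, mode = c("best", "all", "unique")) {
  mode <- match.arg(mode)
  out <- counts$unique * 1.0
  if (mode == "unique" || nrow(counts$ambiguous) == 0) return(out)
  fams <- duplicate_families(counts$annotation)
  for (f in unique(fams$family)) {
    members <- fams$gene_id[fams$family == f]
    amb <- counts$ambiguous[f, ]
    if (mode == "all") {
      out[members, ] <- out[members, ] + rep(amb, each = length(members))
    } else {
      shares <- vapply(amb, function(a) {
        round_cumulative(rep(a / length(members), length(members)))
      }, numeric(length(members)))
      out[members, ] <- out[members, ] + shares
    }
  }
  out
}

#' Compute RPKM from assigned counts
#'
#' rpkm = count / (length_kb * mapped_millions), with the per-sample
#' denominator the total of assigned counts in scope (default: all CDS-
#' assigned counts of that sample).
#'
#' @param assigned gene x sample matrix from [assign_counts()]
#' @param lengths named per-gene CDS lengths in bp
#' @param denominator optional per-sample totals overriding the default
#' @return object of class `iso_expr`: list(rpkm = gene x sample matrix,
#'   mapped = per-sample denominator)
#' @export
compute_rpkm <- function(assigned, lengths, denominator = NULL) {
  lengths <- lengths[rownames(assigned)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("every gene needs a positive length", call. = FALSE)
  }
  den <- denominator %||% colSums(assigned)
  if (any(den == 0)) {
    stop("zero mapped-read denominator for sample(s): ",
         paste(colnames(assigned)[den == 0], collapse = ", "), call. = FALSE)
  }
  rpkm <- assigned / (lengths / 1000) / rep(den / 1e6, each = nrow(assigned))
  structure(list(rpkm = rpkm, mapped = den), class = "iso_expr")
}

#' Default expression-level bin edges
#'
#' The geometric ladder 2.5 x 5^k (k = 0..5): 2.5, 12.5, 62.5, 312.5,
#' 1562.5, 7812.5 RPKM, defining seven ordinal levels from
#' "not transcribed" (< 2.5) to "very highly transcribed" (> 7812.5).
#' @return numeric vector of 6 edges
#' @export
expression_bin_edges <- function() 2.5 * 5^(0:5)

#' Bin RPKM values into the seven ordinal expression levels
#'
#' Edges are exclusive upper bounds of the level below ("not transcribed"
#' is < 2.5 RPKM), so a value equal to an edge falls in the lower level.
#'
#' @param rpkm numeric vector or matrix of RPKM values
#' @param edges bin edges (default [expression_bin_edges()])
#' @return integer levels 1--7, same shape as `rpkm`
#' @export
bin_expression <- function(rpkm, edges = expression_bin_edges()) {
  if (any(rpkm < 0, na.rm = TRUE)) stop("negative RPKM", call. = FALSE)
  lev <- findInterval(rpkm, edges, left.open = TRUE) + 1L
  attributes(lev) <- attributes(rpkm)
  lev
}

#' Names of the seven expression levels
#' @return character vector of length 7
#' @export
expression_level_names <- function() {
  c("not transcribed", "very low", "low", "moderate", "high",
    "highly transcribed", "very highly transcribed")
}

#' Fraction of a sample's transcriptome attributed to a gene set
#'
#' @param assigned gene x sample matrix of assigned counts
#' @param gene_set non-empty character vector of gene ids
#' @return per-sample percentages (named numeric)
#' @export
transcriptome_fraction <- function(assigned, gene_set) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty", call. = FALSE)
  missing <- setdiff(gene_set, rownames(assigned))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  tot <- colSums(assigned)
  100 * colSums(assigned[gene_set, , drop = FALSE]) / tot
}

#' Family-level aggregate counts (duplicate copies considered together)
#'
#' Sums the unique counts of each duplicate family's members with the
#' family's ambiguous count -- the "expression of these duplicates was
#' considered together" view used for the 99%-identical gene pairs.
#'
#' @param counts an `iso_counts`
#' @return family x sample matrix
#' @export
family_counts <- function(counts) {
  fams <- duplicate_families(counts$annotation)
  t(vapply(unique(fams$family), function(f) {
    members <- fams$gene_id[fams$family == f]
    colSums(counts$unique[members, , drop = FALSE]) + counts$ambiguous[f, ]
  }, numeric(ncol(counts$unique))))
}
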