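#' Sample cross-correlation matrix
#'
#' Pearson correlation between sample columns of log10(RPKM + 1) (the
#' declared default transform; `raw` correlates RPKM directly). Constant
#' columns have undefined correlation; they are flagged and treated as 0
#' so the depth/correlation filter removes them.
#'
#' @param expr an `iso_expr` (or a bare RPKM matrix)
#' @param transform "log10p1" (default) or "raw"
#' @return sample x sample correlation matrix
#' @export
correlation_matrix <- function(expr, transform = c("log10p1", "raw")) {
  transform <- match.arg(transform)
  m <- if (inherits(expr, "iso_expr")) expr$rpkm else expr
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  x <- if (transform == "log10p1") log10(m + 1) else m
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  R <- suppressWarnings(stats::cor(x))
  R[constant, ] <- 0; R[, constant] <- 0
  diag(R) <- 1
  R
}

#' Depth and replicate-correlation sample filtering
#'
#' Two passes, mirroring the experiment's QC: (1) drop samples whose total
#' assigned counts fall below `min_depth` (two million reads); (2) within
#' each replicate group (substrate, timepoint, strain), drop every sample
#' whose maximum correlation against its surviving same-group replicates is
#' below `min_R`, iterating until stable. A sample left without any group
#' partner is kept (nothing to compare against) and a warning is recorded
#' in the report.
#'
#' @param counts an `iso_counts`
#' @param expr matching `iso_expr` (RPKM); computed from mode="best"
#'   assigned counts if omitted
#' @param min_depth minimum total assigned counts (default 2e6)
#' @param min_R minimum within-group correlation (default 0.8)
#' @param transform correlation transform, see [correlation_matrix()]
#' @return list of class `iso_qc`: `retained` (sample ids), `report`
#'   (data.frame sample_id, depth, max_group_R, retained, reason),
#'   `correlation` (full matrix), `warnings`
#' @export
filter_samples <- function(counts, expr = NULL, min_depth = 2e6, min_R = 0.8,
                           transform = "log10p1") {
  if (is.null(expr)) {
    assigned <- assign_counts(counts, "best")
    lengths <- stats::setNames(counts$annotation$genes$length,
                               counts$annotation$genes$gene_id)
    expr <- compute_rpkm(assigned, lengths)
  }
  samples <- counts$samples
  depth <- colSums(counts$unique) + if (nrow(counts$ambiguous))
    colSums(counts$ambiguous) else 0
  R <- correlation_matrix(expr, transform)

  reason <- stats::setNames(rep("ok", nrow(samples)), samples$sample_id)
  reason[depth < min_depth] <- "low_depth"
  grp <- interaction(samples$substrate, samples$timepoint, samples$strain,
                     drop = TRUE)
  warnings <- character()
  repeat {
    alive <- names(reason)[reason == "ok"]
    max_r <- stats::setNames(rep(NA_real_, length(alive)), alive)
    drop <- character()
    for (g in levels(grp)) {
      members <- intersect(samples$sample_id[grp == g], alive)
      if (length(members) < 2) {
        if (length(members) == 1)
          warnings <- unique(c(warnings, paste0(
            "replicate group ", g, " reduced to a single sample")))
        next
      }
      for (s in members) {
        max_r[s] <- max(R[s, setdiff(members, s)])
        if (max_r[s] < min_R) drop <- c(drop, s)
      }
    }
    if (!length(drop)) { final_max_r <- max_r; break }
    reason[drop] <- "low_correlation"
  }

  report <- data.frame(
    sample_id = samples$sample_id,
    depth = depth[samples$sample_id],
    max_group_R = final_max_r[samples$sample_id],
    retained = reason[samples$sample_id] == "ok",
    reason = unname(reason[samples$sample_id]),
    stringsAsFactors = FALSE)
  structure(list(retained = samples$sample_id[report$retained],
                 report = report, correlation = R, warnings = warnings),
            class = "iso_qc")
}

#' @export
print.iso_qc <- function(x, ...) {
  cat("iso_qc:", sum(x$report$retained), "of", nrow(x$report),
      "samples retained\n")
  dropped <- x$report[!x$report$retained, c("sample_id", "reason")]
  if (nrow(dropped)) print(dropped, row.names = FALSE)
  invisible(x)
}

#' Per-gene relative standard deviation within a replicate group
#'
#' RSD = 100 * sd / mean (sample sd, n - 1 denominator) across the named
#' samples. Genes with zero mean are undefined (NA) and excluded from any
#' summary.
#'
#' @param expr an `iso_expr` or RPKM matrix
#' @param group character vector of >= 2 sample ids
#' @return named per-gene RSD in percent
#' @export
replicate_rsd <- function(expr, group) {
  m <- if (inherits(expr, "iso_expr")) expr$rpkm else expr
  if (length(group) < 2) stop("replicate group must have >= 2 samples", call. = FALSE)
  m <- m[, group, drop = FALSE]
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  out <- 100 * sd / mu
  out[mu == 0] <- NA_real_
  out
}
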