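#' Replicate-mean expression per design cell
#'
#' Arithmetic mean RPKM per gene for each (substrate, timepoint, strain)
#' cell over retained samples. Because all T0 samples are drawn before
#' substrate addition and are identically treated, the T0 cells are pooled
#' across substrate arms by default (one "T0" cell per strain, 15
#' replicates in the full design).
#'
#' @param expr an `iso_expr` or RPKM matrix
#' @param meta sample metadata (data.frame with sample_id, substrate,
#'   timepoint, strain), typically `counts$samples` restricted to retained
#'   samples
#' @param pool_t0 pool T0 across substrate arms? (default TRUE)
#' @return object of class `iso_means`: list(means = gene x cell matrix,
#'   cells = data.frame(cell, substrate, timepoint, strain, n))
#' @export
condition_means <- function(expr, meta, pool_t0 = TRUE) {
  m <- if (inherits(expr, "iso_expr")) expr$rpkm else expr
  meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  key <- ifelse(pool_t0 & meta$timepoint == "T0",
                paste0("T0.", meta$strain),
                paste(meta$substrate, meta$timepoint, meta$strain, sep = "."))
  groups <- split(meta$sample_id, key)
  means <- vapply(groups, function(s) rowMeans(m[, s, drop = FALSE]),
                  numeric(nrow(m)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(m), names(groups)))
  }
  info <- do.call(rbind, lapply(names(groups), function(k) {
    mm <- meta[meta$sample_id %in% groups[[k]], ]
    data.frame(cell = k,
               substrate = if (startsWith(k, "T0.")) "pooled" else mm$substrate[1],
               timepoint = mm$timepoint[1], strain = mm$strain[1],
               n = length(groups[[k]]), stringsAsFactors = FALSE)
  }))
  structure(list(means = means, cells = info, pool_t0 = pool_t0),
            class = "iso_means")
}

# Resolve a cell label like c("isoprene", "T5") or "T0" against an
# iso_means object; errors with the cell name if absent.
cell_column <- function(means, substrate, timepoint, strain = NULL) {
  strain <- strain %||% means$cells$strain[1]
  lab <- if (timepoint == "T0" && means$pool_t0) paste0("T0.", strain)
         else paste(substrate, timepoint, strain, sep = ".")
  if (!lab %in% colnames(means$means)) {
    stop("required condition cell missing: ", lab, call. = FALSE)
  }
  means$means[, lab]
}

#' Per-gene fold change between two condition cells
#'
#' F = mean_numerator / max(mean_denominator, floor). The floor (default
#' 2.5 RPKM, the lower edge of the "not transcribed" class) keeps fold
#' changes of silent genes finite.
#'
#' @param means an `iso_means`
#' @param num,den length-2 character vectors c(substrate, timepoint), or
#'   "T0" for the pooled baseline
#' @param floor denominator floor in RPKM
#' @param strain strain whose cells to use (default: the object's strain)
#' @return named per-gene fold changes
#' @export
fold_change <- function(means, num, den, floor = 2.5, strain = NULL) {
  get <- function(cell) {
    if (identical(cell, "T0")) cell_column(means, "pooled", "T0", strain)
    else cell_column(means, cell[1], cell[2], strain)
  }
  get(num) / pmax(get(den), floor)
}

#' Housekeeping fold-range calibration
#'
#' For each housekeeping gene, the ratio of its maximum to minimum
#' condition mean across all cells; the derived minimum factor is the
#' largest such ratio rounded up to the next integer. The experiment's
#' reference genes stayed within an approximately fourfold range, which is
#' the empirical justification for the fourfold calling threshold. A
#' warning is issued if the derived factor exceeds `threshold`.
#'
#' @param means an `iso_means`
#' @param hk_genes housekeeping gene ids (default rpoB, gyrA, gmk)
#' @param threshold the calling threshold to compare against (default 4)
#' @return list(ratios, minimum_factor)
#' @export
housekeeping_range <- function(means, hk_genes = housekeeping_genes(),
                               threshold = 4) {
  missing <- setdiff(hk_genes, rownames(means$means))
  if (length(missing)) stop("housekeeping gene(s) absent: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  m <- means$means[hk_genes, , drop = FALSE]
  ratios <- apply(m, 1, function(v) max(v) / min(v))
  factor <- ceiling(max(ratios))
  if (factor > threshold) {
    warning("housekeeping range ", factor,
            " exceeds the calling threshold ", threshold, call. = FALSE)
  }
  list(ratios = ratios, minimum_factor = factor)
}

#' Call substrate-responsive genes by the multi-control fourfold criterion
#'
#' A gene is isoprene-responsive when its isoprene-T5 mean is at least
#' `threshold`-fold above (a) the pooled T0 baseline and (b) the succinate
#' and no-substrate controls at the same time point;
#' epoxyisoprene-responsive analogously at T3. `responsive` is the
#' conjunction of the two arms -- the rule that returned exactly the 22
#' contiguous cluster genes in the experiment. `controls = "either"`
#' relaxes (b) to a disjunction over the two controls.
#'
#' @param means an `iso_means` over retained samples
#' @param threshold fold threshold (default 4)
#' @param floor denominator floor in RPKM (default 2.5)
#' @param controls "both" (default) or "either"
#' @return object of class `iso_calls`: data.frame with per-gene fold
#'   changes for all six contrasts and logical columns iso_responsive,
#'   epoxy_responsive, responsive; threshold/floor/controls as attributes
#' @export
call_responsive <- function(means, threshold = 4, floor = 2.5,
                            controls = c("both", "either")) {
  controls <- match.arg(controls)
  F_iso_t0 <- fold_change(means, c("isoprene", "T5"), "T0", floor)
  F_iso_succ <- fold_change(means, c("isoprene", "T5"), c("succinate", "T5"), floor)
  F_iso_none <- fold_change(means, c("isoprene", "T5"), c("none", "T5"), floor)
  F_epo_t0 <- fold_change(means, c("epoxyisoprene", "T3"), "T0", floor)
  F_epo_succ <- fold_change(means, c("epoxyisoprene", "T3"), c("succinate", "T3"), floor)
  F_epo_none <- fold_change(means, c("epoxyisoprene", "T3"), c("none", "T3"), floor)
  comb <- if (controls == "both") `&` else `|`
  iso <- F_iso_t0 >= threshold &
    comb(F_iso_succ >= threshold, F_iso_none >= threshold)
  epo <- F_epo_t0 >= threshold &
    comb(F_epo_succ >= threshold, F_epo_none >= threshold)
  out <- data.frame(
    gene_id = names(F_iso_t0),
    F_iso_t0 = unname(F_iso_t0), F_iso_succ = unname(F_iso_succ),
    F_iso_none = unname(F_iso_none),
    F_epo_t0 = unname(F_epo_t0), F_epo_succ = unname(F_epo_succ),
    F_epo_none = unname(F_epo_none),
    iso_responsive = unname(iso), epoxy_responsive = unname(epo),
    responsive = unname(iso & epo),
    stringsAsFactors = FALSE)
  rownames(out) <- out$gene_id
  attr(out, "threshold") <- threshold
  attr(out, "floor") <- floor
  attr(out, "controls") <- controls
  class(out) <- c("iso_calls", "data.frame")
  out
}

#' Call epoxyisoprene-only genes
#'
#' Genes at least `threshold`-fold above T0 at one or more of T1--T3 under
#' epoxyisoprene, excluding genes that look isoprene-responsive against the
#' matched-timepoint controls (F(iso T5 / succinate T5) or
#' F(iso T5 / none T5) at or above the threshold). These are stress or
#' starvation responders, disjoint from the substrate-responsive set by
#' construction.
#'
#' @inheritParams call_responsive
#' @return character vector of gene ids; the per-gene max fold over T1--T3
#'   is attached as attribute `max_fold`
#' @export
call_epoxy_only <- function(means, threshold = 4, floor = 2.5) {
  fmax <- pmax(
    fold_change(means, c("epoxyisoprene", "T1"), "T0", floor),
    fold_change(means, c("epoxyisoprene", "T2"), "T0", floor),
    fold_change(means, c("epoxyisoprene", "T3"), "T0", floor))
  F_iso_succ <- fold_change(means, c("isoprene", "T5"), c("succinate", "T5"), floor)
  F_iso_none <- fold_change(means, c("isoprene", "T5"), c("none", "T5"), floor)
  sel <- fmax >= threshold & F_iso_succ < threshold & F_iso_none < threshold
  out <- names(fmax)[sel]
  attr(out, "max_fold") <- fmax[sel]
  out
}

#' Wild-type vs IsoMO-mutant inducer contrast
#'
#' For the genes called responsive in the wild type, asks whether the
#' isoA-deletion strain still induces them (max fold over T1--T5 vs its own
#' T0) under isoprene and under epoxyisoprene. Induction under
#' epoxyisoprene but not isoprene means the inducer is epoxyisoprene or a
#' later metabolite, not isoprene itself ("downstream-metabolite-induced").
#'
#' @param wt_calls an `iso_calls` from the wild-type data
#' @param mutant_means an `iso_means` from delta_isoA data (must contain
#'   isoprene and epoxyisoprene arms)
#' @param threshold fold threshold (default 4)
#' @param floor denominator floor in RPKM
#' @return list(verdict, genes = per-gene data.frame with mutant max folds
#'   and per-gene verdicts). Verdicts: "downstream-metabolite-induced"
#'   (epoxy passes, isoprene fails), "isoprene-induced" (the reverse),
#'   "inconclusive" (both pass), "non-inducible" (neither).
#' @export
strain_contrast <- function(wt_calls, mutant_means, threshold = 4, floor = 2.5) {
  genes <- wt_calls$gene_id[wt_calls$responsive]
  arm_max <- function(substrate) {
    f <- do.call(pmax, lapply(paste0("T", 1:5), function(tp) {
      fold_change(mutant_means, c(substrate, tp), "T0", floor)
    }))
    f[genes]
  }
  iso <- arm_max("isoprene")
  epo <- arm_max("epoxyisoprene")
  verdict_one <- function(i, e) {
    if (e && !i) "downstream-metabolite-induced"
    else if (i && !e) "isoprene-induced"
    else if (i && e) "inconclusive" else "non-inducible"
  }
  per_gene <- mapply(verdict_one, iso >= threshold, epo >= threshold)
  tab <- sort(table(per_gene), decreasing = TRUE)
  list(verdict = names(tab)[1],
       genes = data.frame(gene_id = genes, F_mut_iso = unname(iso),
                          F_mut_epoxy = unname(epo),
                          verdict = unname(per_gene),
                          stringsAsFactors = FALSE))
}
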