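#!/usr/bin/env Rscript
# Stage 3: housekeeping calibration and responsive-gene calling.
#
# Condition means over retained samples (T0 pooled across arms), the
# housekeeping fold-range that justifies the fourfold threshold, the
# multi-control responsive set, the epoxyisoprene-only set, and the
# cluster's share of the transcriptome in isoprene-T5 samples.

suppressPackageStartupMessages(library(isoswitch))
datadir <- "results/data"
ann <- read_annotation_gff3(file.path(datadir, "annotation.gff3"))
counts <- read_counts(file.path(datadir, "counts"), ann)
assigned <- assign_counts(counts, "best")
expr <- compute_rpkm(assigned, setNames(ann$genes$length, ann$genes$gene_id))
qc <- filter_samples(counts, expr)
meta <- counts$samples[counts$samples$sample_id %in% qc$retained, ]

means <- condition_means(expr, meta)
calib <- housekeeping_range(means)
cat(sprintf("housekeeping max/min ratios: %s -> minimum factor %d\n",
            paste(sprintf("%s %.2f", names(calib$ratios), calib$ratios),
                  collapse = ", "),
            calib$minimum_factor))

calls <- call_responsive(means)
eo <- call_epoxy_only(means)
cat(sprintf("responsive genes: %d (%s...)\n", sum(calls$responsive),
            paste(head(sort(calls$gene_id[calls$responsive]), 5), collapse = ", ")))
cat(sprintf("epoxyisoprene-only genes: %d\n", length(eo)))

iso_t5 <- intersect(meta$sample_id[meta$substrate == "isoprene" &
                                     meta$timepoint == "T5"], qc$retained)
frac <- transcriptome_fraction(assigned[, iso_t5, drop = FALSE], cluster_genes())
cat(sprintf("cluster transcriptome share at isoprene T5: %.1f-%.1f%%\n",
            min(frac), max(frac)))

utils::write.table(as.data.frame(calls), "results/calls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(housekeeping_ratios = as.list(round(calib$ratios, 3)),
       minimum_factor = calib$minimum_factor,
       n_responsive = sum(calls$responsive),
       responsive = sort(calls$gene_id[calls$responsive]),
       n_epoxy_only = length(eo), epoxy_only = sort(as.character(eo)),
       cluster_fraction_iso_t5 = as.list(round(frac, 2))),
  "results/calling_summary.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)
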