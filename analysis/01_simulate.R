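#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic substrate-switch dataset.
#
# Builds the AD45-like annotation (6,279 CDS, 321 on the ~300 kbp plasmid,
# the 22-gene responsive cluster with its duplicated isoGHIJ pairs), the
# 90-sample count matrix with planted induction kinetics, and the planted
# QC failures, and writes everything under results/data/.

suppressPackageStartupMessages(library(isoswitch))
seed <- 42L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ann <- make_annotation(seed = seed)
cat(sprintf("annotation: %d genes (%d plasmid, %d cluster, %d epoxy-only)\n",
            nrow(ann$genes), sum(ann$genes$replicon_id == "plasmid"),
            sum(ann$genes$role == "cluster"),
            sum(ann$genes$role == "epoxy_only")))
write_annotation_gff3(ann, file.path(outdir, "annotation.gff3"))

profile <- default_effect_profile(ann, seed = seed + 1L)
counts <- simulate_counts(ann, design_spec(), profile, seed = seed + 2L)
counts <- inject_qc_failures(counts, default_failure_spec(), seed = seed + 3L)
write_counts(counts, file.path(outdir, "counts"))

tr <- simulate_coverage(ann, seed = seed + 4L)
write_coverage_bedgraph(tr, file.path(outdir, "coverage_plasmid.bedGraph"))

truth <- counts$truth
truth$expected_rpkm <- NULL  # large; reproducible from the profile
jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

tot <- colSums(counts$unique) + colSums(counts$ambiguous)
cat(sprintf("samples: %d, depth %.1f-%.1f M (planted failures: %s)\n",
            ncol(counts$unique), min(tot) / 1e6, max(tot) / 1e6,
            paste(default_failure_spec()$sample_id, collapse = ", ")))
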