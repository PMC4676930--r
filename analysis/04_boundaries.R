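#!/usr/bin/env Rscript
# Stage 4: transcription boundaries and operon structure.
#
# Runs the windowed step detector on the simulated plasmid coverage track
# and classifies the isoGHIJABCDEF run and the SZ00_06083 single unit.

suppressPackageStartupMessages(library(isoswitch))
ann <- read_annotation_gff3("results/data/annotation.gff3")
tr <- read_coverage_bedgraph("results/data/coverage_plasmid.bedGraph")
tr$replicon <- "plasmid"

calls <- detect_steps(tr, ann)
cat(sprintf("%d boundary calls (%d TSS, %d terminators)\n", nrow(calls),
            sum(calls$type == "TSS"), sum(calls$type == "terminator")))
print(calls)

operon <- classify_operon(ann, calls, c("isoG", "isoH", "isoI", "isoJ",
                                        "isoA", "isoB", "isoC", "isoD",
                                        "isoE", "isoF"))
cat(sprintf("isoGHIJABCDEF co-transcribed: %s, leading TSS %d bp upstream of isoG\n",
            operon$co_transcribed, operon$leading_offset))
single <- classify_operon(ann, calls, "SZ00_06083")
cat(sprintf("SZ00_06083 single unit: %s (own TSS at %s)\n",
            single$co_transcribed, single$leading_tss))

write_boundaries_bed(calls, "plasmid", "results/boundaries.bed")
jsonlite::write_json(
  list(isoG_operon = operon[c("co_transcribed", "leading_tss", "leading_offset")],
       SZ00_06083 = single[c("co_transcribed", "leading_tss", "leading_offset")]),
  "results/operons.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)
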