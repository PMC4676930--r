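#!/usr/bin/env Rscript
# Stage 6: screen genomes for candidate isoprene degraders.
#
# Consumes a precomputed homology hit table (BLAST outfmt-6 style) and
# requires a high-identity isoA homolog and an isoI-like glutathione
# transferase on the same contig in close proximity. The bundled table is
# synthetic, shaped like the published identity landscape.

suppressPackageStartupMessages(library(isoswitch))
hits <- read_homolog_hits(
  system.file("extdata", "homolog_hits_synthetic.tsv", package = "isoswitch"),
  system.file("extdata", "genome_map_synthetic.tsv", package = "isoswitch"))
cand <- screen_genomes(hits)
cat(sprintf("%d candidate isoprene degraders:\n", nrow(cand)))
print(cand[, c("genome", "contig", "isoA_identity", "isoI_identity",
               "separation")])
dir.create("results", showWarnings = FALSE)
utils::write.table(cand, "results/colocalization_candidates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
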