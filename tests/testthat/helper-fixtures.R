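# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# The default study-condition run: 90-sample WT design, planted failures,
# plus the delta_isoA contrast. Used by most downstream tests.
default_run <- function() {
  cached("run42", run_pipeline(seed = 42, mutant = TRUE))
}

default_annotation <- function() default_run()$annotation

# A hand-sized counts object: one duplicate family {g1, g2} plus a
# singleton g3, with arbitrary sample metadata.
toy_counts <- function(unique_counts = cbind(s1 = c(g1 = 10, g2 = 30, g3 = 5)),
                       ambiguous = cbind(s1 = c(fam1 = 60))) {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    locus_tag = c("g1", "g2", "g3"),
    replicon_id = "chr", strand = "+",
    start = c(1, 1001, 2001), end = c(500, 1500, 2800),
    length = c(500L, 500L, 800L),
    duplicate_family = c("fam1", "fam1", NA),
    role = "background", stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  ann <- structure(list(
    replicons = data.frame(replicon_id = "chr", length = 10000L,
                           topology = "linear", stringsAsFactors = FALSE),
    genes = genes), class = "iso_annotation")
  samples <- data.frame(sample_id = colnames(unique_counts),
                        substrate = "none", timepoint = "T0",
                        minutes = 0, replicate = seq_len(ncol(unique_counts)),
                        strain = "WT", stringsAsFactors = FALSE)
  structure(list(unique = unique_counts, ambiguous = ambiguous,
                 samples = samples, annotation = ann, truth = NULL),
            class = "iso_counts")
}

# A constant-level coverage track with a single step up at `at`
# (1-based position of the first high base).
step_track <- function(n = 2000, at = 1000, low = 2, high = 100, start = 1) {
  structure(list(replicon = "chr", start = start,
                 depth = c(rep(low, at - start), rep(high, n - (at - start))),
                 mean = NULL, truth = NULL),
            class = "iso_coverage")
}
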