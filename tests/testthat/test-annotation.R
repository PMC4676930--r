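test_that("default annotation matches the AD45 genome scale", {
  ann <- default_annotation()
  expect_equal(nrow(ann$genes), 6279)
  expect_equal(sum(ann$genes$replicon_id == "plasmid"), 321)
  expect_setequal(unique(ann$genes$role),
                  c("background", "housekeeping", "epoxy_only", "cluster",
                    "boundary_marker"))
  expect_equal(sum(ann$genes$role == "epoxy_only"), 26)
  expect_setequal(ann$genes$gene_id[ann$genes$role == "housekeeping"],
                  c("rpoB", "gyrA", "gmk"))
})

test_that("the 22 cluster genes are contiguous on the plasmid", {
  ann <- default_annotation()
  pl <- ann$genes[ann$genes$replicon_id == "plasmid", ]
  pl <- pl[order(pl$start), ]
  idx <- which(pl$role == "cluster")
  expect_length(idx, 22)
  expect_equal(idx, seq(min(idx), max(idx)))
  expect_setequal(pl$gene_id[idx], cluster_genes())
  # locus tags span SZ00_06083..SZ00_06104
  tags <- sort(pl$locus_tag[idx])
  expect_equal(tags[1], "SZ00_06083")
  expect_equal(tags[22], "SZ00_06104")
  # flanking regulators sit outside the responsive set
  expect_true(all(c("marR1", "gntR") %in% pl$gene_id))
  expect_false(any(c("marR1", "gntR") %in% cluster_genes()))
})

test_that("coordinates are consistent and non-overlapping", {
  ann <- default_annotation()
  g <- ann$genes
  expect_true(all(g$length == g$end - g$start + 1))
  for (rep_id in unique(g$replicon_id)) {
    gg <- g[g$replicon_id == rep_id, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
    expect_true(max(gg$end) <=
                  ann$replicons$length[ann$replicons$replicon_id == rep_id])
  }
})

test_that("duplicate families have >= 2 members with identical lengths", {
  ann <- default_annotation()
  fams <- duplicate_families(ann)
  expect_setequal(unique(fams$family), c("isoG", "isoH", "isoI", "isoJ"))
  for (f in unique(fams$family)) {
    members <- fams$gene_id[fams$family == f]
    expect_gte(length(members), 2)
    expect_length(unique(ann$genes[members, "length"]), 1)
  }
})

test_that("degenerate config without background still carries the core roles", {
  ann <- make_annotation(n_genes = 29L, n_plasmid_genes = 26L,
                         n_epoxy_only = 0L, seed = 7)
  expect_equal(nrow(ann$genes), 29)
  expect_equal(sum(ann$genes$role == "cluster"), 22)
  expect_equal(sum(ann$genes$role == "housekeeping"), 3)
  expect_equal(sum(ann$genes$role == "boundary_marker"), 2)
})

test_that("seed changes background coordinates but not counts or roles", {
  a <- make_annotation(seed = 1)
  b <- make_annotation(seed = 2)
  expect_identical(a$genes$gene_id, b$genes$gene_id)
  expect_identical(a$genes$role, b$genes$role)
  expect_identical(a$genes$duplicate_family, b$genes$duplicate_family)
  bg <- a$genes$role == "background"
  expect_false(identical(a$genes$start[bg], b$genes$start[bg]))
  # fixed cluster block is seed-invariant
  expect_identical(a$genes[cluster_genes(), c("start", "end", "strand")],
                   b$genes[cluster_genes(), c("start", "end", "strand")])
  # same seed reproduces byte-identically
  expect_identical(a, make_annotation(seed = 1))
})

test_that("impossible configurations error", {
  expect_error(make_annotation(n_plasmid_genes = 10L), ">=")
  expect_error(make_annotation(n_genes = 6279L, n_plasmid_genes = 321L,
                               plasmid_length = 60000L),
               "does not fit")
})

test_that("GFF3 output round-trips without loss", {
  ann <- make_annotation(n_genes = 60L, n_plasmid_genes = 30L,
                         n_epoxy_only = 5L, seed = 3)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- read_annotation_gff3(path)
  back$genes <- back$genes[rownames(ann$genes), ]
  expect_equal(back$genes, ann$genes)
  expect_equal(back$replicons[order(back$replicons$replicon_id), ],
               ann$replicons[order(ann$replicons$replicon_id), ],
               ignore_attr = TRUE)
})
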