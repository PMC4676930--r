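test_that("cluster T0 baselines land in the observed 17-211 RPKM window", {
  run <- default_run()
  t0 <- run$counts$samples$sample_id[run$counts$samples$timepoint == "T0"]
  m <- rowMeans(run$expr$rpkm[cluster_genes(), t0])
  expect_true(all(m >= 17 & m <= 211))
})

test_that("null profile makes every cell's expectation identical", {
  ann <- default_annotation()
  p <- default_effect_profile(ann, seed = 5)
  p$iso_fold_t5[] <- 1; p$epoxy_peak[] <- 1; p$epoxy_only_fold[] <- 1
  p$drift[] <- 1; p$hk_wobble[] <- 1; p$gntR_fold <- 1
  cells <- list(c("isoprene", "T5"), c("epoxyisoprene", "T3"),
                c("none", "T0"), c("succinate", "T4"))
  exps <- lapply(cells, function(cl) expected_rpkm(p, cl[1], cl[2]))
  for (e in exps[-1]) expect_equal(e, exps[[1]])
})

test_that("expected RPKM obeys the closure identity in every cell", {
  run <- default_run()
  p <- run$profile
  for (cell in list(c("none", "T0"), c("isoprene", "T5"),
                    c("epoxyisoprene", "T3"), c("glucose", "T2"))) {
    e <- expected_rpkm(p, cell[1], cell[2])
    expect_equal(sum(e * p$length_kb), 1e6)
  }
})

test_that("simulated library sizes stay in the 3-5 million range", {
  run <- default_run()
  counts <- simulate_counts(run$annotation, design_spec(), run$profile, seed = 9)
  tot <- colSums(counts$unique) + colSums(counts$ambiguous)
  expect_true(all(tot > 2.8e6 & tot < 5.2e6))
})

test_that("count simulation is deterministic under a fixed seed", {
  ann <- default_annotation()
  p <- default_effect_profile(ann, seed = 5)
  d <- design_spec(substrates = c("isoprene", "none"), replicates = 2)
  a <- simulate_counts(ann, d, p, seed = 11)
  b <- simulate_counts(ann, d, p, seed = 11)
  expect_identical(a$unique, b$unique)
  expect_identical(a$ambiguous, b$ambiguous)
  c2 <- simulate_counts(ann, d, p, seed = 12)
  expect_false(identical(a$unique, c2$unique))
})

test_that("99%-identity families have a 2-27% uniquely assignable fraction", {
  run <- default_run()
  counts <- run$counts
  iso_t5 <- counts$samples$sample_id[counts$samples$substrate == "isoprene" &
                                       counts$samples$timepoint == "T5"]
  fams <- duplicate_families(counts$annotation)
  for (f in c("isoG", "isoH", "isoJ")) {
    members <- fams$gene_id[fams$family == f]
    u <- colSums(counts$unique[members, iso_t5, drop = FALSE])
    frac <- u / (u + counts$ambiguous[f, iso_t5])
    expect_true(all(frac >= 0.02 & frac <= 0.27))
  }
  members <- fams$gene_id[fams$family == "isoI"]
  u <- colSums(counts$unique[members, iso_t5, drop = FALSE])
  frac <- u / (u + counts$ambiguous["isoI", iso_t5])
  expect_true(all(frac > 0.5))
})

test_that("delta_isoA strain loses the isoprene response but not the epoxy one", {
  run <- default_run()
  d <- design_spec(substrates = c("isoprene", "epoxyisoprene"),
                   strain = "delta_isoA")
  counts <- simulate_counts(run$annotation, d, run$profile, seed = 21)
  assigned <- assign_counts(counts, "best")
  lengths <- setNames(run$annotation$genes$length, run$annotation$genes$gene_id)
  expr <- compute_rpkm(assigned, lengths)
  means <- condition_means(expr, counts$samples)
  iso_ratio <- fold_change(means, c("isoprene", "T5"), "T0")[cluster_genes()]
  expect_true(all(iso_ratio > 0.5 & iso_ratio < 2))
  # isoG family strongly induced by epoxyisoprene at 240 min (T4)
  epo_ratio <- fold_change(means, c("epoxyisoprene", "T4"), "T0")
  expect_true(all(epo_ratio[c("isoG", "isoG2")] > 4))
})

test_that("T0 replicate RSD falls in the configured band", {
  run <- default_run()
  t0 <- run$counts$samples$sample_id[run$counts$samples$timepoint == "T0"]
  rsd <- replicate_rsd(run$expr, t0)
  rsd <- rsd[!is.na(rsd)]
  expect_true(all(rsd >= 1 & rsd <= 400))
  # cluster genes: moderate expression, RSD within the reported 10-100%
  # (documented band; dispersion 0.02 puts them at the low edge)
  expect_true(all(replicate_rsd(run$expr, t0)[cluster_genes()] < 100))
})

test_that("planted fold trajectories below zero are rejected", {
  ann <- default_annotation()
  p <- default_effect_profile(ann, seed = 5)
  expect_error(default_effect_profile(ann, dispersion = 0), "dispersion")
  p2 <- p; p2$gene_id <- rev(p2$gene_id)
  expect_error(simulate_counts(ann, design_spec(), p2, seed = 1),
               "different annotation")
})

test_that("QC failure injection alters exactly the named samples", {
  run <- default_run()
  clean <- simulate_counts(run$annotation, design_spec(), run$profile, seed = 31)
  spec <- default_failure_spec()
  bad <- inject_qc_failures(clean, spec, seed = 32)
  changed <- vapply(colnames(clean$unique), function(s) {
    !identical(clean$unique[, s], bad$unique[, s])
  }, logical(1))
  expect_setequal(names(changed)[changed], spec$sample_id)
  expect_equal(sum(changed), 6)

  # failed samples fall below the depth threshold; discordant ones keep depth
  tot <- colSums(bad$unique) + colSums(bad$ambiguous)
  expect_true(all(tot[spec$sample_id[spec$type == "low_depth"]] < 2e6))
  expect_true(all(tot[spec$sample_id[spec$type == "discordant"]] > 2e6))

  # no-op and error paths
  expect_identical(inject_qc_failures(clean, spec[0, ], seed = 1)$unique,
                   clean$unique)
  expect_error(inject_qc_failures(clean, data.frame(sample_id = "nope",
                                                    type = "low_depth"),
                                  seed = 1),
               "unknown samples")
})

test_that("decorrelated samples drop below R = 0.8 against both partners", {
  run <- default_run()
  R <- correlation_matrix(run$expr)
  for (s in c("succinate_T5_r2", "glucose_T5_r2")) {
    partners <- setdiff(grep(sub("_r2", "", s), rownames(R), value = TRUE), s)
    expect_true(all(R[s, partners] < 0.8))
  }
})
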