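test_that("condition means average replicates and pool T0 correctly", {
  m <- cbind(a_T1_1 = c(g = 90), a_T1_2 = c(g = 100), a_T1_3 = c(g = 110),
             a_T0_1 = c(g = 10), b_T0_1 = c(g = 20), b_T0_2 = c(g = 30))
  meta <- data.frame(
    sample_id = colnames(m),
    substrate = c("a", "a", "a", "a", "b", "b"),
    timepoint = c("T1", "T1", "T1", "T0", "T0", "T0"),
    strain = "WT", stringsAsFactors = FALSE)
  cm <- condition_means(m, meta)
  expect_equal(unname(cm$means["g", "a.T1.WT"]), 100)
  # pooled T0 equals the replicate-weighted mean of the arm T0 means
  expect_equal(unname(cm$means["g", "T0.WT"]), mean(c(10, 20, 30)))
  cm2 <- condition_means(m, meta, pool_t0 = FALSE)
  arm_means <- c(cm2$means["g", "a.T0.WT"], cm2$means["g", "b.T0.WT"])
  w <- c(1, 2)
  expect_equal(unname(cm$means["g", "T0.WT"]),
               sum(arm_means * w) / sum(w))
})

test_that("fold changes divide means with the 2.5 RPKM denominator floor", {
  run <- default_run()
  means <- run$means
  f <- fold_change(means, c("isoprene", "T5"), "T0")
  expect_named(f)
  m <- cbind(`x.T1.WT` = c(g1 = 24000, g2 = 7, g3 = 10),
             `y.T1.WT` = c(g1 = 100, g2 = 7, g3 = 0))
  mm <- structure(list(means = m,
                       cells = data.frame(cell = colnames(m), substrate = c("x", "y"),
                                          timepoint = "T1", strain = "WT", n = 3),
                       pool_t0 = TRUE), class = "iso_means")
  ff <- fold_change(mm, c("x", "T1"), c("y", "T1"))
  expect_equal(unname(ff), c(240, 1, 4))   # 10 / max(0, 2.5) = 4
  expect_error(fold_change(mm, c("x", "T9"), c("y", "T1")), "missing")
})

test_that("housekeeping calibration derives the minimum factor", {
  m <- cbind(a = c(rpoB = 50, gyrA = 100, gmk = 10),
             b = c(rpoB = 100, gyrA = 100, gmk = 10),
             c = c(rpoB = 190, gyrA = 100, gmk = 10))
  mm <- structure(list(means = m, cells = NULL, pool_t0 = TRUE),
                  class = "iso_means")
  cal <- housekeeping_range(mm)
  expect_equal(unname(cal$ratios["rpoB"]), 3.8)
  expect_equal(cal$minimum_factor, 4)
  expect_equal(unname(cal$ratios["gyrA"]), 1)
  expect_warning(housekeeping_range(mm, threshold = 3), "exceeds")
  expect_error(housekeeping_range(mm, hk_genes = c("rpoB", "nope")), "absent")
})

test_that("responsive calls recover exactly the planted cluster", {
  run <- default_run()
  calls <- run$calls
  expect_setequal(calls$gene_id[calls$responsive], cluster_genes())
  expect_equal(sum(calls$responsive), 22)
  # the gntR regulator's planted threefold stays below the cut-off
  expect_false(calls["gntR", "responsive"])
  expect_lt(calls["gntR", "F_iso_t0"], 4)
  # marR2 is part of the responsive cluster with its printed ~19-fold
  expect_true(calls["marR2", "responsive"])
  expect_gt(calls["marR2", "F_iso_none"], 4)
})

test_that("a brute-force fold-change oracle agrees with the pipeline calls", {
  run <- default_run()
  counts <- run$counts
  keep <- run$qc$retained
  g <- run$annotation$genes
  # oracle: recompute everything from raw counts by definition
  fams <- duplicate_families(run$annotation)
  assigned <- counts$unique * 1.0
  for (f in unique(fams$family)) {
    members <- fams$gene_id[fams$family == f]
    share <- counts$ambiguous[f, ] / length(members)
    for (i in seq_along(members)) {
      base <- (i - 1) * share
      assigned[members[i], ] <- assigned[members[i], ] +
        round(base + share) - round(base)
    }
  }
  assigned <- assigned[, keep]
  rpkm <- sapply(colnames(assigned), function(s) {
    assigned[, s] / (g[rownames(assigned), "length"] / 1000) /
      (sum(assigned[, s]) / 1e6)
  })
  meta <- counts$samples[keep, ]
  cell_mean <- function(substrate, tp) {
    sel <- if (tp == "T0") meta$timepoint == "T0"
    else meta$substrate == substrate & meta$timepoint == tp
    rowMeans(rpkm[, meta$sample_id[sel], drop = FALSE])
  }
  fc <- function(num, den) num / pmax(den, 2.5)
  iso5 <- cell_mean("isoprene", "T5"); epo3 <- cell_mean("epoxyisoprene", "T3")
  t0 <- cell_mean(NA, "T0")
  resp <- fc(iso5, t0) >= 4 &
    fc(iso5, cell_mean("succinate", "T5")) >= 4 &
    fc(iso5, cell_mean("none", "T5")) >= 4 &
    fc(epo3, t0) >= 4 &
    fc(epo3, cell_mean("succinate", "T3")) >= 4 &
    fc(epo3, cell_mean("none", "T3")) >= 4
  expect_equal(unname(resp[run$calls$gene_id]),
               unname(run$calls$responsive))
})

test_that("raising the threshold never enlarges a called set", {
  run <- default_run()
  sets <- lapply(c(4, 8, 16), function(th) {
    calls <- call_responsive(run$means, threshold = th)
    calls$gene_id[calls$responsive]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  eset <- lapply(c(4, 8), function(th) call_epoxy_only(run$means, threshold = th))
  expect_true(all(eset[[2]] %in% eset[[1]]))
})

test_that("either-control mode is at least as permissive as both-control", {
  run <- default_run()
  both <- call_responsive(run$means, controls = "both")
  either <- call_responsive(run$means, controls = "either")
  expect_true(all(both$gene_id[both$responsive] %in%
                    either$gene_id[either$responsive]))
})

test_that("epoxyisoprene-only calls match the planted truth and stay disjoint", {
  run <- default_run()
  eo <- run$epoxy_only
  expect_setequal(as.character(eo), run$counts$truth$epoxy_only)
  expect_length(intersect(eo, run$calls$gene_id[run$calls$responsive]), 0)
  # cluster genes are excluded by the isoprene-control condition
  expect_false(any(cluster_genes() %in% eo))
})

test_that("strain contrast identifies the downstream metabolite as inducer", {
  run <- default_run()
  expect_equal(run$contrast$verdict, "downstream-metabolite-induced")
  gv <- run$contrast$genes
  expect_setequal(gv$gene_id, cluster_genes())
  expect_true(all(gv$verdict == "downstream-metabolite-induced"))
  expect_true(all(gv$F_mut_epoxy >= 4) && all(gv$F_mut_iso < 4))

  # WT data passed as "mutant": both arms pass -> inconclusive
  wt_as_mut <- strain_contrast(run$calls, run$means)
  expect_equal(wt_as_mut$verdict, "inconclusive")

  # flat expression in the mutant -> non-inducible
  flat <- run$means
  flat$means[] <- 100
  expect_equal(strain_contrast(run$calls, flat)$verdict, "non-inducible")
})
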