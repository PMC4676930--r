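test_that("assignment modes resolve the ambiguous component as defined", {
  tc <- toy_counts()
  expect_equal(assign_counts(tc, "unique")[, "s1"], c(g1 = 10, g2 = 30, g3 = 5))
  expect_equal(assign_counts(tc, "all")[, "s1"], c(g1 = 70, g2 = 90, g3 = 5))
  expect_equal(assign_counts(tc, "best")[, "s1"], c(g1 = 40, g2 = 60, g3 = 5))
  expect_error(assign_counts(tc, "bogus"))
})

test_that("best-mode assignment conserves totals, unique-mode discards ambiguity", {
  for (amb in c(60, 61, 1, 7)) {   # odd totals exercise the rounding rule
    tc <- toy_counts(ambiguous = cbind(s1 = c(fam1 = amb)))
    best <- assign_counts(tc, "best")
    expect_equal(sum(best), sum(tc$unique) + sum(tc$ambiguous))
    expect_equal(sum(assign_counts(tc, "unique")), sum(tc$unique))
  }
  # property at scale: the default simulated matrix conserves too
  counts <- default_run()$counts
  expect_equal(sum(assign_counts(counts, "best")),
               sum(counts$unique) + sum(counts$ambiguous))
})

test_that("RPKM follows its definition and rejects empty samples", {
  m <- cbind(s1 = c(a = 100, b = 0))
  lengths <- c(a = 500, b = 1200)
  expr <- compute_rpkm(m, lengths, denominator = c(s1 = 2e6))
  expect_equal(expr$rpkm["a", "s1"], 100)   # 100 / (0.5 kb x 2 M)
  expect_equal(expr$rpkm["b", "s1"], 0)
  expect_error(compute_rpkm(m, lengths, denominator = c(s1 = 0)), "s1")
  expect_error(compute_rpkm(m, c(a = 500, b = -1)), "positive length")
})

test_that("per-sample RPKM x length(kb) sums to one million", {
  run <- default_run()
  sums <- colSums(run$expr$rpkm *
                    (run$annotation$genes[rownames(run$expr$rpkm), "length"] / 1000))
  expect_equal(unname(sums), rep(1e6, length(sums)), tolerance = 1e-9)
})

test_that("RPKM is invariant to uniform count rescaling", {
  tc <- toy_counts()
  a <- compute_rpkm(assign_counts(tc, "best"),
                    setNames(tc$annotation$genes$length,
                             tc$annotation$genes$gene_id))
  scaled <- assign_counts(tc, "best") * 7
  b <- compute_rpkm(scaled, setNames(tc$annotation$genes$length,
                                     tc$annotation$genes$gene_id))
  expect_equal(a$rpkm, b$rpkm)
})

test_that("expression levels bin on the 2.5 x 5^k ladder with closed left bins", {
  expect_equal(bin_expression(1.0), 1L)        # "not transcribed", < 2.5
  expect_equal(bin_expression(47500), 7L)      # beyond the 7812.5 top edge
  expect_equal(bin_expression(12.5), 2L)       # boundary goes to the lower bin
  expect_equal(bin_expression(c(0, 2.5, 2.50001, 7812.5, 7812.6)),
               c(1L, 1L, 2L, 6L, 7L))
  x <- sort(runif(100, 0, 1e5))
  expect_true(all(diff(bin_expression(x)) >= 0))  # monotone
  expect_setequal(bin_expression(c(1, 5, 20, 100, 500, 2000, 10000)), 1:7)
  expect_error(bin_expression(-1), "negative")
  expect_length(expression_level_names(), 7)
})

test_that("transcriptome fraction is a percentage of assigned counts", {
  tc <- toy_counts()
  assigned <- assign_counts(tc, "best")
  expect_equal(unname(transcriptome_fraction(assigned, c("g1", "g2", "g3"))), 100)
  expect_equal(unname(transcriptome_fraction(assigned, "g3")),
               100 * 5 / 105)
  expect_error(transcriptome_fraction(assigned, character()), "non-empty")
  expect_error(transcriptome_fraction(assigned, "missing_gene"), "absent")
})

test_that("family aggregates equal member uniques plus the ambiguous pool", {
  counts <- default_run()$counts
  fc <- family_counts(counts)
  fams <- duplicate_families(counts$annotation)
  s <- colnames(counts$unique)[5]
  for (f in rownames(fc)) {
    members <- fams$gene_id[fams$family == f]
    expect_equal(fc[f, s],
                 sum(counts$unique[members, s]) + counts$ambiguous[f, s])
  }
})
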