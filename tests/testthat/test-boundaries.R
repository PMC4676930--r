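test_that("a clean constructed step is called at the exact change point", {
  tr <- step_track(n = 2000, at = 1000, low = 2, high = 100)
  calls <- detect_steps(tr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 1000)
  expect_equal(calls$ratio, 50)      # 100 / max(2, 1)
  expect_equal(calls$direction, "up")
})

test_that("flat and sub-threshold tracks yield no calls", {
  flat <- step_track(low = 50, high = 50)
  expect_equal(nrow(detect_steps(flat)), 0)
  weak <- step_track(low = 50, high = 100)   # ratio 2 < theta
  expect_equal(nrow(detect_steps(weak)), 0)
  dim_track <- step_track(low = 0, high = 5) # below min_depth
  expect_equal(nrow(detect_steps(dim_track)), 0)
  expect_error(detect_steps(flat, W = 0), "W")
  expect_error(detect_steps(flat, theta = 1), "theta")
})

test_that("noiseless synthetic track puts the isoG TSS 68 bp upstream", {
  ann <- default_annotation()
  tr <- simulate_coverage(ann, noise = FALSE)
  calls <- detect_steps(tr, ann)
  isoG_start <- ann$genes["isoG", "start"]
  hit <- calls[calls$position >= isoG_start - 80 &
                 calls$position <= isoG_start - 50, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$position, unname(tr$truth$tss["isoG"]))
  expect_equal(hit$type, "TSS")
  expect_equal(hit$gene, "isoG")
  expect_equal(hit$offset, 68)
  # no boundary inside the 326 bp isoJ-isoA intergene
  isoJ_end <- ann$genes["isoJ", "end"]; isoA_start <- ann$genes["isoA", "start"]
  expect_equal(nrow(calls[calls$position > isoJ_end &
                            calls$position < isoA_start, ]), 0)
  # detected positions equal planted change points exactly
  expect_true(all(tr$truth$tss %in% calls$position))
})

test_that("zero-noise track equals the piecewise mean exactly", {
  ann <- default_annotation()
  tr <- simulate_coverage(ann, noise = FALSE)
  expect_identical(tr$depth, tr$mean)
  noisy <- simulate_coverage(ann, seed = 3, noise = TRUE)
  expect_false(identical(noisy$depth, noisy$mean))
  expect_identical(noisy$depth, simulate_coverage(ann, seed = 3)$depth)
})

test_that("the isoGHIJABCDEF run is co-transcribed behind one promoter", {
  ann <- default_annotation()
  tr <- simulate_coverage(ann, seed = 5)
  calls <- detect_steps(tr, ann)
  run_genes <- c("isoG", "isoH", "isoI", "isoJ", "isoA", "isoB", "isoC",
                 "isoD", "isoE", "isoF")
  verdict <- classify_operon(ann, calls, run_genes)
  expect_true(verdict$co_transcribed)
  expect_equal(verdict$leading_offset, 68)
  # a planted internal terminator breaks co-transcription
  mid <- ann$genes["isoI", "end"] - tr$start + 1
  tr2 <- tr
  tr2$depth[(mid + 1):length(tr2$depth)] <- 0.1 * tr2$depth[(mid + 1):length(tr2$depth)]
  tr2$depth[seq(mid + 1, mid + 200)] <- 0
  verdict2 <- classify_operon(ann, detect_steps(tr2, ann), run_genes)
  expect_false(verdict2$co_transcribed)
  # genes on both strands cannot form a run
  expect_error(classify_operon(ann, calls, c("isoG", "gshA")), "strand")
})

test_that("the SZ00_06083 gene is transcribed as its own unit", {
  ann <- default_annotation()
  tr <- simulate_coverage(ann, seed = 6)
  calls <- detect_steps(tr, ann)
  g <- ann$genes["SZ00_06083", ]
  own <- calls[calls$gene %in% "SZ00_06083" & calls$type == "TSS", ]
  expect_equal(nrow(own), 1)
  expect_equal(own$offset, 68)    # minus strand: 68 bp beyond the 3' coordinate
  verdict <- classify_operon(ann, calls, "SZ00_06083")
  expect_true(verdict$co_transcribed)
  expect_equal(verdict$leading_tss, own$position)
})

test_that("planted TSS is recovered within 5 bp in >= 95% of noisy tracks", {
  ann <- default_annotation()
  truth <- default_operon_spec(ann)$truth$tss["isoG"]
  hits <- vapply(1:100, function(i) {
    tr <- simulate_coverage(ann, seed = 1000 + i)
    calls <- detect_steps(tr, ann)
    any(abs(calls$position[calls$type == "TSS"] - truth) <= 5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("calls are scale-free above the depth floor", {
  tr <- step_track(n = 2000, at = 1000, low = 15, high = 300)
  a <- detect_steps(tr)
  tr$depth <- tr$depth * 10
  b <- detect_steps(tr)
  expect_equal(a$position, b$position)
  expect_equal(a$direction, b$direction)
})

test_that("coverage tracks round-trip through bedGraph", {
  ann <- default_annotation()
  tr <- simulate_coverage(ann, seed = 8)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage_bedgraph(tr, path)
  back <- read_coverage_bedgraph(path)
  expect_equal(back$start, tr$start)
  expect_equal(back$depth, tr$depth)
  expect_equal(back$replicon, tr$replicon)
})
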