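#' Default transcription-unit layout for the coverage simulator
#'
#' Derived from the annotation: the isoG2H2I2J2 unit with its own start
#' site 68 bp upstream of isoG2, the divergently transcribed gshA unit, the
#' main isoGHIJABCDEF operon with a start site 68 bp 5' of isoG, a smooth
#' monotone decay across the whole operon (no internal boundaries, in
#' particular none in the 326 bp isoJ--isoA intergene), and the separate
#' single-gene unit of SZ00_06083 (minus strand, start site 68 bp ahead of
#' its 5' end).
#'
#' @param annotation an `iso_annotation`
#' @param tss_offset distance of planted start sites upstream of the start
#'   codon (default 68 bp)
#' @return list describing the window and the planted piecewise-mean units
#' @export
default_operon_spec <- function(annotation, tss_offset = 68L) {
  g <- annotation$genes
  gene <- function(id) {
    if (!id %in% g$gene_id) stop("operon spec references gene absent from annotation: ",
                                 id, call. = FALSE)
    g[g$gene_id == id, ]
  }
  win_lo <- gene("marR1")$start - 500L
  win_hi <- gene("gntR")$end + 500L
  units <- list(
    list(name = "isoG2_operon",
         from = gene("isoG2")$start - tss_offset, to = gene("isoJ2")$end,
         level_from = 300, level_to = 80),
    list(name = "gshA",
         from = gene("gshA")$start, to = gene("gshA")$end,
         level_from = 40, level_to = 40),
    list(name = "isoG_operon",
         from = gene("isoG")$start - tss_offset, to = gene("isoF")$end,
         level_from = 500, level_to = 150),
    list(name = "SZ00_06083",   # minus strand: 5' end is the right edge
         from = gene("SZ00_06083")$start,
         to = gene("SZ00_06083")$end + tss_offset,
         level_from = 60, level_to = 60))
  tss <- c(isoG = gene("isoG")$start - tss_offset,
           isoG2 = gene("isoG2")$start - tss_offset,
           SZ00_06083 = gene("SZ00_06083")$end + tss_offset)
  term <- c(isoF = gene("isoF")$end + 1L, isoJ2 = gene("isoJ2")$end + 1L)
  list(replicon = "plasmid", window = c(win_lo, win_hi),
       background = 0.5, units = units,
       truth = list(tss = tss, terminators = term))
}

#' Simulate a per-base coverage track over the cluster window
#'
#' Emits Poisson counts around the piecewise mean defined by the operon
#' spec; with `noise = FALSE` the track equals the piecewise mean exactly.
#'
#' @param annotation an `iso_annotation`
#' @param operon_spec layout from [default_operon_spec()]
#' @param seed RNG seed
#' @param noise draw Poisson noise? (default TRUE)
#' @return object of class `iso_coverage`: list(replicon, start, depth,
#'   truth) where `depth[i]` is the depth at 1-based genome position
#'   `start + i - 1`
#' @export
simulate_coverage <- function(annotation, operon_spec = default_operon_spec(annotation),
                              seed = 44L, noise = TRUE) {
  win <- operon_spec$window
  n <- win[2] - win[1] + 1L
  mu <- rep(operon_spec$background, n)
  pos <- seq(win[1], win[2])
  for (u in operon_spec$units) {
    idx <- which(pos >= u$from & pos <= u$to)
    if (!length(idx)) stop("unit outside window: ", u$name, call. = FALSE)
    mu[idx] <- seq(u$level_from, u$level_to, length.out = length(idx))
  }
  depth <- if (noise) with_seed(seed, stats::rpois(n, mu)) else mu
  structure(list(replicon = operon_spec$replicon, start = win[1],
                 depth = as.numeric(depth), mean = mu,
                 truth = operon_spec$truth),
            class = "iso_coverage")
}

#' Write a coverage track as bedGraph (0-based half-open)
#' @param track an `iso_coverage`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_coverage_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  end1 <- track$start - 1L + cumsum(r$lengths)    # 1-based inclusive ends
  start1 <- end1 - r$lengths + 1L
  gr <- GenomicRanges::GRanges(track$replicon,
                               IRanges::IRanges(start1, end1),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a per-base coverage track
#' @param path bedGraph file
#' @return an `iso_coverage` (without planted truth)
#' @export
read_coverage_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- sort(gr)
  lo <- min(GenomicRanges::start(gr)); hi <- max(GenomicRanges::end(gr))
  depth <- numeric(hi - lo + 1L)
  for (i in seq_along(gr)) {
    idx <- (GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]) - lo + 1L
    depth[idx] <- gr$score[i]
  }
  structure(list(replicon = as.character(GenomicRanges::seqnames(gr)[1]),
                 start = lo, depth = depth, mean = NULL, truth = NULL),
            class = "iso_coverage")
}
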