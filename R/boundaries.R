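#' Detect transcription boundaries as coverage steps
#'
#' At each position p the detector compares the mean depth of the W bases
#' starting at p against the W bases before p:
#' r_up(p) = mean(depth\[p, p+W)) / max(mean(depth\[p-W, p)), 1).
#' Positions where r_up >= theta and the downstream mean >= min_depth are
#' step-up candidates; step-downs use the inverse ratio symmetrically.
#' Candidates closer than W are merged keeping the maximum-ratio position.
#' Steps are interpreted through the annotation: a step-up just 5' of a
#' plus-strand gene start (or a step-down just 3' of a minus-strand gene
#' end) is a TSS; other steps are terminators.
#'
#' @param track an `iso_coverage`
#' @param annotation optional `iso_annotation` used to classify steps and
#'   compute offsets; without it steps are labelled by direction only
#' @param W window half-width in bp (default 50)
#' @param theta minimum step ratio (default 5)
#' @param min_depth minimum mean depth on the transcribed side (default 10)
#' @param max_tss_distance how far upstream of a start codon a step may sit
#'   and still be called that gene's TSS (default 300 bp)
#' @return data.frame of class `iso_boundaries`: position (1-based genome
#'   coordinate of the first base after the change point), direction,
#'   type (TSS/terminator), ratio, up_mean, down_mean, gene, offset
#' @export
detect_steps <- function(track, annotation = NULL, W = 50L, theta = 5,
                         min_depth = 10, max_tss_distance = 300L) {
  if (W <= 0) stop("W must be positive", call. = FALSE)
  if (theta <= 1) stop("theta must exceed 1", call. = FALSE)
  x <- track$depth
  n <- length(x)
  if (n <= 2 * W) stop("track shorter than 2 * W", call. = FALSE)
  cs <- c(0, cumsum(x))
  # p indexes the boundary before base p (positions W+1 .. n-W+1)
  p <- seq(W + 1L, n - W + 1L)
  after <- (cs[p + W] - cs[p]) / W        # mean of [p, p+W)
  before <- (cs[p] - cs[p - W]) / W       # mean of [p-W, p)
  r_up <- after / pmax(before, 1)
  r_dn <- before / pmax(after, 1)

  pick <- function(ratio, side_mean) {
    cand <- which(ratio >= theta & side_mean >= min_depth)
    if (!length(cand)) return(integer())
    groups <- cumsum(c(1L, diff(cand) > W))
    vapply(split(cand, groups), function(ix) ix[which.max(ratio[ix])],
           integer(1))
  }
  ups <- pick(r_up, after)
  dns <- pick(r_dn, before)
  calls <- rbind(
    if (length(ups)) data.frame(idx = ups, direction = "up",
                                ratio = r_up[ups], stringsAsFactors = FALSE),
    if (length(dns)) data.frame(idx = dns, direction = "down",
                                ratio = r_dn[dns], stringsAsFactors = FALSE))
  if (is.null(calls) || !nrow(calls)) {
    out <- data.frame(position = integer(), direction = character(),
                      type = character(), ratio = numeric(),
                      up_mean = numeric(), down_mean = numeric(),
                      gene = character(), offset = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("iso_boundaries", "data.frame")
    return(out)
  }
  calls$position <- track$start + p[calls$idx] - 1L
  calls$up_mean <- before[calls$idx]
  calls$down_mean <- after[calls$idx]

  calls$type <- "terminator"
  calls$gene <- NA_character_
  calls$offset <- NA_integer_
  if (!is.null(annotation)) {
    g <- annotation$genes[annotation$genes$replicon_id == track$replicon, ]
    for (i in seq_len(nrow(calls))) {
      pos <- calls$position[i]
      if (calls$direction[i] == "up") {
        cand <- g[g$strand == "+" & g$start >= pos &
                    g$start - pos <= max_tss_distance, ]
        if (nrow(cand)) {
          j <- which.min(cand$start - pos)
          calls$type[i] <- "TSS"
          calls$gene[i] <- cand$gene_id[j]
          calls$offset[i] <- cand$start[j] - pos     # bp upstream of ATG
        }
      } else {
        # change point at `pos` means transcription covered ... pos-1
        cand <- g[g$strand == "-" & g$end <= pos - 1L &
                    (pos - 1L) - g$end <= max_tss_distance, ]
        if (nrow(cand)) {
          j <- which.min(pos - 1L - cand$end)
          calls$type[i] <- "TSS"
          calls$gene[i] <- cand$gene_id[j]
          calls$offset[i] <- (pos - 1L) - cand$end[j]
          # report the TSS base itself (last covered base on a minus strand)
          calls$position[i] <- pos - 1L
        }
      }
    }
  } else {
    calls$type <- ifelse(calls$direction == "up", "step_up", "step_down")
  }
  out <- calls[order(calls$position),
               c("position", "direction", "type", "ratio",
                 "up_mean", "down_mean", "gene", "offset")]
  rownames(out) <- NULL
  class(out) <- c("iso_boundaries", "data.frame")
  out
}

#' Classify a gene run as co-transcribed or not
#'
#' A run is co-transcribed when no boundary call falls strictly inside its
#' span (between the first gene's start and the last gene's end); one TSS
#' upstream of the first gene is expected and reported with its offset to
#' the start codon.
#'
#' @param annotation an `iso_annotation`
#' @param calls an `iso_boundaries` from [detect_steps()]
#' @param genes gene ids of the run, in genomic order
#' @param max_tss_distance leading-TSS search window upstream of the first
#'   gene (default 300 bp)
#' @return list(co_transcribed, leading_tss, leading_offset, internal =
#'   data.frame of internal calls)
#' @export
classify_operon <- function(annotation, calls, genes, max_tss_distance = 300L) {
  g <- annotation$genes[match(genes, annotation$genes$gene_id), ]
  if (any(is.na(g$gene_id))) stop("run references unknown genes", call. = FALSE)
  if (length(unique(g$replicon_id)) != 1 || length(unique(g$strand)) != 1) {
    stop("run genes must be colinear on one strand of one replicon", call. = FALSE)
  }
  span <- c(min(g$start), max(g$end))
  internal <- calls[calls$position > span[1] & calls$position < span[2], ,
                    drop = FALSE]
  plus <- g$strand[1] == "+"
  lead <- if (plus) {
    calls[calls$type == "TSS" & calls$position <= span[1] &
            span[1] - calls$position <= max_tss_distance, , drop = FALSE]
  } else {
    calls[calls$type == "TSS" & calls$position >= span[2] &
            calls$position - span[2] <= max_tss_distance, , drop = FALSE]
  }
  leading_tss <- if (nrow(lead)) lead$position[which.max(lead$ratio)] else NA_integer_
  leading_offset <- if (nrow(lead)) {
    if (plus) span[1] - leading_tss else leading_tss - span[2]
  } else NA_integer_
  list(co_transcribed = nrow(internal) == 0,
       leading_tss = leading_tss, leading_offset = leading_offset,
       internal = as.data.frame(internal))
}

#' Write boundary calls as BED6 (0-based half-open, score = step ratio)
#' @param calls an `iso_boundaries`
#' @param replicon replicon id for the BED chrom column
#' @param path output file
#' @return `path`, invisibly
#' @export
write_boundaries_bed <- function(calls, replicon, path) {
  bed <- data.frame(chrom = replicon,
                    start = calls$position - 1L, end = calls$position,
                    name = paste0(calls$type, "_", seq_len(nrow(calls))),
                    score = round(calls$ratio, 2),
                    strand = ifelse(calls$direction == "up", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
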