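#' Read a BLAST outfmt-6 style homology hit table
#'
#' Twelve tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), optionally with
#' a subject-to-genome map (TSV: sseqid, genome) so hits on different
#' contigs of one assembly share a genome id. Subject coordinates are
#' strand-normalized so start <= end. Hits with identity outside [0, 100]
#' are rejected with a warning.
#'
#' @param path hit table file
#' @param genome_map_path optional subject->genome map TSV (with header)
#' @return data.frame of hits with a `genome` column
#' @export
read_homolog_hits <- function(path, genome_map_path = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = cols, stringsAsFactors = FALSE)
  bad <- hits$pident < 0 | hits$pident > 100
  if (any(bad)) {
    warning(sum(bad), " hit(s) with identity outside [0, 100] rejected",
            call. = FALSE)
    hits <- hits[!bad, , drop = FALSE]
  }
  flip <- hits$sstart > hits$send
  tmp <- hits$sstart[flip]; hits$sstart[flip] <- hits$send[flip]
  hits$send[flip] <- tmp
  if (!is.null(genome_map_path)) {
    map <- utils::read.table(genome_map_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    hits$genome <- map$genome[match(hits$sseqid, map$sseqid)]
    if (any(is.na(hits$genome))) {
      stop("subjects missing from genome map: ",
           paste(unique(hits$sseqid[is.na(hits$genome)]), collapse = ", "),
           call. = FALSE)
    }
  } else {
    hits$genome <- hits$sseqid
  }
  hits
}

#' Screen genomes for colocalized isoA and isoI homologs
#'
#' A genome is a candidate isoprene degrader when it carries an isoA
#' homolog at or above `min_identity_isoA`, an isoI homolog at or above
#' `min_identity_isoI`, both on the same contig with at most
#' `max_separation` bp between the hit intervals. Among qualifying hit
#' pairs the one with the highest combined bit score is reported;
#' candidates are sorted by that score.
#'
#' @param hits data.frame from [read_homolog_hits()] with queries "isoA"
#'   and "isoI"
#' @param min_identity_isoA,min_identity_isoI percent-identity thresholds
#'   (defaults 70 and 50)
#' @param max_separation maximum gap between hit intervals in bp
#'   (default 50,000)
#' @return data.frame: genome, contig, isoA identity/coords, isoI
#'   identity/coords, separation, combined bitscore
#' @export
screen_genomes <- function(hits, min_identity_isoA = 70,
                           min_identity_isoI = 50, max_separation = 50000) {
  a <- hits[hits$qseqid == "isoA" & hits$pident >= min_identity_isoA, ]
  i <- hits[hits$qseqid == "isoI" & hits$pident >= min_identity_isoI, ]
  out <- list()
  for (g in intersect(unique(a$genome), unique(i$genome))) {
    ag <- a[a$genome == g, ]; ig <- i[i$genome == g, ]
    best <- NULL
    for (x in seq_len(nrow(ag))) for (y in seq_len(nrow(ig))) {
      if (ag$sseqid[x] != ig$sseqid[y]) next
      gap <- max(0L, max(ag$sstart[x], ig$sstart[y]) -
                   min(ag$send[x], ig$send[y]) - 1L)
      if (gap > max_separation) next
      score <- ag$bitscore[x] + ig$bitscore[y]
      if (is.null(best) || score > best$score) {
        best <- list(score = score, x = x, y = y, gap = gap)
      }
    }
    if (!is.null(best)) {
      out[[g]] <- data.frame(
        genome = g, contig = ag$sseqid[best$x],
        isoA_identity = ag$pident[best$x], isoA_start = ag$sstart[best$x],
        isoA_end = ag$send[best$x],
        isoI_identity = ig$pident[best$y], isoI_start = ig$sstart[best$y],
        isoI_end = ig$send[best$y],
        separation = best$gap, bitscore = best$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(genome = character(), contig = character(),
                      isoA_identity = numeric(), isoA_start = integer(),
                      isoA_end = integer(), isoI_identity = numeric(),
                      isoI_start = integer(), isoI_end = integer(),
                      separation = integer(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$bitscore), ]
  rownames(res) <- NULL
  res
}
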