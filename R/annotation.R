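#' Fixed gene table for the plasmid-borne isoprene metabolic cluster
#'
#' The 22 contiguous responsive genes (locus tags SZ00_06083--SZ00_06104,
#' including the duplicated isoGHIJ / isoG2H2I2J2 pairs, gshA and the marR2
#' regulator) plus the flanking marker genes (marR1 upstream of isoG2, and
#' the dioxygenase / hypothetical / gntR genes beyond SZ00_06083). Lengths
#' for genes with a printed molecular mass follow ~1 residue per 0.11 kDa
#' (x3 bp); the rest are plausible CDS lengths for the annotated function.
#' Listed in ascending plasmid coordinate order; `gap` is the intergenic
#' distance to the PREVIOUS gene. The isoJ--isoA intergene is 326 bp and
#' the gshA--isoG intergene 250 bp, matching the transcript-boundary
#' geometry the coverage analysis depends on.
#'
#' @return data.frame with gene_id, locus_tag, length, strand, family, role, gap
#' @keywords internal
cluster_gene_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene_id      locus_tag   length strand family role            gap
marR1        SZ00_06105     453  -      NA    boundary_marker   0
isoG2        SZ00_06104    1218  +      isoG  cluster         300
isoH2        SZ00_06103    1053  +      isoH  cluster          20
isoI2        SZ00_06102     741  +      isoI  cluster          20
isoJ2        SZ00_06101     720  +      isoJ  cluster          20
aldh1        SZ00_06100    1503  +      NA    cluster         150
gshB1        SZ00_06099    1068  +      NA    cluster          80
SZ00_06098   SZ00_06098    1320  +      NA    cluster          80
marR2        SZ00_06097     453  +      NA    cluster         120
gshA         SZ00_06096    1275  -      NA    cluster         180
isoG         SZ00_06095    1218  +      isoG  cluster         250
isoH         SZ00_06094    1053  +      isoH  cluster          20
isoI         SZ00_06093     741  +      isoI  cluster          20
isoJ         SZ00_06092     720  +      isoJ  cluster          20
isoA         SZ00_06091    1359  +      NA    cluster         326
isoB         SZ00_06090    1011  +      NA    cluster          20
isoC         SZ00_06089     354  +      NA    cluster          20
isoD         SZ00_06088     507  +      NA    cluster          20
isoE         SZ00_06087    1053  +      NA    cluster          20
isoF         SZ00_06086    1020  +      NA    cluster          20
aldh2        SZ00_06085    1503  +      NA    cluster         150
gshB2        SZ00_06084    1071  +      NA    cluster          80
SZ00_06083   SZ00_06083     474  -      NA    cluster         200
SZ00_06082   SZ00_06082     852  +      NA    background      120
SZ00_06081   SZ00_06081     429  -      NA    background      100
gntR         SZ00_06080     690  -      NA    boundary_marker 150
")
  tab$family[tab$family == "NA"] <- NA_character_
  tab
}

#' Names of the 22 isoprene-responsive cluster genes
#'
#' The contiguous plasmid locus SZ00_06083--SZ00_06104 in ascending
#' coordinate order (isoG2 first).
#' @return character vector of 22 gene ids
#' @export
cluster_genes <- function() {
  tab <- cluster_gene_table()
  tab$gene_id[tab$role == "cluster"]
}

#' Housekeeping reference genes used for fold-change calibration
#' @return character vector: rpoB, gyrA, gmk
#' @export
housekeeping_genes <- function() c("rpoB", "gyrA", "gmk")

# Place `n` genes sequentially in [lo, hi] without overlap; seeded lengths
# (log-normal, multiples of 3) and intergenic gaps. Errors if they do not fit.
place_background <- function(n, lo, hi, prefix, start_tag,
                             meanlog = log(820), sdlog = 0.32,
                             gap_range = c(40L, 160L)) {
  if (n == 0L) {
    return(data.frame(gene_id = character(), locus_tag = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  len <- pmax(150L, 3L * round(exp(rnorm(n, meanlog, sdlog)) / 3))
  gap <- sample(gap_range[1]:gap_range[2], n, replace = TRUE)
  start <- lo + cumsum(c(0L, (len + gap)[-n]))
  end <- start + len - 1L
  if (end[n] > hi) {
    stop("background genes do not fit in replicon interval [", lo, ", ", hi,
         "]: need ", end[n], call. = FALSE)
  }
  tags <- sprintf("%s%05d", "SZ00_", seq(start_tag, length.out = n))
  data.frame(gene_id = tags, locus_tag = tags, start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate an AD45-like gene annotation with planted roles
#'
#' Builds a two-replicon annotation emulating the *Rhodococcus* sp. AD45
#' genome: a chromosome and a ~300 kbp plasmid carrying the contiguous
#' 22-gene isoprene-responsive cluster (SZ00_06083--SZ00_06104, with
#' duplicated gene families isoG/isoG2, isoH/isoH2, isoJ/isoJ2 at 99%
#' identity and isoI/isoI2 at 79%), flanked by the marR1 and gntR marker
#' genes. Defaults give 6,279 protein-coding genes of which 321 lie on the
#' plasmid. Housekeeping genes (rpoB, gyrA, gmk) and a configurable number
#' of epoxyisoprene-only response genes sit on the chromosome at
#' deterministic positions in the gene list, so two seeds with the same
#' configuration agree gene-for-gene in counts and role assignments and
#' differ only in background coordinates.
#'
#' @param n_genes total protein-coding genes (default 6279)
#' @param n_plasmid_genes genes on the plasmid (default 321; must be >= 26)
#' @param n_epoxy_only chromosome genes planted as epoxyisoprene-only
#'   responders (default 26)
#' @param plasmid_length,chromosome_length replicon sizes in bp
#' @param seed RNG seed for background coordinates
#' @return object of class `iso_annotation`: list with `replicons`
#'   (data.frame: replicon_id, length, topology) and `genes` (data.frame:
#'   gene_id, locus_tag, replicon_id, strand, start, end, length,
#'   duplicate_family, role)
#' @export
make_annotation <- function(n_genes = 6279L, n_plasmid_genes = 321L,
                            n_epoxy_only = 26L,
                            plasmid_length = 300000L,
                            chromosome_length = 6500000L,
                            seed = 42L) {
  fixed <- cluster_gene_table()
  n_fixed <- nrow(fixed)                      # 26 plasmid genes fixed in place
  hk_len <- c(rpoB = 3480L, gyrA = 2520L, gmk = 630L)
  n_hk <- length(hk_len)

  n_plasmid_bg <- n_plasmid_genes - n_fixed
  n_chrom <- n_genes - n_plasmid_genes
  n_chrom_bg <- n_chrom - n_hk - n_epoxy_only
  if (n_plasmid_bg < 0L) stop("n_plasmid_genes must be >= ", n_fixed, call. = FALSE)
  if (n_chrom_bg < 0L) stop("n_genes too small for chromosome roles", call. = FALSE)

  # Fixed plasmid block, anchored so that isoG starts at 56215.
  off <- cumsum(fixed$gap + c(0L, fixed$length[-n_fixed]))
  anchor <- 56215L - off[fixed$gene_id == "isoG"]
  fixed$start <- anchor + off
  fixed$end <- fixed$start + fixed$length - 1L
  block_lo <- min(fixed$start); block_hi <- max(fixed$end)
  if (block_hi > plasmid_length) {
    stop("responsive cluster does not fit on the plasmid", call. = FALSE)
  }

  with_seed(seed, {
    # plasmid background genes are packed more tightly than the chromosome
    # (321 CDS on ~300 kbp with a ~26 kbp fixed block): shorter genes,
    # smaller gaps, capacity-proportional split around the cluster block
    left_space <- block_lo - 400L
    right_space <- plasmid_length - block_hi - 300L
    n_left <- round(n_plasmid_bg * left_space / (left_space + right_space))
    n_left <- max(0L, min(n_plasmid_bg, n_left))
    pl_left <- place_background(n_left, 200L, block_lo - 200L, "SZ00_", 6106L,
                                meanlog = log(690), sdlog = 0.28,
                                gap_range = c(30L, 110L))
    pl_right <- place_background(n_plasmid_bg - n_left, block_hi + 200L,
                                 plasmid_length - 100L, "SZ00_",
                                 6106L + n_left,
                                 meanlog = log(690), sdlog = 0.28,
                                 gap_range = c(30L, 110L))
    chrom_all <- place_background(n_chrom, 200L, chromosome_length - 100L,
                                  "SZ00_", 1L)
    plasmid <- rbind(
      data.frame(gene_id = fixed$gene_id, locus_tag = fixed$locus_tag,
                 start = fixed$start, end = fixed$end, strand = fixed$strand,
                 stringsAsFactors = FALSE),
      pl_left, pl_right)
    plasmid <- plasmid[order(plasmid$start), ]
    plasmid$replicon_id <- "plasmid"
    chrom_all$replicon_id <- "chromosome"

    # Deterministic chromosome roles: housekeeping and epoxy-only genes sit
    # at fixed, evenly spread indices of the gene list regardless of seed.
    chrom_all$role <- "background"
    hk_idx <- pmin(n_chrom, pmax(1L, round(seq(0.1, 0.9, length.out = n_hk) * n_chrom)))
    while (anyDuplicated(hk_idx)) hk_idx[duplicated(hk_idx)] <-
      hk_idx[duplicated(hk_idx)] + 1L
    chrom_all$gene_id[hk_idx] <- names(hk_len)
    chrom_all$role[hk_idx] <- "housekeeping"
    # Re-fit housekeeping lengths in place (coordinates shift downstream genes).
    for (i in seq_along(hk_idx)) {
      k <- hk_idx[i]
      delta <- hk_len[i] - (chrom_all$end[k] - chrom_all$start[k] + 1L)
      chrom_all$end[k:n_chrom] <- chrom_all$end[k:n_chrom] + delta
      if (k < n_chrom) {
        idx <- (k + 1L):n_chrom
        chrom_all$start[idx] <- chrom_all$start[idx] + delta
      }
    }
    if (max(chrom_all$end) > chromosome_length) {
      stop("chromosome genes do not fit after housekeeping resize", call. = FALSE)
    }
    if (n_epoxy_only > 0L) {
      pool <- which(chrom_all$role == "background")
      epx_idx <- pool[round(seq(0.05, 0.95, length.out = n_epoxy_only) * length(pool))]
      chrom_all$role[epx_idx] <- "epoxy_only"
    }

    fixed_meta <- fixed[match(plasmid$gene_id, fixed$gene_id), c("family", "role")]
    plasmid$role <- ifelse(is.na(fixed_meta$role), "background", fixed_meta$role)
    plasmid$duplicate_family <- fixed_meta$family
    chrom_all$duplicate_family <- NA_character_

    cols <- c("gene_id", "locus_tag", "replicon_id", "strand", "start", "end",
              "duplicate_family", "role")
    genes <- rbind(chrom_all[, cols], plasmid[, cols])
    genes$length <- genes$end - genes$start + 1L
    rownames(genes) <- genes$gene_id
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids generated", call. = FALSE)

    ann <- list(
      replicons = data.frame(
        replicon_id = c("chromosome", "plasmid"),
        length = c(chromosome_length, plasmid_length),
        topology = c("circular", "circular"),
        stringsAsFactors = FALSE),
      genes = genes[, c("gene_id", "locus_tag", "replicon_id", "strand",
                        "start", "end", "length", "duplicate_family", "role")])
    class(ann) <- "iso_annotation"
    validate_annotation(ann)
    ann
  })
}

# Invariant checks shared by the generator and the GFF3 reader.
validate_annotation <- function(ann) {
  g <- ann$genes
  rl <- stats::setNames(ann$replicons$length, ann$replicons$replicon_id)
  if (any(g$start < 1L) || any(g$end > rl[g$replicon_id])) {
    stop("gene coordinates outside replicon", call. = FALSE)
  }
  if (any(g$length != g$end - g$start + 1L)) {
    stop("length field inconsistent with coordinates", call. = FALSE)
  }
  for (rep_id in unique(g$replicon_id)) {
    gg <- g[g$replicon_id == rep_id, ]
    gg <- gg[order(gg$start), ]
    if (any(gg$start[-1] <= gg$end[-nrow(gg)])) {
      stop("overlapping gene coordinates on ", rep_id, call. = FALSE)
    }
  }
  fams <- split(g$length, g$duplicate_family)
  bad <- vapply(fams, function(x) length(x) < 2L || length(unique(x)) != 1L, TRUE)
  if (any(bad)) stop("duplicate families must have >= 2 members of equal length",
                     call. = FALSE)
  invisible(ann)
}

#' @export
print.iso_annotation <- function(x, ...) {
  cat("iso_annotation:", nrow(x$genes), "genes on",
      nrow(x$replicons), "replicons\n")
  print(table(x$genes$role))
  invisible(x)
}

#' Duplicate-family membership table
#' @param annotation an `iso_annotation`
#' @return data.frame with family, gene_id
#' @export
duplicate_families <- function(annotation) {
  g <- annotation$genes
  g <- g[!is.na(g$duplicate_family), c("duplicate_family", "gene_id")]
  names(g) <- c("family", "gene_id")
  rownames(g) <- NULL
  g[order(g$family, g$gene_id), ]
}

#' Write an annotation to GFF3
#'
#' One `region` feature per replicon (carrying `Is_circular`) and one `gene`
#' feature per gene with `ID`, `locus_tag`, `role` and `duplicate_family`
#' attributes; 1-based inclusive coordinates as GFF3 requires.
#'
#' @param annotation an `iso_annotation`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  rl <- annotation$replicons
  seqinf <- GenomeInfoDb::Seqinfo(seqnames = rl$replicon_id,
                                  seqlengths = rl$length,
                                  isCircular = rl$topology == "circular")
  regions <- GenomicRanges::GRanges(
    rl$replicon_id, IRanges::IRanges(1L, rl$length), strand = "*",
    type = "region", ID = paste0("region:", rl$replicon_id),
    Is_circular = ifelse(rl$topology == "circular", "true", "false"),
    locus_tag = NA_character_, role = NA_character_,
    duplicate_family = NA_character_, seqinfo = seqinf)
  genes <- GenomicRanges::GRanges(
    g$replicon_id, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Is_circular = NA_character_,
    locus_tag = g$locus_tag, role = g$role,
    duplicate_family = g$duplicate_family, seqinfo = seqinf)
  rtracklayer::export(c(regions, genes), path, format = "gff3")
  invisible(path)
}

#' Read an annotation written by [write_annotation_gff3()]
#' @param path GFF3 file
#' @return an `iso_annotation`
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  reg <- gr[gr$type == "region"]
  gg <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gg$ID,
    locus_tag = gg$locus_tag,
    replicon_id = as.character(GenomicRanges::seqnames(gg)),
    strand = as.character(GenomicRanges::strand(gg)),
    start = GenomicRanges::start(gg),
    end = GenomicRanges::end(gg),
    stringsAsFactors = FALSE)
  genes$length <- genes$end - genes$start + 1L
  genes$duplicate_family <- as.character(gg$duplicate_family)
  genes$role <- as.character(gg$role)
  rownames(genes) <- genes$gene_id
  ann <- list(
    replicons = data.frame(
      replicon_id = as.character(GenomicRanges::seqnames(reg)),
      length = GenomicRanges::end(reg),
      topology = ifelse(!is.na(reg$Is_circular) & reg$Is_circular == "true",
                        "circular", "linear"),
      stringsAsFactors = FALSE),
    genes = genes)
  class(ann) <- "iso_annotation"
  validate_annotation(ann)
  ann
}
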