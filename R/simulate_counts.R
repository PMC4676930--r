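#' Simulate the substrate-switch count matrix with planted truth
#'
#' Draws negative-binomial read counts for every gene x sample cell of the
#' design around the planted expected expression ([expected_rpkm()]), with
#' per-sample library sizes drawn from the configured 3--5 million range.
#' Counts for the duplicated gene families are split into a per-gene
#' uniquely-assignable component and a family-level ambiguous component
#' (the model of multi-mapping reads removed by the MQ < 5 filter): the
#' 99%-identity families (isoG, isoH, isoJ) get a small unique fraction,
#' the 79%-identity isoI family a large one.
#'
#' @param annotation an `iso_annotation`
#' @param design an `iso_design` (default: the full 90-sample WT design)
#' @param profile an `iso_profile` (default: [default_effect_profile()])
#' @param seed RNG seed
#' @return list with class `iso_counts`: `unique` (gene x sample integer
#'   matrix), `ambiguous` (family x sample), `samples` (the design
#'   data.frame), `annotation`, and `truth` (planted ground truth:
#'   responsive and epoxy-only gene sets, fold factors, expected RPKM per
#'   cell, unique fractions)
#' @export
simulate_counts <- function(annotation, design = design_spec(),
                            profile = default_effect_profile(annotation),
                            seed = 42L) {
  g <- annotation$genes
  ids <- g$gene_id
  if (!identical(ids, profile$gene_id)) {
    stop("profile was built for a different annotation", call. = FALSE)
  }
  fams <- duplicate_families(annotation)
  fam_ids <- unique(fams$family)
  size <- 1 / profile$dispersion

  with_seed(seed, {
    lib <- round(runif(nrow(design), profile$lib_range[1], profile$lib_range[2]))
    u99 <- profile$unique_fraction_99
    u79 <- profile$unique_fraction_79
    ufrac <- stats::setNames(runif(length(fam_ids), u99[1], u99[2]), fam_ids)
    ufrac["isoI"] <- runif(1, u79[1], u79[2])

    uniq <- matrix(0L, nrow = length(ids), ncol = nrow(design),
                   dimnames = list(ids, design$sample_id))
    amb <- matrix(0L, nrow = length(fam_ids), ncol = nrow(design),
                  dimnames = list(fam_ids, design$sample_id))
    fam_of <- profile$family
    in_fam <- !is.na(fam_of)
    expected <- list()

    cells <- unique(design[, c("substrate", "timepoint", "strain")])
    for (k in seq_len(nrow(cells))) {
      cell <- cells[k, ]
      rp <- expected_rpkm(profile, cell$substrate, cell$timepoint, cell$strain)
      expected[[paste(cell$substrate, cell$timepoint, sep = ".")]] <- rp
      rate <- rp * profile$length_kb       # expected count share per gene
      share <- rate / sum(rate)
      sel <- which(design$substrate == cell$substrate &
                     design$timepoint == cell$timepoint &
                     design$strain == cell$strain)
      for (j in sel) {
        mu <- share * lib[j]
        mu_u <- ifelse(in_fam, mu * ufrac[fam_of], mu)
        uniq[, j] <- stats::rnbinom(length(mu_u), mu = mu_u, size = size)
        mu_a <- vapply(fam_ids, function(f) {
          sum(mu[in_fam & fam_of == f]) * (1 - ufrac[f])
        }, numeric(1))
        amb[, j] <- stats::rnbinom(length(mu_a), mu = mu_a, size = size)
      }
    }

    counts <- list(
      unique = uniq, ambiguous = amb, samples = as.data.frame(design),
      annotation = annotation,
      truth = list(
        responsive = ids[g$role == "cluster"],
        epoxy_only = ids[g$role == "epoxy_only"],
        iso_fold = profile$iso_fold,
        epoxy_only_fold = profile$epoxy_only_fold,
        expected_rpkm = expected,
        unique_fraction = ufrac,
        library_size = stats::setNames(lib, design$sample_id),
        failed_samples = character(), discordant_samples = character()))
    class(counts) <- "iso_counts"
    counts
  })
}

#' @export
print.iso_counts <- function(x, ...) {
  cat("iso_counts:", nrow(x$unique), "genes x", ncol(x$unique), "samples (",
      nrow(x$ambiguous), "ambiguous families )\n")
  invisible(x)
}

#' Default QC failure specification
#'
#' Mirrors the failures observed in the experiment: four samples lost to
#' failed sequencing reactions (succinate T1 rep 1, glucose T3 rep 1,
#' no-substrate T4 rep 3, no-substrate T5 rep 3) and two removed for poor
#' replicate correlation (succinate T5 rep 2, glucose T5 rep 2).
#'
#' @return data.frame with sample_id and type in {low_depth, discordant}
#' @export
default_failure_spec <- function() {
  data.frame(
    sample_id = c("succinate_T1_r1", "glucose_T3_r1", "none_T4_r3",
                  "none_T5_r3", "succinate_T5_r2", "glucose_T5_r2"),
    type = c(rep("low_depth", 4), rep("discordant", 2)),
    stringsAsFactors = FALSE)
}

#' Degrade named samples to emulate sequencing QC failures
#'
#' `low_depth` samples are binomially thinned to a total below the two-
#' million-read depth threshold; `discordant` samples keep their depth but
#' have their per-gene counts permuted across genes, destroying replicate
#' correlation. All other samples are untouched. The truth labels are
#' updated with the injected failure sets.
#'
#' @param counts an `iso_counts`
#' @param failure_spec data.frame(sample_id, type); default mirrors the
#'   experiment ([default_failure_spec()])
#' @param seed RNG seed
#' @param depth_range target total-count range for low_depth samples
#' @return modified `iso_counts`
#' @export
inject_qc_failures <- function(counts, failure_spec = default_failure_spec(),
                               seed = 43L, depth_range = c(5e5, 1.5e6)) {
  if (nrow(failure_spec) == 0) return(counts)
  unknown <- setdiff(failure_spec$sample_id, colnames(counts$unique))
  if (length(unknown)) {
    stop("failure_spec names unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    for (i in seq_len(nrow(failure_spec))) {
      s <- failure_spec$sample_id[i]
      if (failure_spec$type[i] == "low_depth") {
        tot <- sum(counts$unique[, s]) + sum(counts$ambiguous[, s])
        p <- runif(1, depth_range[1], depth_range[2]) / tot
        counts$unique[, s] <- stats::rbinom(nrow(counts$unique),
                                            counts$unique[, s], p)
        counts$ambiguous[, s] <- stats::rbinom(nrow(counts$ambiguous),
                                               counts$ambiguous[, s], p)
      } else if (failure_spec$type[i] == "discordant") {
        counts$unique[, s] <- counts$unique[sample(nrow(counts$unique)), s]
        counts$ambiguous[, s] <- counts$ambiguous[sample(nrow(counts$ambiguous)), s]
      } else {
        stop("unknown failure type: ", failure_spec$type[i], call. = FALSE)
      }
    }
    counts$truth$failed_samples <-
      failure_spec$sample_id[failure_spec$type == "low_depth"]
    counts$truth$discordant_samples <-
      failure_spec$sample_id[failure_spec$type == "discordant"]
    counts
  })
}
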