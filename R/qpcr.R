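#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(quantity) over the dilution series.
#' Amplification efficiency is 10^(-1/slope) - 1 (1 = 100%, perfect
#' doubling at slope -3.32). Warns when R^2 < 0.98, errors on non-positive
#' quantities or a non-negative slope.
#'
#' @param quantity standard quantities (>= 3 points spanning >= 2 logs)
#' @param cq observed Cq values
#' @return object of class `iso_std_curve`: list(slope, intercept,
#'   r_squared, efficiency)
#' @export
fit_standard_curve <- function(quantity, cq) {
  if (any(quantity <= 0)) stop("standard quantities must be positive", call. = FALSE)
  if (length(unique(quantity)) < 3 ||
      diff(range(log10(quantity))) < 2) {
    stop("need >= 3 dilution points spanning >= 2 logs", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("standard curve slope must be negative", call. = FALSE)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected
  if (r2 < 0.98) warning("standard curve R^2 = ", round(r2, 4), " < 0.98",
                         call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "iso_std_curve")
}

#' Quantity from Cq through a fitted standard curve
#' @param curve an `iso_std_curve`
#' @param cq Cq values
#' @return estimated quantities (same units as the standards)
#' @export
curve_quantity <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Reference-normalized relative expression from a qPCR plate
#'
#' Standard-curve quantification as used in the validation experiment (not
#' delta-delta-Ct): per-assay curves are fitted from that plate's standards
#' unless supplied; unknown Cq values are converted to quantities, averaged
#' in quantity space within (time point, replicate aggregation), divided by
#' the reference-gene quantity, and normalized to the T0 (0 min) ratio,
#' which is 1 by construction. A delta-delta-Ct mode is provided for
#' comparison (assumes shared perfect efficiency).
#'
#' @param plate plate data.frame as produced by [simulate_qpcr()] or read
#'   via [read_qpcr_plate()]
#' @param target target assay (e.g. "isoG")
#' @param reference reference assay (default "rpoB")
#' @param curves optional named list of `iso_std_curve` per assay
#' @param method "standard_curve" (default) or "ddct"
#' @return data.frame: timepoint_min, ratio (mean across replicates,
#'   normalized to T0), sd, n
#' @export
relative_expression <- function(plate, target, reference = "rpoB",
                                curves = NULL,
                                method = c("standard_curve", "ddct")) {
  method <- match.arg(method)
  std <- plate[plate$role == "standard", ]
  unk <- plate[plate$role == "unknown", ]
  if (!any(unk$timepoint_min == 0)) stop("plate has no T0 samples", call. = FALSE)
  per_sample <- function(assay) {
    u <- unk[unk$assay == assay, ]
    q <- if (method == "standard_curve") {
      cu <- curves[[assay]] %||% {
        s <- std[std$assay == assay, ]
        fit_standard_curve(s$quantity, s$cq)
      }
      curve_quantity(cu, u$cq)
    } else {
      2^(-u$cq)
    }
    data.frame(timepoint_min = u$timepoint_min, replicate = u$replicate, q = q)
  }
  tq <- per_sample(target); rq <- per_sample(reference)
  key <- c("timepoint_min", "replicate")
  m <- merge(tq, rq, by = key, suffixes = c("_t", "_r"))
  m$ratio_raw <- m$q_t / m$q_r
  t0 <- mean(m$ratio_raw[m$timepoint_min == 0])
  m$ratio <- m$ratio_raw / t0
  agg <- do.call(rbind, lapply(split(m, m$timepoint_min), function(d) {
    data.frame(timepoint_min = d$timepoint_min[1], ratio = mean(d$ratio),
               sd = stats::sd(d$ratio), n = nrow(d))
  }))
  rownames(agg) <- NULL
  agg[order(agg$timepoint_min), ]
}

#' Write/read a qPCR plate as CSV
#' @param plate plate data.frame
#' @param path CSV file
#' @return `path` (writer) or the plate data.frame (reader)
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_plate
#' @export
read_qpcr_plate <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
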