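#' Simulate an RT-qPCR plate with standards and planted relative quantities
#'
#' Generates Cq values through the log-linear standard-curve model
#' Cq = intercept + slope * log10(quantity) + N(0, cq_sd), for three assays
#' (isoA, isoG, rpoB). Each plate carries a tenfold dilution standard
#' series per assay plus unknown samples whose planted quantities follow
#' the chosen scenario:
#' \describe{
#'   \item{mutant_epoxyisoprene}{the isoA-deletion strain exposed to
#'     epoxyisoprene: isoG/isoA transcripts rise ~100-fold by 225 min
#'     (3.75 h) relative to rpoB and T0.}
#'   \item{mutant_isoprene}{the mutant with isoprene: no induction, all
#'     ratios ~1.}
#'   \item{wt_isoprene}{wild type with isoprene: strong late induction.}
#' }
#' The isoG primer pair does not distinguish the two isoG copies, so the
#' planted isoG quantity is the sum of both copies (2x the per-copy value).
#'
#' @param scenario one of the planted induction scenarios
#' @param curve_params list(slope, intercept, cq_sd); slope defaults to
#'   -3.32 (100% efficiency)
#' @param minutes unknown-sample time points (minutes)
#' @param replicates biological replicates per time point
#' @param dilutions standard-series quantities (relative units)
#' @param seed RNG seed
#' @return list with `plate` (data.frame: well, assay, sample, role,
#'   timepoint_min, replicate, quantity, cq) and `truth` (planted fold
#'   trajectories vs T0)
#' @export
simulate_qpcr <- function(scenario = c("mutant_epoxyisoprene", "mutant_isoprene",
                                       "wt_isoprene"),
                          curve_params = list(slope = -3.32, intercept = 15,
                                              cq_sd = 0.1),
                          minutes = c(0, 75, 225),
                          replicates = 3L,
                          dilutions = 10^seq(0, -4),
                          seed = 45L) {
  scenario <- match.arg(scenario)
  slope <- curve_params$slope %||% -3.32
  intercept <- curve_params$intercept %||% 15
  cq_sd <- curve_params$cq_sd %||% 0.1
  if (any(dilutions <= 0)) stop("standard quantities must be positive", call. = FALSE)

  fold_at <- function(min) {
    switch(scenario,
      mutant_epoxyisoprene = stats::approx(c(0, 75, 225, 1500), c(1, 25, 100, 40),
                                           xout = min, rule = 2)$y,
      mutant_isoprene = rep(1, length(min)),
      wt_isoprene = stats::approx(c(0, 75, 225, 1500), c(1, 2, 20, 150),
                                  xout = min, rule = 2)$y)
  }
  base_q <- c(isoA = 2e-3, isoG = 2 * 2e-3, rpoB = 5e-2)  # isoG = both copies
  assays <- names(base_q)

  with_seed(seed, {
    rows <- list()
    for (a in assays) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay = a, sample = sprintf("std_%s_%d", a, seq_along(dilutions)),
        role = "standard", timepoint_min = NA_real_, replicate = NA_integer_,
        quantity = dilutions, stringsAsFactors = FALSE)
    }
    for (m in minutes) {
      for (r in seq_len(replicates)) {
        fold <- fold_at(m)
        q <- base_q
        q[c("isoA", "isoG")] <- q[c("isoA", "isoG")] * fold
        rows[[length(rows) + 1L]] <- data.frame(
          assay = assays, sample = sprintf("t%g_r%d", m, r),
          role = "unknown", timepoint_min = m, replicate = r,
          quantity = unname(q), stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, rows)
    plate$cq <- intercept + slope * log10(plate$quantity) +
      stats::rnorm(nrow(plate), 0, cq_sd)
    plate$quantity[plate$role != "standard"] <- NA_real_
    plate$well <- sprintf("W%03d", seq_len(nrow(plate)))
    plate <- plate[, c("well", "assay", "sample", "role", "timepoint_min",
                       "replicate", "quantity", "cq")]
    list(plate = plate,
         truth = list(scenario = scenario,
                      fold_vs_t0 = stats::setNames(fold_at(minutes),
                                                   paste0("t", minutes)),
                      slope = slope, intercept = intercept, cq_sd = cq_sd))
  })
}
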