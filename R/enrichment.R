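#' RT-qPCR measurement for efficiency-corrected enrichment
#'
#' Threshold cycles (Ct) for a target and a reference gene, each measured
#' in the sorted and the initial (unsorted) sample, together with the two
#' genes' amplification efficiencies on the 0-1 scale (per-cycle fold
#' increase is 1 + E).
#'
#' @param ct_target_sorted,ct_target_initial Target-gene Ct in the sorted /
#'   initial sample (cycles).
#' @param ct_ref_sorted,ct_ref_initial Reference-gene Ct in the sorted /
#'   initial sample (cycles).
#' @param eff_target,eff_ref Amplification efficiencies in \[0, 1\].
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_target_sorted, ct_target_initial,
                             ct_ref_sorted, ct_ref_initial,
                             eff_target, eff_ref) {
  cts <- c(ct_target_sorted, ct_target_initial, ct_ref_sorted, ct_ref_initial)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be positive and finite")
  }
  for (e in c(eff_target, eff_ref)) {
    if (!is.finite(e) || e < 0 || e > 1) {
      stop("amplification efficiencies must lie in [0, 1]")
    }
  }
  structure(
    list(ct_target_sorted = ct_target_sorted,
         ct_target_initial = ct_target_initial,
         ct_ref_sorted = ct_ref_sorted,
         ct_ref_initial = ct_ref_initial,
         eff_target = eff_target, eff_ref = eff_ref),
    class = "qpcr_measurement"
  )
}

#' Efficiency-corrected fold enrichment from Ct values
#'
#' Generalization of the classical `2^-ddCt` relative-quantification method
#' to genes with unequal amplification efficiencies:
#'
#' \deqn{E = (1 + E_R)^{(Ct_{R,sorted} - Ct_{R,initial})} \cdot
#'           (1 + E_X)^{(Ct_{X,initial} - Ct_{X,sorted})}}
#'
#' where X is the target and R the reference gene. When both efficiencies
#' are 1 this reduces to the classical form; when all ddCt terms are 0 the
#' enrichment is 1. Swapping the sorted and initial labels inverts the
#' result.
#'
#' @param m A [qpcr_measurement()].
#' @return The fold-enrichment factor (> 0).
#' @examples
#' m <- qpcr_measurement(20, 23, 18, 18, eff_target = 0.17, eff_ref = 0.36)
#' fold_enrichment(m)  # 1.17^3
#' @export
fold_enrichment <- function(m) {
  stopifnot(inherits(m, "qpcr_measurement"))
  (1 + m$eff_ref)^(m$ct_ref_sorted - m$ct_ref_initial) *
    (1 + m$eff_target)^(m$ct_target_initial - m$ct_target_sorted)
}

#' Estimate amplification efficiency from a dilution series
#'
#' Fits an ordinary least-squares line of Ct against log2(relative
#' template concentration). For perfect doubling chemistry the slope is
#' -1 (one extra cycle per 2-fold dilution) and the efficiency is 1; in
#' general `E = 2^(-1/slope) - 1`. Estimates falling outside \[0, 1\] are
#' clipped with a warning.
#'
#' @param ct Ct values at each dilution point (>= 3 points).
#' @param concentration Relative template concentrations (same length as
#'   `ct`); e.g. `c(1, 0.5, 0.25)` for a 2-fold series. Alternatively pass
#'   `dilution_step` and omit `concentration`.
#' @param dilution_step Fold-dilution per step when `concentration` is not
#'   given; point i gets concentration `dilution_step^-(i-1)`.
#' @return The efficiency estimate in \[0, 1\].
#' @examples
#' efficiency_from_dilution(c(20, 21, 22, 23), dilution_step = 2)  # 1.0
#' @export
efficiency_from_dilution <- function(ct, concentration = NULL,
                                     dilution_step = 2) {
  if (length(ct) < 3L) stop("need at least 3 dilution points")
  if (is.null(concentration)) {
    concentration <- dilution_step^-(seq_along(ct) - 1)
  }
  if (length(concentration) != length(ct)) {
    stop("'ct' and 'concentration' must have equal length")
  }
  x <- log2(concentration)
  if (stats::var(x) == 0) stop("dilution series is degenerate (one concentration)")
  slope <- unname(stats::coef(stats::lm(ct ~ x))[2L])
  if (!is.finite(slope) || slope == 0) {
    stop("dilution series has no Ct trend; cannot estimate efficiency")
  }
  eff <- 2^(-1 / slope) - 1
  tol <- 1e-9   # keep round-off at the boundaries from warning
  if (eff < -tol || eff > 1 + tol) {
    warning("efficiency estimate ", signif(eff, 4),
            " outside [0, 1]; clipping")
  }
  min(1, max(0, eff))
}

#' Average replicate Ct values from a long-format qPCR table
#'
#' Reduces a table with columns `gene`, `condition` and `ct` (one row per
#' replicate) to mean Ct per gene x condition, as expected by
#' [qpcr_measurement()].
#'
#' @param df Data.frame with columns `gene`, `condition`, `ct`.
#' @return Data.frame of mean Ct per gene and condition.
#' @export
mean_ct <- function(df) {
  for (col in c("gene", "condition", "ct")) {
    if (!col %in% names(df)) stop("qPCR table is missing column '", col, "'")
  }
  out <- stats::aggregate(ct ~ gene + condition, data = df, FUN = mean)
  names(out)[names(out) == "ct"] <- "mean_ct"
  out
}
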