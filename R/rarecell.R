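#' Rare-cell detection design
#'
#' A design point for the binomial detectability model: how many cells are
#' analyzed, the true prevalence of the positive cell type, the assay's
#' per-cell true and false positive rates, and the significance level. The
#' default rates are the assay's empirical estimates: TPR 97.1% and FPR
#' 0.02%.
#'
#' @param n_total Cells analyzed (>= 1).
#' @param prevalence True positive-cell fraction in \[0, 1\].
#' @param tpr True positive rate in \[0, 1\].
#' @param fpr False positive rate in \[0, 1\].
#' @param alpha Significance level in (0, 1).
#' @return An object of class `detection_design`.
#' @examples
#' detection_design(10000, prevalence = 0.001)
#' @export
detection_design <- function(n_total, prevalence, tpr = 0.971, fpr = 2e-4,
                             alpha = 0.05) {
  if (!is.finite(n_total) || n_total < 1) stop("'n_total' must be >= 1")
  for (p in c(prevalence, tpr, fpr)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("prevalence, tpr and fpr must lie in [0, 1]")
    }
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)")
  }
  structure(
    list(n_total = n_total, prevalence = prevalence, tpr = tpr, fpr = fpr,
         alpha = alpha),
    class = "detection_design"
  )
}

## Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Expected number of observed positive cells
#'
#' With `n_pos = n_total * prevalence` positive and `n_neg = n_total -
#' n_pos` negative cells, the expected positive count is
#' `n_neg * fpr + n_pos * tpr`; it may be non-integer.
#'
#' @param design A [detection_design()].
#' @return The expected count (numeric).
#' @examples
#' expected_positive_count(detection_design(10000, 0.001)) # 11.708
#' @export
expected_positive_count <- function(design) {
  stopifnot(inherits(design, "detection_design"))
  n_pos <- design$n_total * design$prevalence
  n_neg <- design$n_total - n_pos
  n_neg * design$fpr + n_pos * design$tpr
}

#' Binomial detection p-value against the pure-negative null
#'
#' The null model is the pure negative population: positives ~
#' Binomial(n_total, fpr). The observed count is the expected positive
#' count of the mixture, rounded half-up to the nearest integer, and the
#' p-value is the exact one-sided upper tail P(X >= k) (detection means an
#' excess of positives). A two-sided variant doubles the smaller tail,
#' capped at 1.
#'
#' @param design A [detection_design()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The p-value in (0, 1\].
#' @examples
#' detection_pvalue(detection_design(1e5, 1e-4)) # ~0.022
#' @export
detection_pvalue <- function(design, alternative = c("greater", "two.sided")) {
  stopifnot(inherits(design, "detection_design"))
  alternative <- match.arg(alternative)
  k <- round_half_up(expected_positive_count(design))
  n <- design$n_total
  upper <- stats::pbinom(k - 1, n, design$fpr, lower.tail = FALSE)
  if (alternative == "greater") return(upper)
  lower <- stats::pbinom(k, n, design$fpr)
  min(1, 2 * min(upper, lower))
}

#' Minimum detectable prevalence on a grid
#'
#' Scans an ascending prevalence grid and returns the smallest value whose
#' [detection_pvalue()] falls below `alpha`, or `NA` if none qualifies. The
#' default grid covers prevalences from one in a million to one in a
#' hundred in decade steps.
#'
#' @param n_total Cells analyzed.
#' @param tpr,fpr,alpha As in [detection_design()].
#' @param grid Ascending prevalence grid.
#' @return The minimum detectable prevalence (or `NA_real_`).
#' @examples
#' min_detectable_prevalence(1e5) # 1e-4: one in 10,000
#' @export
min_detectable_prevalence <- function(n_total, tpr = 0.971, fpr = 2e-4,
                                      alpha = 0.05, grid = 10^(-6:-2)) {
  if (length(grid) == 0L) stop("prevalence grid is empty")
  if (is.unsorted(grid)) stop("prevalence grid must be ascending")
  for (p in grid) {
    d <- detection_design(n_total, p, tpr = tpr, fpr = fpr, alpha = alpha)
    if (detection_pvalue(d) < alpha) return(p)
  }
  NA_real_
}

#' Limit-of-detection grid over cells analyzed x prevalence
#'
#' Full cross-product of sample sizes and prevalences; each cell carries
#' the exact binomial detection p-value and a detect flag (p < alpha).
#'
#' @param n_list Sample sizes (cells analyzed).
#' @param prevalence_list Prevalences.
#' @param tpr,fpr,alpha As in [detection_design()].
#' @return A data.frame with columns `n_total`, `prevalence`, `expected`,
#'   `p_value`, `detect`.
#' @export
lod_grid <- function(n_list, prevalence_list, tpr = 0.971, fpr = 2e-4,
                     alpha = 0.05) {
  if (length(n_list) == 0L || length(prevalence_list) == 0L) {
    stop("'n_list' and 'prevalence_list' must be non-empty")
  }
  g <- expand.grid(n_total = n_list, prevalence = prevalence_list,
                   KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(g)), function(i) {
    d <- detection_design(g$n_total[i], g$prevalence[i], tpr = tpr, fpr = fpr,
                          alpha = alpha)
    c(expected = expected_positive_count(d), p_value = detection_pvalue(d))
  })
  res <- do.call(rbind, res)
  g$expected <- res[, "expected"]
  g$p_value <- res[, "p_value"]
  g$detect <- g$p_value < alpha
  g
}

#' Simulate a mixture dilution series and fit measured vs true proportion
#'
#' For each true proportion p, draws the observed positive count as
#' Binomial(n_pos, tpr) + Binomial(n_neg, fpr) with `n_pos = round(p * n)`,
#' then fits an ordinary least-squares line of measured positive fraction
#' against true proportion. With the default rates the slope's expectation
#' is tpr - fpr and the fit is essentially perfect (R^2 = 1.00 to two
#' decimals at 10,000 cells per point).
#'
#' @param proportions True positive-cell proportions in \[0, 1\] (>= 2).
#' @param n_cells Cells analyzed per mixture point.
#' @param tpr,fpr Assay rates.
#' @param seed RNG seed.
#' @return A list with `data` (true vs measured fractions), `slope`,
#'   `intercept` and `r_squared`.
#' @examples
#' fit <- simulate_mixture_series(seq(0, 1, 0.25), n_cells = 10000, seed = 1)
#' fit$r_squared
#' @export
simulate_mixture_series <- function(proportions, n_cells = 10000, tpr = 0.971,
                                    fpr = 2e-4, seed = 1L) {
  if (length(proportions) < 2L) stop("need at least 2 mixture proportions")
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  set.seed(seed)
  n_pos <- round_half_up(proportions * n_cells)
  n_neg <- n_cells - n_pos
  positives <- stats::rbinom(length(proportions), n_pos, tpr) +
    stats::rbinom(length(proportions), n_neg, fpr)
  measured <- positives / n_cells
  fit <- stats::lm(measured ~ proportions)
  list(
    data = data.frame(true_proportion = proportions,
                      measured_fraction = measured),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    # a perfect fit is the expected regime here; summary.lm warns about it
    r_squared = suppressWarnings(summary(fit)$r.squared)
  )
}
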