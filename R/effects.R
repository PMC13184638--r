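# Absolute risk differences: convert pooled rate ratios into additional
# cases per million persons using the stratum baseline rate.

#' Baseline outcome rate in a stratum
#'
#' The baseline rate alpha is computed over the reference (NONE) exposure
#' person-time: 1e6 x total deaths during NONE months / total person-months
#' during NONE months, i.e. deaths per million persons per month.
#'
#' @param panel Labeled panel (optionally stratified).
#' @param outcome Counts column name.
#' @param stratum Stratum to restrict to (requires a `stratum` column),
#'   or `NULL` for the whole panel.
#' @return Baseline rate per million persons per month.
#' @export
baseline_rate <- function(panel, outcome = "deaths_firearm",
                          stratum = NULL) {
  sub <- panel
  if (!is.null(stratum)) {
    if (!"stratum" %in% names(panel)) stop("panel has no stratum column",
                                           call. = FALSE)
    sub <- panel[panel$stratum == stratum, , drop = FALSE]
  }
  sub <- sub[sub$exposure_label == "NONE", , drop = FALSE]
  pm <- sum(sub$population)
  if (!nrow(sub) || pm <= 0) {
    stop("no reference (NONE) person-time in this stratum", call. = FALSE)
  }
  1e6 * sum(sub[[outcome]]) / pm
}

#' Absolute risk difference from an incidence rate ratio
#'
#' ARD = alpha x (IRR - 1) / IRR: the additional cases per million persons
#' per month attributable to the exposure, where alpha is the stratum
#' baseline rate. The map is monotone increasing in IRR for alpha > 0, so
#' the 95% bounds are the same transform of the IRR interval endpoints.
#'
#' @param alpha Baseline rate (per million persons per month), > 0.
#' @param irr Pooled incidence rate ratio, > 0.
#' @param ci_low,ci_high Optional IRR interval endpoints
#'   (`0 < ci_low <= irr <= ci_high`).
#' @return List with `alpha`, `ard` and, when bounds are given, `ard_low`,
#'   `ard_high`.
#' @export
#' @examples
#' ard_from_irr(alpha = 10, irr = 2)           # ard = 5
#' ard_from_irr(7.162, 1.109, 1.091, 1.128)
ard_from_irr <- function(alpha, irr, ci_low = NULL, ci_high = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0",
                                             call. = FALSE)
  if (!is.numeric(irr) || irr <= 0) stop("irr must be > 0", call. = FALSE)
  f <- function(r) alpha * (r - 1) / r
  out <- list(alpha = alpha, ard = f(irr))
  if (!is.null(ci_low) || !is.null(ci_high)) {
    if (is.null(ci_low) || is.null(ci_high) || ci_low <= 0 ||
        ci_low > irr || ci_high < irr) {
      stop("need 0 < ci_low <= irr <= ci_high", call. = FALSE)
    }
    out$ard_low <- f(ci_low)
    out$ard_high <- f(ci_high)
  }
  out
}

#' Invert an absolute risk difference back to its rate ratio
#'
#' Exact inverse of [ard_from_irr()]: IRR = alpha / (alpha - ARD), defined
#' for `ard < alpha`.
#'
#' @inheritParams ard_from_irr
#' @param ard Absolute risk difference (same units as `alpha`).
#' @return The implied IRR.
#' @export
irr_from_ard <- function(alpha, ard) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (ard >= alpha) stop("ard must be < alpha", call. = FALSE)
  alpha / (alpha - ard)
}

#' Join pooled IRRs with baseline rates and ARDs
#'
#' @param pooled Pooled effects from [pool_estimates()].
#' @param panel Labeled panel used for the baseline rates.
#' @return `pooled` with `alpha`, `ard`, `ard_low`, `ard_high` columns.
#' @export
effects_table <- function(pooled, panel) {
  pooled$alpha <- NA_real_
  pooled$ard <- NA_real_
  pooled$ard_low <- NA_real_
  pooled$ard_high <- NA_real_
  for (i in seq_len(nrow(pooled))) {
    st <- if ("stratum" %in% names(panel) &&
              pooled$stratum[i] %in% panel$stratum) pooled$stratum[i]
          else NULL
    a <- baseline_rate(panel, pooled$outcome[i], st)
    # pooled interval endpoints can, in odd degenerate cases, not bracket
    # the point estimate exactly; clamp defensively
    lo <- min(pooled$ci_low[i], pooled$irr[i])
    hi <- max(pooled$ci_high[i], pooled$irr[i])
    r <- ard_from_irr(a, pooled$irr[i], lo, hi)
    pooled$alpha[i] <- r$alpha
    pooled$ard[i] <- r$ard
    pooled$ard_low[i] <- r$ard_low
    pooled$ard_high[i] <- r$ard_high
  }
  pooled
}
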