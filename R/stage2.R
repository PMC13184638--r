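# Stage 2: random-effects meta-analysis of county log-IRRs per exposure
# category, with the stability filter and county-coverage labeling.

#' Filter county estimates before pooling
#'
#' Default rule keeps estimates whose log-IRR standard error is at most
#' `se_max` (boundary inclusive: "greater than 2" excludes strictly above
#' the threshold). Alternatively a minimum-population rule can be applied
#' for sensitivity analysis. The exclusion report profiles the dropped
#' counties (population median and share of time in drought) when the
#' panel is supplied.
#'
#' @param estimates Data frame from [fit_county_models()].
#' @param se_max Maximum allowed standard error (log-IRR scale).
#' @param population_min Optional minimum county population; when given it
#'   replaces the SE rule.
#' @param panel Optional labeled panel used to profile exclusions and to
#'   look up county populations for the population rule.
#' @return List with `included`, `excluded` (estimate rows) and `report`
#'   (one-row summary of the excluded counties).
#' @export
filter_estimates <- function(estimates, se_max = 2, population_min = NULL,
                             panel = NULL) {
  if (!all(is.finite(estimates$se))) {
    stop("estimates must carry finite standard errors", call. = FALSE)
  }
  if (is.null(population_min)) {
    keep <- estimates$se <= se_max
  } else {
    if (is.null(panel)) stop("population rule needs the panel",
                             call. = FALSE)
    pops <- tapply(panel$population, panel$county_id, stats::median)
    keep <- pops[estimates$county_id] >= population_min
  }
  included <- estimates[keep, , drop = FALSE]
  excluded <- estimates[!keep, , drop = FALSE]
  report <- data.frame(n_excluded_estimates = nrow(excluded),
                       n_excluded_counties =
                         length(unique(excluded$county_id)),
                       median_population = NA_real_,
                       median_drought_share = NA_real_)
  if (!is.null(panel) && nrow(excluded)) {
    cids <- unique(excluded$county_id)
    sub <- panel[panel$county_id %in% cids, , drop = FALSE]
    report$median_population <-
      stats::median(tapply(sub$population, sub$county_id, stats::median))
    drought <- sub$exposure_label %in% c("M2SD_WRS", "S2ED_WRS",
                                         "S2ED_IMP", "M2SD_IMP")
    report$median_drought_share <-
      stats::median(tapply(drought, sub$county_id, mean)) * 100
  }
  list(included = included, excluded = excluded, report = report)
}

#' Pool county log-IRRs by random-effects meta-analysis
#'
#' Inverse-variance pooling with between-county variance estimated by
#' restricted maximum likelihood (or DerSimonian-Laird), Wald 95% interval
#' on the log scale, exponentiated to the IRR scale. A single estimate
#' passes through with a warning; degenerate inputs with all-zero standard
#' errors fall back to their exact average.
#'
#' @param log_irr,se Numeric vectors of county estimates and standard
#'   errors.
#' @param method `"REML"` (default) or `"DL"`.
#' @param n_eligible Number of counties eligible for this category (for
#'   the coverage fraction); defaults to `length(log_irr)`.
#' @return List: `irr`, `ci_low`, `ci_high`, `log_irr`, `se`, `tau2`,
#'   `n_included`, `n_eligible`, `coverage`, `coverage_flag`.
#' @export
pool_random_effects <- function(log_irr, se, method = "REML",
                                n_eligible = length(log_irr)) {
  if (length(log_irr) == 0L) stop("no estimates to pool", call. = FALSE)
  if (length(log_irr) != length(se)) stop("length mismatch", call. = FALSE)
  if (all(se == 0)) {
    mu <- mean(log_irr)
    t2 <- if (length(log_irr) > 1L) stats::var(log_irr) else 0
    res <- list(mu = mu, se = 0, tau2 = t2, ci_lb = mu, ci_ub = mu)
    warning("all standard errors are zero; returning the exact average")
  } else if (length(log_irr) == 1L) {
    warning("single estimate; pass-through, no heterogeneity estimable")
    res <- list(mu = log_irr, se = se, tau2 = 0,
                ci_lb = log_irr - 1.96 * se, ci_ub = log_irr + 1.96 * se)
  } else {
    fit <- tryCatch(
      metafor::rma.uni(yi = log_irr, sei = se, method = method,
                       control = list(maxiter = 500, stepadj = 0.5)),
      error = function(e) NULL)
    if (is.null(fit) && method != "DL") {
      # Fisher scoring for REML can fail on pathological inputs; the
      # moment-based estimator always exists
      warning("REML did not converge; falling back to DerSimonian-Laird")
      fit <- metafor::rma.uni(yi = log_irr, sei = se, method = "DL")
    }
    if (is.null(fit)) stop("meta-analysis failed to converge", call. = FALSE)
    res <- list(mu = as.numeric(fit$b), se = fit$se, tau2 = fit$tau2,
                ci_lb = res_ci(fit)[1], ci_ub = res_ci(fit)[2])
  }
  n_inc <- length(log_irr)
  cov <- n_inc / n_eligible
  list(irr = exp(res$mu), ci_low = exp(res$ci_lb),
       ci_high = exp(res$ci_ub), log_irr = res$mu, se = res$se,
       tau2 = res$tau2, n_included = n_inc, n_eligible = n_eligible,
       coverage = cov, coverage_flag = coverage_label(n_inc, n_eligible))
}

# Wald interval on the log scale (z-based, matching the 95% CI convention)
res_ci <- function(fit) {
  mu <- as.numeric(fit$b)
  c(mu - stats::qnorm(0.975) * fit$se, mu + stats::qnorm(0.975) * fit$se)
}

#' Coverage label for a pooled estimate
#'
#' `"over85"` when strictly more than 85% of eligible counties contributed,
#' `"under85"` otherwise.
#'
#' @param n_included,n_eligible County counts.
#' @return `"over85"` or `"under85"`.
#' @export
coverage_label <- function(n_included, n_eligible) {
  if (n_eligible <= 0) stop("n_eligible must be positive", call. = FALSE)
  if (n_included / n_eligible > 0.85) "over85" else "under85"
}

#' Pool every outcome x stratum x category group
#'
#' @param estimates Filtered estimates (the `included` element of
#'   [filter_estimates()]).
#' @param n_eligible Eligible-county denominator for the coverage label
#'   (default: all counties appearing in the unfiltered input panel, passed
#'   by the caller; falls back to counties present in `estimates`).
#' @param method Heterogeneity estimator, `"REML"` or `"DL"`.
#' @return Data frame with one row per group: pooled `irr`, `ci_low`,
#'   `ci_high`, `log_irr`, `se`, `tau2`, `n_included`, `n_eligible`,
#'   `coverage_flag`.
#' @export
pool_estimates <- function(estimates, n_eligible = NULL, method = "REML") {
  if (!nrow(estimates)) stop("no estimates to pool", call. = FALSE)
  if (is.null(n_eligible)) n_eligible <- length(unique(estimates$county_id))
  groups <- unique(estimates[, c("outcome", "stratum", "category")])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- estimates[estimates$outcome == g$outcome &
                     estimates$stratum == g$stratum &
                     estimates$category == g$category, , drop = FALSE]
    p <- suppressWarnings(
      pool_random_effects(sub$log_irr, sub$se, method = method,
                          n_eligible = n_eligible))
    out[[i]] <- data.frame(outcome = g$outcome, stratum = g$stratum,
                           category = g$category, irr = p$irr,
                           ci_low = p$ci_low, ci_high = p$ci_high,
                           log_irr = p$log_irr, se = p$se, tau2 = p$tau2,
                           n_included = p$n_included,
                           n_eligible = p$n_eligible,
                           coverage_flag = p$coverage_flag,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
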