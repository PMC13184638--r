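# Stage 1 of the two-stage design: one negative-binomial count model per
# county (and outcome/stratum), exposure category with NONE as reference,
# season dummies, unpenalized natural-spline smooths for temperature and
# time, and a log-population offset. Smooth complexity is chosen per
# county by AIC over a knot grid.

KNOT_GRID_TEMP <- 2:5
KNOT_GRID_TIME <- 3:6

#' Build the stage-1 model frame and formula for one county
#'
#' The design is: intercept + exposure dummies (reference `NONE`) + three
#' season dummies + a natural cubic spline in temperature with `k_temp`
#' knots (basis dimension `k_temp - 1`) + a natural cubic spline in the
#' month index 1..T with `k_time` knots (basis dimension `k_time - 1`),
#' with `log(population)` as offset. Exposure levels absent from the county
#' are dropped and reported; a constant temperature (or time) series
#' collapses its spline term, which is then dropped and flagged.
#'
#' @param panel One county's rows: `exposure_label`, `season`,
#'   `temperature`, `month_index`, `population`, and the counts column.
#' @param outcome Name of the counts column (e.g. `"deaths_firearm"`).
#' @param k_temp,k_time Knot counts for the temperature and time smooths.
#' @return List with `formula`, `data` (model frame), `excluded_categories`,
#'   `dropped_terms`, and `n_params` (columns + 1 for the NB dispersion).
#' @export
build_design <- function(panel, outcome, k_temp = 4L, k_time = 4L) {
  need <- c("exposure_label", "season", "temperature", "month_index",
            "population", outcome)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(panel$population <= 0)) stop("populations must be positive",
                                       call. = FALSE)
  present <- intersect(EXPOSURE_LEVELS, unique(panel$exposure_label))
  excluded <- setdiff(EXPOSURE_LEVELS, present)
  d <- data.frame(
    y = panel[[outcome]],
    exposure = factor(panel$exposure_label, levels = present),
    season = factor(as.character(panel$season),
                    levels = c("DJF", "MAM", "JJA", "SON")),
    temperature = panel$temperature,
    time = panel$month_index,
    log_pop = log(panel$population)
  )
  d$season <- droplevels(d$season)
  terms <- character(0)
  if (length(present) > 1L) terms <- c(terms, "exposure")
  if (nlevels(d$season) > 1L) terms <- c(terms, "season")
  dropped <- character(0)
  if (length(unique(d$temperature)) > k_temp) {
    terms <- c(terms, sprintf("splines::ns(temperature, df = %d)",
                              k_temp - 1L))
  } else {
    dropped <- c(dropped, "temperature")
  }
  if (length(unique(d$time)) > k_time) {
    terms <- c(terms, sprintf("splines::ns(time, df = %d)", k_time - 1L))
  } else {
    dropped <- c(dropped, "time")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("y ~", rhs, "+ offset(log_pop)"))
  n_cols <- 1L + (length(present) - 1L) + (nlevels(d$season) - 1L) +
    (if ("temperature" %in% dropped) 0L else k_temp - 1L) +
    (if ("time" %in% dropped) 0L else k_time - 1L)
  list(formula = f, data = d, excluded_categories = excluded,
       dropped_terms = dropped, n_params = n_cols + 1L)
}

#' Fit one negative-binomial county model
#'
#' Maximum-likelihood fit (coefficients and dispersion jointly) of the
#' stage-1 design. AIC counts every estimated parameter including the
#' dispersion. Non-convergence (including all-zero counts) is reported,
#' not raised.
#'
#' @inheritParams build_design
#' @return List with `coefficients` (per-exposure `log_irr`, `se`), `aic`,
#'   `loglik`, `theta`, `converged`, `excluded_categories`, `k_temp`,
#'   `k_time`.
#' @export
fit_nb_model <- function(panel, outcome, k_temp = 4L, k_time = 4L) {
  des <- build_design(panel, outcome, k_temp, k_time)
  out <- list(coefficients = data.frame(category = character(0),
                                        log_irr = numeric(0),
                                        se = numeric(0)),
              aic = Inf, loglik = NA_real_, theta = NA_real_,
              converged = FALSE,
              excluded_categories = des$excluded_categories,
              k_temp = k_temp, k_time = k_time)
  if (sum(des$data$y) == 0) return(out)  # no information: non-convergence
  # without deaths under the reference exposure the reference rate (and so
  # every rate ratio) is not estimable; the likelihood diverges
  if (!"NONE" %in% levels(des$data$exposure) ||
      sum(des$data$y[des$data$exposure == "NONE"]) == 0) {
    return(out)
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(des$formula, data = des$data,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  capped <- FALSE
  if (is.null(fit) || fit$theta > 1e5) {
    # dispersion at/near the Poisson boundary: refit with theta capped
    fit <- tryCatch(
      suppressWarnings(stats::glm(des$formula, data = des$data,
                                  family = MASS::negative.binomial(1e5),
                                  control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    fit$theta <- 1e5
    capped <- TRUE
  }
  cf <- summary(fit)$coefficients
  rows <- grep("^exposure", rownames(cf))
  coefs <- data.frame(
    category = sub("^exposure", "", rownames(cf)[rows]),
    log_irr = cf[rows, "Estimate"],
    se = cf[rows, "Std. Error"],
    stringsAsFactors = FALSE
  )
  # rank-deficient fits leave NA coefficients; treat those levels as absent
  na_lv <- setdiff(sub("^exposure", "",
                       grep("^exposure", names(stats::coef(fit)),
                            value = TRUE)),
                   coefs$category)
  # quasi-separated categories (deaths only, or never, in a handful of
  # months) drift to divergent coefficients whose curvature-based SE is
  # meaningless; treat them as unstable rather than report them
  separated <- abs(coefs$log_irr) > 10
  out$coefficients <- coefs[is.finite(coefs$log_irr) & coefs$se > 0 &
                              !separated, , drop = FALSE]
  out$excluded_categories <- union(out$excluded_categories,
                                   c(na_lv, coefs$category[separated]))
  out$loglik <- as.numeric(stats::logLik(fit))
  # AIC parameter count = coefficients + 1 for the dispersion, also when
  # the dispersion sits capped at the boundary
  out$aic <- if (capped) stats::AIC(fit) + 2 else stats::AIC(fit)
  out$theta <- fit$theta
  out$converged <- isTRUE(fit$converged) && is.finite(out$aic)
  out
}

#' Select smooth complexity for one county by AIC
#'
#' Fits every combination of the temperature and time knot grids (16 by
#' default) and keeps the converged fit with the lowest AIC. Ties are
#' broken deterministically toward parsimony: smallest `k_temp + k_time`,
#' then smallest `k_temp`.
#'
#' @inheritParams build_design
#' @param temp_grid,time_grid Integer knot grids.
#' @return The winning [fit_nb_model()] result with `n_fits` and an
#'   `aic_table` of all attempted combinations; `NULL` fit results set
#'   `converged = FALSE` everywhere.
#' @export
select_knots <- function(panel, outcome, temp_grid = KNOT_GRID_TEMP,
                         time_grid = KNOT_GRID_TIME) {
  grid <- expand.grid(k_temp = temp_grid, k_time = time_grid)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_nb_model(panel, outcome, grid$k_temp[i],
                              grid$k_time[i])
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  tab <- cbind(grid, aic = aics, converged = conv)
  if (!any(conv)) {
    best <- fits[[1L]]
    best$converged <- FALSE
  } else {
    cand <- which(conv & aics <= min(aics[conv]) + 1e-9)
    ord <- order(grid$k_temp[cand] + grid$k_time[cand], grid$k_temp[cand])
    best <- fits[[cand[ord][1L]]]
  }
  best$n_fits <- nrow(grid)
  best$aic_table <- tab
  best
}

#' Fit stage-1 models for every county (and stratum) in a panel
#'
#' @param panel Labeled panel (optionally with a `stratum` column).
#' @param outcomes Counts columns to model.
#' @param knots `"grid"` for per-county AIC selection over the 16-
#'   combination grid, or a length-2 integer vector (e.g. `c(4, 4)`) to fit
#'   that single combination everywhere.
#' @return Data frame with one row per county x outcome x stratum x
#'   exposure category: `county_id`, `outcome`, `stratum`, `category`,
#'   `log_irr`, `se`, `aic`, `k_temp`, `k_time`, `converged`. Attribute
#'   `fit_log` records non-converged or level-deficient fits with a
#'   machine-readable reason.
#' @export
fit_county_models <- function(panel,
                              outcomes = c("deaths_firearm",
                                           "deaths_nonfirearm"),
                              knots = "grid") {
  strata <- if ("stratum" %in% names(panel)) unique(panel$stratum)
            else "total"
  counties <- unique(panel$county_id)
  rows <- list()
  log_rows <- list()
  for (st in strata) {
    sub <- if ("stratum" %in% names(panel))
      panel[panel$stratum == st, , drop = FALSE] else panel
    for (cid in counties) {
      cdat <- sub[sub$county_id == cid, , drop = FALSE]
      for (oc in outcomes) {
        res <- if (identical(knots, "grid")) {
          select_knots(cdat, oc)
        } else {
          fit_nb_model(cdat, oc, knots[1L], knots[2L])
        }
        if (!res$converged) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            county_id = cid, outcome = oc, stratum = st,
            reason = "nonconvergence", detail = "")
          next
        }
        if (length(res$excluded_categories)) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            county_id = cid, outcome = oc, stratum = st,
            reason = "level-absent",
            detail = paste(res$excluded_categories, collapse = ";"))
        }
        if (nrow(res$coefficients)) {
          rows[[length(rows) + 1L]] <- data.frame(
            county_id = cid, outcome = oc, stratum = st,
            category = res$coefficients$category,
            log_irr = res$coefficients$log_irr,
            se = res$coefficients$se,
            aic = res$aic, k_temp = res$k_temp, k_time = res$k_time,
            converged = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  est <- if (length(rows)) do.call(rbind, rows) else
    data.frame(county_id = character(0), outcome = character(0),
               stratum = character(0), category = character(0),
               log_irr = numeric(0), se = numeric(0), aic = numeric(0),
               k_temp = integer(0), k_time = integer(0),
               converged = logical(0))
  rownames(est) <- NULL
  attr(est, "fit_log") <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(county_id = character(0), outcome = character(0),
                    stratum = character(0), reason = character(0),
                    detail = character(0))
  attr(est, "n_counties") <- length(counties)
  est
}

#' Most frequently selected knot combination across counties
#'
#' Diagnostic summary of the per-county AIC selection: the modal
#' `(k_temp, k_time)` pair and the full frequency table. Reported
#' descriptively; it does not trigger refitting.
#'
#' @param estimates Output of [fit_county_models()].
#' @return List with `modal` (data frame of the tied modal pair(s)) and
#'   `table` (frequencies over county x outcome x stratum fits).
#' @export
national_modal_knots <- function(estimates) {
  u <- unique(estimates[, c("county_id", "outcome", "stratum",
                            "k_temp", "k_time")])
  if (!nrow(u)) stop("no converged county fits", call. = FALSE)
  key <- paste(u$k_temp, u$k_time, sep = "-")
  tab <- sort(table(key), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  parts <- do.call(rbind, strsplit(top, "-"))
  list(modal = data.frame(k_temp = as.integer(parts[, 1]),
                          k_time = as.integer(parts[, 2]),
                          n = as.integer(tab[top])),
       table = tab)
}
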