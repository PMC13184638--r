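# End-to-end orchestration: ingest or simulate a panel, label exposures,
# fit county models, pool, convert to ARDs, and write the artifact set.

#' Default county-identifier recode table
#'
#' Harmonizes known county reorganizations so mortality time series stay
#' continuous: Shannon County, SD to Oglala Lakota County (46113 -> 46102)
#' and Bedford city, VA into Bedford County (51515 -> 51019).
#'
#' @return Data frame with columns `from`, `to`.
#' @export
fips_recodes <- function() {
  data.frame(from = c("46113", "51515"), to = c("46102", "51019"),
             stringsAsFactors = FALSE)
}

#' Read a county-month panel CSV
#'
#' Validates the pipeline schema, zero-pads county identifiers, applies
#' the FIPS recode table, and derives `month_index` (1..T per county, from
#' year/month) and `season` when absent. The file needs `county_id`,
#' `year`, `month`, `population`, `temperature`, at least one
#' `deaths_*` column, and either `percentile`, `eddi`, or `category`;
#' `eddi` values are rank-transformed to dryness percentiles within county
#' and calendar month.
#'
#' @param path CSV path.
#' @param recode Apply [fips_recodes()] (summing counts across merged
#'   counties is the caller's job; recoding only renames).
#' @return Panel data frame.
#' @export
read_panel_csv <- function(path, recode = TRUE) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(county_id = "character"))
  required <- c("county_id", "year", "month", "population", "temperature")
  miss <- setdiff(required, names(panel))
  if (!any(grepl("^deaths_", names(panel)))) miss <- c(miss, "deaths_<outcome>")
  if (!any(c("percentile", "eddi", "category") %in% names(panel))) {
    miss <- c(miss, "percentile|eddi|category")
  }
  if (length(miss)) {
    stop("panel CSV missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  panel$county_id <- sprintf("%05d", as.integer(panel$county_id))
  if (recode) {
    rc <- fips_recodes()
    m <- match(panel$county_id, rc$from)
    panel$county_id[!is.na(m)] <- rc$to[m[!is.na(m)]]
  }
  if (!"month_index" %in% names(panel)) {
    base <- min(panel$year * 12L + panel$month)
    panel$month_index <- panel$year * 12L + panel$month - base + 1L
  }
  if (!"season" %in% names(panel)) {
    panel$season <- season_of_month(panel$month)
  }
  if (!"percentile" %in% names(panel) && "eddi" %in% names(panel)) {
    panel$percentile <- NA_real_
    for (cid in unique(panel$county_id)) {
      i <- panel$county_id == cid
      panel$percentile[i] <- index_to_percentile(panel$eddi[i],
                                                 panel$month[i])
    }
  }
  panel
}

#' Percentages over a set of category counts
#'
#' Shares computed against the sum of the supplied counts themselves (the
#' categorized denominator), rounded to two decimals. This is the
#' convention for exposure rows of the descriptive summary: deaths whose
#' exposure is unknown are absent from both numerator and denominator.
#'
#' @param counts Named non-negative numeric vector.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' exposure_percentages(c(NONE = 55, M2SD_WRS = 25, WET = 20))
exposure_percentages <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  round(100 * counts / sum(counts), 2)
}

#' Descriptive summary of a labeled panel
#'
#' Reproduces the structure of a baseline-characteristics table:
#' person-based rows (death counts and shares by stratum and urbanicity,
#' denominator = outcome total), exposure rows (death counts per exposure
#' category, denominator = the sum of the six category counts), and
#' county-month frequencies per category (denominator = total
#' county-months). Shares are rounded to two decimals.
#'
#' @param panel Labeled panel; every row must carry an `exposure_label`.
#' @param outcomes Death-count columns to summarize.
#' @return List of data frames: `persons` (NULL without stratum/urbanicity
#'   columns), `exposure_deaths`, `county_months`.
#' @export
descriptive_summary <- function(panel,
                                outcomes = grep("^deaths_", names(panel),
                                                value = TRUE)) {
  if (!nrow(panel)) stop("empty panel", call. = FALSE)
  if (anyNA(panel$exposure_label)) {
    stop("panel contains unlabeled county-months", call. = FALSE)
  }
  lev <- EXPOSURE_LEVELS
  persons <- NULL
  pvars <- intersect(c("stratum", "urbanicity"), names(panel))
  if (length(pvars)) {
    rows <- list()
    for (v in pvars) {
      for (oc in outcomes) {
        tot <- sum(panel[[oc]])
        agg <- tapply(panel[[oc]], panel[[v]], sum)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = names(agg), outcome = oc,
          deaths = as.integer(agg),
          pct = round(100 * as.numeric(agg) / tot, 2),
          stringsAsFactors = FALSE)
      }
    }
    persons <- do.call(rbind, rows)
    rownames(persons) <- NULL
  }
  exp_rows <- list()
  for (oc in outcomes) {
    agg <- tapply(panel[[oc]], factor(panel$exposure_label, levels = lev),
                  sum, default = 0)
    exp_rows[[oc]] <- data.frame(
      category = lev, outcome = oc, deaths = as.integer(agg),
      pct = exposure_percentages(as.numeric(agg)),
      stringsAsFactors = FALSE)
  }
  exposure_deaths <- do.call(rbind, exp_rows)
  rownames(exposure_deaths) <- NULL
  cm <- table(factor(panel$exposure_label, levels = lev))
  county_months <- data.frame(
    category = lev, n = as.integer(cm),
    pct = round(100 * as.integer(cm) / nrow(panel), 2),
    stringsAsFactors = FALSE)
  list(persons = persons, exposure_deaths = exposure_deaths,
       county_months = county_months)
}

#' Run the full two-stage pipeline and write its artifacts
#'
#' Simulates (or ingests) a county-month panel, labels drought exposures,
#' fits the per-county negative-binomial models, pools them by
#' random-effects meta-analysis with the stability filter, converts pooled
#' IRRs to absolute risk differences, and writes every table plus a JSON
#' run manifest. Deterministic given the configuration (which carries the
#' seed); individual county failures are logged and excluded, never fatal.
#'
#' @param config A [sim_config()]; in csv mode it still supplies bins,
#'   event duration, and metadata.
#' @param input_csv Optional panel CSV path; when given the panel is read
#'   instead of simulated.
#' @param output_dir Directory for artifacts; created if needed. `NULL`
#'   skips writing.
#' @param outcomes Death-count columns to analyze.
#' @param knots `"grid"` or a fixed `c(k_temp, k_time)` pair.
#' @param se_max SE inclusion threshold for the meta-analysis.
#' @param population_min Optional population threshold replacing the SE
#'   rule (sensitivity mode).
#' @param method Heterogeneity estimator, `"REML"` or `"DL"`.
#' @return (Invisibly) list with `panel`, `estimates`, `pooled`, `effects`,
#'   `summary`, `exclusions`, `modal_knots`, `fit_log`.
#' @export
run_pipeline <- function(config = sim_config(),
                         input_csv = NULL,
                         output_dir = NULL,
                         outcomes = NULL,
                         knots = "grid",
                         se_max = 2,
                         population_min = NULL,
                         method = "REML") {
  if (is.null(input_csv)) {
    panel <- simulate_panel(config)
  } else {
    panel <- read_panel_csv(input_csv)
    if (!"exposure_label" %in% names(panel)) {
      panel <- label_exposure(panel, bins = config$bins,
                              min_duration = config$min_duration)
    }
  }
  if (is.null(outcomes)) {
    outcomes <- grep("^deaths_", names(panel), value = TRUE)
  }
  summary_tabs <- descriptive_summary(panel, outcomes)
  estimates <- fit_county_models(panel, outcomes, knots = knots)
  if (!nrow(estimates)) stop("no county model converged", call. = FALSE)
  filt <- filter_estimates(estimates, se_max = se_max,
                           population_min = population_min, panel = panel)
  pooled <- pool_estimates(filt$included,
                           n_eligible = length(unique(panel$county_id)),
                           method = method)
  effects <- effects_table(pooled, panel)
  modal <- national_modal_knots(estimates)
  out <- list(panel = panel, estimates = estimates, pooled = pooled,
              effects = effects, summary = summary_tabs,
              exclusions = filt$report, excluded = filt$excluded,
              modal_knots = modal, fit_log = attr(estimates, "fit_log"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(x, file.path(output_dir, f),
                                          row.names = FALSE)
    wr(panel[, c("county_id", "year", "month", "category", "event_id",
                 "phase", "exposure_label")], "exposure_labels.csv")
    wr(estimates, "county_estimates.csv")
    wr(effects, "pooled_effects.csv")
    wr(summary_tabs$exposure_deaths, "summary_exposure_deaths.csv")
    wr(summary_tabs$county_months, "summary_county_months.csv")
    if (!is.null(summary_tabs$persons)) wr(summary_tabs$persons,
                                           "summary_persons.csv")
    wr(filt$report, "exclusion_report.csv")
    wr(out$fit_log, "fit_log.csv")
    wr(modal$modal, "modal_knots.csv")
    manifest <- list(
      mode = if (is.null(input_csv)) "simulate" else "csv",
      seed = config$seed, n_counties = config$n_counties,
      n_months = config$n_months, timescale = config$timescale,
      outcomes = outcomes, knots = knots, se_max = se_max,
      population_min = population_min, method = method,
      planted_log_irr = config$true_log_irr,
      baseline_rate = config$baseline_rate,
      dispersion = config$dispersion)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
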