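# Seeded synthetic county-month panels with the structure the two-stage
# analysis assumes: persistent AR(1) drought, seasonal temperature,
# log-normal county populations, and rare overdispersed death counts.

#' Meteorological season of a calendar month
#'
#' @param month Integer 1-12.
#' @return Factor with levels DJF, MAM, JJA, SON.
#' @export
season_of_month <- function(month) {
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}

# Deterministic per-stream seed below 2^31, so each county's series is
# reproducible independently of call order.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483587)
}

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the study conditions of a national county-month suicide
#' panel: 228 months (19 years), strongly persistent 12-month-scale drought
#' (AR(1) coefficient 0.95), heavy-tailed log-normal county populations
#' (median 25,000), a baseline firearm suicide rate of about 7.2 deaths per
#' million adults per month, a slow upward secular trend, mild seasonality
#' peaking in spring, and a smooth temperature-rate curve. Planted
#' log rate ratios default to the headline national estimates this class of
#' analysis reports (e.g. IRR 1.109 for worsening severe-to-exceptional
#' drought, firearm), so recovery tests target realistic effect sizes.
#'
#' @param n_counties Number of counties.
#' @param n_months Panel length in months (>= 24); default 228.
#' @param seed Integer master seed.
#' @param population_meanlog,population_sdlog Log-normal county population
#'   parameters (persons).
#' @param eddi_ar1 AR(1) persistence of the latent drought driver, in
#'   \[0, 1); higher values give longer drought runs.
#' @param true_log_irr Named vector (or list with elements `firearm`,
#'   `nonfirearm`) of planted log rate ratios per exposure label; `NONE`
#'   must be 0.
#' @param season_effects Named additive log-rate effects for DJF/MAM/JJA/SON
#'   (reference DJF = 0).
#' @param temp_effect Length-2 numeric: linear and quadratic coefficients of
#'   centered temperature (degrees C about 12) on the log rate.
#' @param trend_effect Log-rate slope per month of a linear secular trend,
#'   centered mid-panel.
#' @param baseline_rate Deaths per person-month under NONE exposure at the
#'   covariate center.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); counts approach Poisson as it grows.
#' @param bins Percentile bin-edge table used for labeling.
#' @param min_duration Minimum drought-event duration (months).
#' @param timescale Drought-index timescale tag (6 or 12); metadata only.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_counties = 50L,
                       n_months = 228L,
                       seed = 20260101L,
                       population_meanlog = log(25000),
                       population_sdlog = 1.5,
                       eddi_ar1 = 0.95,
                       true_log_irr = list(
                         firearm = c(NONE = 0,
                                     M2SD_WRS = log(1.031),
                                     S2ED_WRS = log(1.109),
                                     S2ED_IMP = log(1.094),
                                     M2SD_IMP = log(1.024),
                                     WET = 0),
                         nonfirearm = c(NONE = 0,
                                        M2SD_WRS = log(1.017),
                                        S2ED_WRS = log(1.057),
                                        S2ED_IMP = log(1.073),
                                        M2SD_IMP = log(1.029),
                                        WET = 0)),
                       season_effects = c(DJF = 0, MAM = 0.08,
                                          JJA = 0.05, SON = 0.01),
                       temp_effect = c(0.003, -5e-5),
                       trend_effect = 0.0013,
                       baseline_rate = 7.16e-6,
                       dispersion = 20,
                       bins = usdm_bins(),
                       min_duration = 2L,
                       timescale = 12L) {
  if (n_months < 24L) stop("n_months must be >= 24", call. = FALSE)
  if (baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (eddi_ar1 < 0 || eddi_ar1 >= 1) {
    stop("eddi_ar1 must be in [0, 1)", call. = FALSE)
  }
  if (!is.list(true_log_irr)) {
    true_log_irr <- list(firearm = true_log_irr, nonfirearm = true_log_irr)
  }
  for (v in true_log_irr) {
    if (!all(EXPOSURE_LEVELS %in% names(v))) {
      stop("true_log_irr must name every exposure level", call. = FALSE)
    }
    if (v[["NONE"]] != 0) stop("true_log_irr['NONE'] must be 0",
                               call. = FALSE)
  }
  validate_bins(bins)
  structure(list(n_counties = as.integer(n_counties),
                 n_months = as.integer(n_months), seed = as.integer(seed),
                 population_meanlog = population_meanlog,
                 population_sdlog = population_sdlog, eddi_ar1 = eddi_ar1,
                 true_log_irr = true_log_irr,
                 season_effects = season_effects, temp_effect = temp_effect,
                 trend_effect = trend_effect, baseline_rate = baseline_rate,
                 dispersion = dispersion, bins = bins,
                 min_duration = as.integer(min_duration),
                 timescale = timescale),
            class = "sim_config")
}

#' Simulate one county's dryness-percentile series
#'
#' The latent drought driver is a stationary Gaussian AR(1); percentiles
#' are its exact marginal probability transform (times 100), so over long
#' horizons each category's occupancy equals its bin width while
#' persistence produces USDM-like multi-month drought runs.
#'
#' @param config A [sim_config()].
#' @param county_index Integer county number (its RNG stream).
#' @return Numeric vector of dryness percentiles, length `n_months`.
#' @export
simulate_drought_series <- function(config, county_index) {
  phi <- config$eddi_ar1
  n <- config$n_months
  set.seed(derive_seed(config$seed, county_index))
  sigma <- 1 / sqrt(1 - phi^2)
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sigma)
  innov <- stats::rnorm(n - 1)
  for (t in seq_len(n - 1L)) z[t + 1L] <- phi * z[t] + innov[t]
  100 * stats::pnorm(z, sd = sigma)
}

# Seasonal sinusoid (peak July) with county-specific amplitude plus noise.
simulate_temperature <- function(config, county_index) {
  set.seed(derive_seed(config$seed, 10000000 + county_index))
  n <- config$n_months
  amp <- stats::runif(1, 8, 13)
  mean_t <- stats::runif(1, 8, 16)
  month <- ((seq_len(n) - 1L) %% 12L) + 1L
  mean_t + amp * cos(2 * pi * (month - 7) / 12) + stats::rnorm(n, 0, 1.5)
}

# Log relative rate implied by the planted covariate effects (exposure
# excluded); temperature centered at 12 C, time centered mid-panel.
planted_eta <- function(config, season, temperature, month_index) {
  tc <- temperature - 12
  config$season_effects[as.character(season)] +
    config$temp_effect[1] * tc + config$temp_effect[2] * tc^2 +
    config$trend_effect * (month_index - (config$n_months + 1) / 2)
}

#' Draw negative-binomial death counts for a labeled panel
#'
#' Counts are drawn with mean `population * baseline_rate * exp(season +
#' f(temperature) + trend + true_log_irr[exposure])` and the configured
#' dispersion, i.e. the generator inverts the first-stage model.
#'
#' @param config A [sim_config()].
#' @param panel Data frame with `exposure_label`, `season`, `temperature`,
#'   `population`, `month_index`.
#' @param outcome `"firearm"` or `"nonfirearm"` (selects planted effects).
#' @param stream Extra RNG stream offset so outcomes are independent.
#' @return Integer vector of death counts, one per panel row.
#' @export
simulate_counts <- function(config, panel, outcome = "firearm",
                            stream = 0L) {
  irr <- config$true_log_irr[[outcome]]
  if (is.null(irr)) stop("no planted effects for outcome ", outcome,
                         call. = FALSE)
  eta <- planted_eta(config, panel$season, panel$temperature,
                     panel$month_index)
  mu <- panel$population * config$baseline_rate *
    exp(eta + irr[panel$exposure_label])
  if (any(!is.finite(mu)) || any(mu > panel$population)) {
    stop("configured mean exceeds population; check rates/effects",
         call. = FALSE)
  }
  set.seed(derive_seed(config$seed,
                       20000000 + stream + match(outcome,
                                                 names(config$true_log_irr))))
  stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
}

#' Generate a complete labeled synthetic county-month panel
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per county-month: `county_id` (zero-
#'   padded FIPS-style), `year`, `month`, `month_index`, `season`,
#'   `temperature`, `population`, `percentile`, `category`, `event_id`,
#'   `phase`, `exposure_label`, `deaths_firearm`, `deaths_nonfirearm`,
#'   `urbanicity`.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_counties = 3, n_months = 48))
#' table(panel$exposure_label)
simulate_panel <- function(config) {
  n <- config$n_months
  set.seed(derive_seed(config$seed, 999))
  pops <- round(stats::rlnorm(config$n_counties,
                              config$population_meanlog,
                              config$population_sdlog))
  pops <- pmax(pops, 100)
  metro <- stats::runif(config$n_counties) <
    stats::plogis((log(pops) - log(40000)) / 0.8)
  pieces <- vector("list", config$n_counties)
  for (i in seq_len(config$n_counties)) {
    pct <- simulate_drought_series(config, i)
    temp <- simulate_temperature(config, i)
    month <- ((seq_len(n) - 1L) %% 12L) + 1L
    pieces[[i]] <- data.frame(
      county_id = sprintf("%05d", i),
      year = 2000L + (seq_len(n) - 1L) %/% 12L,
      month = month,
      month_index = seq_len(n),
      season = season_of_month(month),
      temperature = temp,
      population = pops[i],
      percentile = pct,
      urbanicity = if (metro[i]) "metro" else "nonmetro",
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, pieces)
  panel <- label_exposure(panel, bins = config$bins,
                          min_duration = config$min_duration)
  for (oc in names(config$true_log_irr)) {
    panel[[paste0("deaths_", oc)]] <- simulate_counts(config, panel, oc)
  }
  rownames(panel) <- NULL
  panel
}

#' Tune a configuration to a target long-run exposure mix
#'
#' Rescales the percentile bin edges (and sets a persistent AR(1) driver)
#' so the generator's long-run exposure-label shares approximate a target
#' mix of NONE / moderate-to-severe / severe-to-exceptional / WET
#' county-months. The default targets are the national 2000-2018 12-month
#' drought climatology of the contiguous US (about 56% no drought, 28%
#' moderate-to-severe, 10% severe-to-exceptional, 6.5% wet). Because label
#' shares equal bin widths up to leakage of sub-threshold short runs into
#' NONE, the tuned edges allocate the NONE share to NEUTRAL and D0 (9:1)
#' and split the drought shares evenly within their buckets.
#'
#' @param config A [sim_config()] to retune.
#' @param targets Named shares (percent) `none`, `m2sd`, `s2ed`, `wet`;
#'   must be positive and sum to 100 (within 0.5).
#' @return The config with retuned `bins` and `eddi_ar1`.
#' @export
emulate_table1_mix <- function(config = sim_config(),
                               targets = c(none = 56.15, m2sd = 27.63,
                                           s2ed = 9.75, wet = 6.47)) {
  need <- c("none", "m2sd", "s2ed", "wet")
  if (!all(need %in% names(targets))) {
    stop("targets must name none, m2sd, s2ed, wet", call. = FALSE)
  }
  targets <- targets[need]
  if (any(targets <= 0)) {
    stop("infeasible targets: every share must be positive", call. = FALSE)
  }
  if (abs(sum(targets) - 100) > 0.5) {
    stop("infeasible targets: shares must sum to 100", call. = FALSE)
  }
  w <- unname(targets["wet"]) ; no <- unname(targets["none"])
  m <- unname(targets["m2sd"]) ; s <- unname(targets["s2ed"])
  widths <- c(W4 = w / 5, W3 = w / 5, W2 = w / 5, W1 = w / 5, W0 = w / 5,
              NEUTRAL = 0.9 * no, D0 = 0.1 * no,
              D1 = m / 2, D2 = m / 2, D3 = s / 2, D4 = s / 2)
  breaks <- cumsum(widths)[-length(widths)]
  config$bins <- usdm_bins(breaks = unname(breaks))
  config$eddi_ar1 <- 0.95
  config
}

#' Split panel death counts into strata by multinomial thinning
#'
#' Each row's deaths are allocated to strata with fixed probabilities, and
#' population is split with the same fractions, so stratum counts sum
#' exactly to the totals and each stratum keeps approximately the marginal
#' count structure.
#'
#' @param panel A labeled panel from [simulate_panel()].
#' @param fractions Named numeric vector of stratum shares summing to 1.
#' @param outcomes Death-count columns to thin.
#' @param seed Integer seed for the thinning draws.
#' @return Long panel with a `stratum` column; one block per stratum.
#' @export
stratify_panel <- function(panel,
                           fractions = c(`20-64` = 0.8, `65+` = 0.2),
                           outcomes = c("deaths_firearm",
                                        "deaths_nonfirearm"),
                           seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  set.seed(derive_seed(seed, 31L))
  k <- length(fractions)
  out <- vector("list", k)
  alloc <- lapply(outcomes, function(oc) {
    t(vapply(panel[[oc]],
             function(d) as.integer(stats::rmultinom(1, d, fractions)),
             integer(k)))
  })
  names(alloc) <- outcomes
  for (j in seq_len(k)) {
    block <- panel
    block$stratum <- names(fractions)[j]
    block$population <- panel$population * fractions[j]
    for (oc in outcomes) block[[oc]] <- alloc[[oc]][, j]
    out[[j]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
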