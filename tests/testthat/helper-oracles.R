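# Independent oracles used by the test suite. These deliberately share no
# code with the package: the labeler is a plain loop-based enumerator of
# the event/CDI/split rules, the count-model oracle maximizes the
# negative-binomial likelihood on a parameter grid, and the meta-analysis
# oracle maximizes the restricted likelihood over a (mu, tau2) grid.

# Brute-force exposure labeler over a category series.
oracle_label <- function(categories, min_duration = 2L) {
  n <- length(categories)
  sev_map <- c(D1 = 1, D2 = 2, D3 = 3, D4 = 4)
  labels <- character(n)
  for (i in seq_len(n)) {
    labels[i] <- if (substr(categories[i], 1, 1) == "W") "WET" else "NONE"
  }
  i <- 1L
  while (i <= n) {
    if (categories[i] %in% names(sev_map)) {
      j <- i
      while (j < n && categories[j + 1L] %in% names(sev_map)) j <- j + 1L
      len <- j - i + 1L
      if (len >= min_duration) {
        sev <- unname(sev_map[categories[i:j]])
        total <- sum(sev)
        running <- 0
        in_half <- logical(len)
        for (k in seq_len(len)) {
          running <- running + sev[k]
          in_half[k] <- running <= total / 2
        }
        last_worsening <- if (any(in_half)) max(which(in_half)) else 1L
        for (k in seq_len(len)) {
          bucket <- if (sev[k] <= 2) "M2SD" else "S2ED"
          phase <- if (k <= last_worsening) "WRS" else "IMP"
          labels[i + k - 1L] <- paste0(bucket, "_", phase)
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  labels
}

# Wrap a severity sequence (values 1..4) in neutral padding as D categories.
severities_to_categories <- function(sev) {
  c("NEUTRAL", paste0("D", sev), "NEUTRAL")
}

# Negative-binomial log-likelihood of an intercept + binary-covariate model
# with offset, evaluated directly.
nb_loglik <- function(y, x, off, b0, b1, theta) {
  mu <- exp(b0 + b1 * x + off)
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# Coarse-to-fine grid maximization of the NB likelihood over
# (intercept, slope, theta).
nb_grid_oracle <- function(y, x, off, b0_range, b1_range,
                           theta_range = c(0.1, 50)) {
  best <- c(b0 = NA, b1 = NA, theta = NA, ll = -Inf)
  b0s <- seq(b0_range[1], b0_range[2], length.out = 41)
  b1s <- seq(b1_range[1], b1_range[2], length.out = 41)
  ths <- exp(seq(log(theta_range[1]), log(theta_range[2]),
                 length.out = 25))
  for (pass in 1:5) {
    for (b0 in b0s) for (b1 in b1s) for (th in ths) {
      ll <- nb_loglik(y, x, off, b0, b1, th)
      if (ll > best["ll"]) best <- c(b0 = b0, b1 = b1, theta = th, ll = ll)
    }
    w0 <- diff(range(b0s)) / 6 ; w1 <- diff(range(b1s)) / 6
    wt <- diff(range(log(ths))) / 6
    b0s <- seq(best["b0"] - w0, best["b0"] + w0, length.out = 21)
    b1s <- seq(best["b1"] - w1, best["b1"] + w1, length.out = 21)
    ths <- exp(seq(log(best["theta"]) - wt, log(best["theta"]) + wt,
                   length.out = 15))
  }
  best
}

# Restricted-likelihood grid maximization for the random-effects model:
# yi ~ N(mu, sei^2 + tau2).
reml_grid_oracle <- function(yi, sei, tau2_max = 1, n_grid = 5001) {
  best <- c(mu = NA, tau2 = NA, ll = -Inf)
  for (tau2 in seq(0, tau2_max, length.out = n_grid)) {
    v <- sei^2 + tau2
    w <- 1 / v
    mu <- sum(w * yi) / sum(w)
    ll <- -0.5 * (sum(log(v)) + sum(w * (yi - mu)^2) + log(sum(w)))
    if (ll > best["ll"]) best <- c(mu = mu, tau2 = tau2, ll = ll)
  }
  best
}

# Small labeled single-county panel for stage-1 unit tests, with enough
# months in each exposure level to keep fits stable.
toy_county_panel <- function(n_months = 120, seed = 404,
                             population = 5e5, rate = 2e-5) {
  set.seed(seed)
  month <- ((seq_len(n_months) - 1L) %% 12L) + 1L
  cats <- rep("NEUTRAL", n_months)
  cats[20:40] <- c(rep("D1", 6), rep("D3", 9), rep("D2", 6))
  cats[70:90] <- c(rep("D2", 7), rep("D4", 7), rep("D1", 7))
  cats[100:105] <- "W2"
  panel <- data.frame(
    county_id = "00001", month_index = seq_len(n_months), month = month,
    season = droughtphase::season_of_month(month),
    temperature = 12 + 10 * cos(2 * pi * (month - 7) / 12) +
      rnorm(n_months),
    population = population, category = cats
  )
  panel <- droughtphase::label_exposure(panel)
  mu <- population * rate *
    exp(0.2 * (panel$exposure_label %in% c("S2ED_WRS", "S2ED_IMP")))
  panel$deaths_firearm <- rnbinom(n_months, size = 5, mu = mu)
  panel
}
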