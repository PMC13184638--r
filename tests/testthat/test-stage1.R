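test_that("the design has the documented column count and offset", {
  panel <- toy_county_panel()
  des <- build_design(panel, "deaths_firearm", k_temp = 4, k_time = 4)
  n_levels <- length(unique(panel$exposure_label))
  # intercept + exposure dummies + 3 season dummies + (k-1) spline columns
  # each + 1 dispersion parameter
  expect_equal(des$n_params,
               1 + (n_levels - 1) + 3 + 3 + 3 + 1)
  expect_equal(des$data$log_pop, log(panel$population))
  expect_equal(des$excluded_categories,
               setdiff(EXPOSURE_LEVELS, panel$exposure_label))
})

test_that("degenerate covariates collapse their spline terms with a flag", {
  panel <- toy_county_panel()
  panel$temperature <- 10
  des <- build_design(panel, "deaths_firearm")
  expect_true("temperature" %in% des$dropped_terms)
  expect_false(grepl("temperature", deparse(des$formula)[1]))
})

test_that("the intercept-only rate model has its closed-form optimum", {
  set.seed(71)
  n <- 24
  panel <- data.frame(
    county_id = "x", month_index = rep(5L, n),
    season = factor("DJF", levels = c("DJF", "MAM", "JJA", "SON")),
    temperature = 10, population = round(runif(n, 1e4, 1e6)),
    exposure_label = "NONE"
  )
  panel$deaths_firearm <- rpois(n, panel$population * 1e-5)
  fit <- fit_nb_model(panel, "deaths_firearm")
  expect_true(fit$converged)
  des <- build_design(panel, "deaths_firearm")
  m <- suppressWarnings(MASS::glm.nb(des$formula, data = des$data))
  expect_equal(unname(coef(m)["(Intercept)"]),
               log(sum(panel$deaths_firearm) / sum(panel$population)),
               tolerance = 1e-6)
})

test_that("coefficients match grid-search likelihood maximization on a toy", {
  set.seed(72)
  n <- 16
  x <- rep(c(0, 1), each = n / 2)
  pop <- rep(c(2e4, 5e4), n / 2)
  mu <- pop * 3e-4 * exp(0.5 * x)
  y <- rnbinom(n, size = 3, mu = mu)
  panel <- data.frame(
    county_id = "t", month_index = rep(1L, n),
    season = factor("DJF", levels = c("DJF", "MAM", "JJA", "SON")),
    temperature = 1, population = pop,
    exposure_label = ifelse(x == 1, "S2ED_WRS", "NONE"),
    deaths_firearm = y
  )
  fit <- fit_nb_model(panel, "deaths_firearm")
  expect_true(fit$converged)
  b1 <- fit$coefficients$log_irr[fit$coefficients$category == "S2ED_WRS"]
  oracle <- nb_grid_oracle(y, x, log(pop), b0_range = c(-10, -6),
                           b1_range = c(-1, 2))
  expect_equal(b1, unname(oracle["b1"]), tolerance = 5e-3)
})

test_that("Poisson-generated data drive dispersion to the Poisson limit", {
  set.seed(73)
  panel <- toy_county_panel()
  mu <- panel$population * 2e-5
  panel$deaths_firearm <- rpois(nrow(panel), mu)
  fit <- fit_nb_model(panel, "deaths_firearm", 3, 3)
  expect_true(fit$converged)
  expect_gt(fit$theta, 50)  # dispersion drifts toward the Poisson boundary
  des <- build_design(panel, "deaths_firearm", 3, 3)
  pois <- glm(des$formula, data = des$data, family = poisson())
  rows <- grep("^exposure", names(coef(pois)))
  expect_equal(fit$coefficients$log_irr,
               unname(coef(pois)[rows]), tolerance = 0.02)
})

test_that("rescaling populations shifts only the intercept", {
  panel <- toy_county_panel()
  fit1 <- fit_nb_model(panel, "deaths_firearm", 4, 4)
  panel2 <- panel
  panel2$population <- panel$population * 10
  fit2 <- fit_nb_model(panel2, "deaths_firearm", 4, 4)
  expect_equal(fit1$coefficients$log_irr, fit2$coefficients$log_irr,
               tolerance = 1e-6)
  expect_equal(fit1$coefficients$se, fit2$coefficients$se,
               tolerance = 1e-6)
})

test_that("all-zero counts are a non-convergence path, not an error", {
  panel <- toy_county_panel()
  panel$deaths_firearm <- 0L
  fit <- fit_nb_model(panel, "deaths_firearm")
  expect_false(fit$converged)
})

test_that("AIC knot selection tries the full grid and breaks ties toward parsimony", {
  panel <- toy_county_panel()
  sel <- select_knots(panel, "deaths_firearm")
  expect_equal(sel$n_fits, 16L)
  expect_equal(nrow(sel$aic_table), 16L)
  expect_true(sel$converged)
  best <- min(sel$aic_table$aic[sel$aic_table$converged])
  expect_equal(sel$aic, best)
  # degenerate series: both smooths collapse, all 16 fits identical;
  # the deterministic tie-break picks the smallest (k_temp, k_time)
  panel2 <- panel
  panel2$temperature <- 10
  panel2$month_index <- 7L
  sel2 <- select_knots(panel2, "deaths_firearm")
  expect_equal(c(sel2$k_temp, sel2$k_time), c(2L, 3L))
})

test_that("adding basis columns never decreases the maximized likelihood", {
  panel <- toy_county_panel()
  lls <- sapply(c(3, 4, 5), function(k)
    fit_nb_model(panel, "deaths_firearm", k_temp = 2, k_time = k)$loglik)
  expect_true(all(diff(lls) > -1e-6))
})

test_that("modal knot reporting covers single counties and ties", {
  est1 <- data.frame(county_id = "a", outcome = "o", stratum = "total",
                     category = "WET", log_irr = 0, se = 1, aic = 1,
                     k_temp = 4L, k_time = 4L, converged = TRUE)
  m1 <- national_modal_knots(est1)
  expect_equal(m1$modal$k_temp, 4L)
  expect_equal(m1$modal$k_time, 4L)
  est2 <- rbind(est1,
                within(est1, { county_id <- "b"; k_temp <- 2L }))
  m2 <- national_modal_knots(est2)
  expect_equal(nrow(m2$modal), 2L)  # tie: report all tied pairs
  expect_error(national_modal_knots(est1[0, ]), "no converged")
})

test_that("county fits log absent exposure levels and skip failed counties", {
  cfg <- sim_config(n_counties = 3, n_months = 60, seed = 81,
                    baseline_rate = 1e-4)
  panel <- simulate_panel(cfg)
  est <- fit_county_models(panel, outcomes = "deaths_firearm",
                           knots = c(3, 3))
  expect_true(all(est$converged))
  expect_true(all(est$se > 0))
  log <- attr(est, "fit_log")
  expect_true(is.data.frame(log))
  present <- unique(panel$exposure_label)
  if (length(setdiff(EXPOSURE_LEVELS, present))) {
    expect_true(any(log$reason == "level-absent"))
  }
})
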