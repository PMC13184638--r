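test_that("percentile binning follows the USDM convention and is monotone", {
  expect_equal(categorize_percentile(99), "D4")
  expect_equal(categorize_percentile(98), "D4")   # >= 98th is exceptional
  expect_equal(categorize_percentile(50), "NEUTRAL")
  expect_equal(categorize_percentile(1), "W4")
  expect_equal(categorize_percentile(c(70, 80, 90, 95)),
               c("D0", "D1", "D2", "D3"))
  expect_equal(categorize_percentile(c(0, 100)), c("W4", "D4"))
  # monotone: increasing dryness never yields a wetter category
  p <- sort(runif(500, 0, 100))
  idx <- match(categorize_percentile(p), DROUGHT_CATEGORIES)
  expect_true(all(diff(idx) >= 0))
})

test_that("percentile binning rejects bad inputs and malformed bins", {
  expect_error(categorize_percentile(101), "\\[0, 100\\]")
  expect_error(categorize_percentile(-0.1), "\\[0, 100\\]")
  gap <- usdm_bins()
  gap$upper[3] <- gap$upper[3] - 1   # introduce a gap
  expect_error(categorize_percentile(50, gap), "contiguous")
  nocover <- usdm_bins()
  nocover$upper[nrow(nocover)] <- 99
  expect_error(categorize_percentile(50, nocover), "cover")
})

test_that("empirical rank transform yields climatology-relative percentiles", {
  x <- c(5, 1, 3, 2, 4)
  expect_equal(index_to_percentile(x), 100 * (rank(x) - 0.5) / 5)
  # within-calendar-month ranking: each January ranked against Januaries
  v <- c(10, 0, 20, 0, 30, 0)
  m <- c(1L, 2L, 1L, 2L, 1L, 2L)
  p <- index_to_percentile(v, m)
  expect_equal(p[m == 1], c(100 * 0.5 / 3, 100 * 1.5 / 3, 100 * 2.5 / 3))
  expect_true(all(p[m == 2] == p[m == 2][1]))  # ties share a percentile
})

test_that("event detection keeps only persistent D1-D4 runs", {
  ev <- detect_events(c("NEUTRAL", "D1", "D2", "D1", "NEUTRAL"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 2L)
  expect_equal(ev$end, 4L)
  expect_equal(ev$severities[[1]], c(1L, 2L, 1L))

  expect_equal(nrow(detect_events(c("NEUTRAL", "D2", "NEUTRAL", "D3",
                                    "NEUTRAL"))), 0L)

  ev2 <- detect_events(c("D1", "D1", "D0", "D4", "D4", "D4"))
  expect_equal(nrow(ev2), 2L)   # D0 breaks contiguity
  expect_equal(ev2$severities[[1]], c(1L, 1L))
  expect_equal(ev2$severities[[2]], c(4L, 4L, 4L))

  expect_error(detect_events(character(0)), "non-empty")
  expect_error(detect_events(c("D1", "XX")), "unknown")
})

test_that("CDI is the event-scoped running severity sum", {
  r <- compute_cdi(c(1, 2, 3, 3, 2, 1))
  expect_equal(r$cdi_cumulative, c(1, 3, 6, 9, 11, 12))
  expect_equal(r$total_cdi, 12)
  r2 <- compute_cdi(c(4, 4))
  expect_equal(r2$cdi_cumulative, c(4, 8))
  expect_equal(r2$total_cdi, 8)
  expect_error(compute_cdi(integer(0)), "non-empty")
  expect_error(compute_cdi(c(1, 5)), "1..4")
})

test_that("50%-CDI split separates worsening from improving months", {
  expect_equal(split_phases(c(1, 3, 6, 9, 11, 12)), 3L)  # symmetric event
  expect_equal(split_phases(c(4, 8)), 1L)                # 4 <= 8/2, inclusive
  expect_equal(split_phases(c(4, 5, 6)), 1L)  # severe onset: fallback month 1
  expect_error(split_phases(c(3, 2)), "increasing")
  expect_error(split_phases(numeric(0)), "increasing")
})

test_that("month labeling crosses phase with contemporaneous severity", {
  cats <- c("NEUTRAL", "D1", "D2", "D3", "D3", "D2", "D1", "W2")
  expect_equal(label_months(cats),
               c("NONE", "M2SD_WRS", "M2SD_WRS", "S2ED_WRS", "S2ED_IMP",
                 "M2SD_IMP", "M2SD_IMP", "WET"))
  # isolated single severe month fails the persistence rule
  expect_equal(label_months(c("NEUTRAL", "D3", "NEUTRAL")),
               c("NONE", "NONE", "NONE"))
  expect_equal(label_months("W2"), "WET")
  expect_equal(label_months(c("D0", "D0", "D0")), c("NONE", "NONE", "NONE"))
})

test_that("labels partition every series and match the brute-force oracle", {
  set.seed(61)
  for (i in 1:60) {
    cats <- sample(DROUGHT_CATEGORIES, 80, replace = TRUE,
                   prob = c(rep(1, 5), 8, rep(2, 5)))
    lab <- label_months(cats)
    expect_equal(length(lab), length(cats))
    expect_true(all(lab %in% EXPOSURE_LEVELS))
    expect_equal(lab, oracle_label(cats))
  }
})

test_that("CDI splits conserve intensity and respect palindrome symmetry", {
  set.seed(62)
  for (i in 1:200) {
    len <- sample(2:10, 1)
    sev <- sample(1:4, len, replace = TRUE)
    cdi <- compute_cdi(sev)
    sa <- split_phases(cdi$cdi_cumulative)
    expect_true(sa >= 1 && sa < len)   # both phases non-empty
    w <- sum(sev[1:sa]); im <- sum(sev[(sa + 1):len])
    expect_equal(w + im, cdi$total_cdi)
    if (cdi$cdi_cumulative[1] <= cdi$total_cdi / 2) {
      expect_lte(w, cdi$total_cdi / 2)  # except the severe-onset fallback
    }
  }
  # even-length palindromes with equal half-sums split at the midpoint
  for (half in list(c(1, 2), c(3, 1, 2), c(4, 4), c(2, 3, 4, 1))) {
    sev <- c(half, rev(half))
    sa <- split_phases(compute_cdi(sev)$cdi_cumulative)
    expect_equal(sa, length(half))
  }
})

test_that("panel labeling is a partition with consistent event metadata", {
  cfg <- sim_config(n_counties = 4, n_months = 120, seed = 9)
  panel <- simulate_panel(cfg)
  expect_false(anyNA(panel$exposure_label))
  expect_equal(sum(table(panel$exposure_label)), nrow(panel))
  in_event <- !is.na(panel$event_id)
  expect_true(all(panel$exposure_label[in_event] != "NONE"))
  expect_true(all(panel$exposure_label[in_event] != "WET"))
  expect_true(all(is.na(panel$phase[!in_event])))
  expect_equal(grepl("WRS", panel$exposure_label[in_event]),
               panel$phase[in_event] == "worsening")
  expect_error(label_exposure(data.frame(county_id = "a",
                                         month_index = c(1, 3),
                                         category = c("D1", "D1"))),
               "consecutive")
})
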