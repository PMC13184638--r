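#' Detect persistent drought events in a county's category series
#'
#' A drought event is a maximal contiguous run of months in categories
#' D1-D4 lasting at least `min_duration` months. Shorter runs are treated
#' as short-lived anomalies and produce no event; D0 and wet/neutral months
#' break contiguity.
#'
#' @param categories Character vector of drought categories, one per month,
#'   time-ordered with no gaps (month 1 = first element).
#' @param min_duration Minimum run length to qualify as an event.
#' @return A `data.frame` with one row per event: `event_id`, `start`,
#'   `end` (inclusive month indices) and a list-column `severities`
#'   (integer severity 1-4 per event month, D1 -> 1 ... D4 -> 4).
#' @export
#' @examples
#' detect_events(c("NEUTRAL", "D1", "D2", "D1", "NEUTRAL"))
detect_events <- function(categories, min_duration = 2L) {
  if (!is.character(categories) || length(categories) == 0L) {
    stop("categories must be a non-empty character vector", call. = FALSE)
  }
  bad <- setdiff(unique(categories), DROUGHT_CATEGORIES)
  if (length(bad)) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sev <- match(categories, c("D1", "D2", "D3", "D4"))  # NA outside D1-D4
  in_drought <- !is.na(sev)
  r <- rle(in_drought)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  starts <- starts[keep]
  ends <- ends[keep]
  data.frame(
    event_id = seq_along(starts),
    start = starts,
    end = ends,
    severities = I(mapply(function(s, e) sev[s:e], starts, ends,
                          SIMPLIFY = FALSE))
  )
}

#' Cumulative drought intensity of an event
#'
#' CDI is the running sum of monthly severity scores (D1 = 1 ... D4 = 4)
#' within a drought event; it is event-scoped and resets implicitly when
#' the event ends.
#'
#' @param severities Integer vector of severities in 1..4, one per event
#'   month.
#' @return List with `cdi_cumulative` (running sum) and `total_cdi`.
#' @export
#' @examples
#' compute_cdi(c(1, 2, 3, 3, 2, 1))
compute_cdi <- function(severities) {
  if (length(severities) == 0L) {
    stop("severities must be non-empty", call. = FALSE)
  }
  if (anyNA(severities) || !all(severities %in% 1:4)) {
    stop("severities must be integers in 1..4", call. = FALSE)
  }
  cc <- cumsum(as.integer(severities))
  list(cdi_cumulative = cc, total_cdi = cc[length(cc)])
}

#' Split a drought event into worsening and improving phases
#'
#' The worsening phase comprises the months whose running CDI is at most
#' 50% of the event total (inclusive at exact equality); the remaining
#' months are the improving phase. If even the first month's CDI exceeds
#' half the total (a severe onset), the first month alone is worsening, so
#' both phases are non-empty for events of two or more months. Because the
#' split is based on cumulative intensity rather than elapsed time, severe
#' months pull the split point toward themselves.
#'
#' @param cdi_cumulative Running CDI from [compute_cdi()].
#' @return `split_after`: index of the last worsening month.
#' @export
#' @examples
#' split_phases(cumsum(c(1, 2, 3, 3, 2, 1)))  # 3
split_phases <- function(cdi_cumulative) {
  if (length(cdi_cumulative) == 0L || any(diff(cdi_cumulative) <= 0) ||
      any(cdi_cumulative <= 0)) {
    stop("cdi_cumulative must be a strictly increasing positive sequence; ",
         "run compute_cdi() first", call. = FALSE)
  }
  total <- cdi_cumulative[length(cdi_cumulative)]
  ok <- which(cdi_cumulative <= total / 2)
  if (length(ok) == 0L) 1L else max(ok)
}

#' Assign one exposure label to every month of a county series
#'
#' Months inside a qualifying drought event are labeled by crossing the
#' event phase (worsening up to the 50%-CDI split, improving after) with
#' the contemporaneous severity bucket (D1-D2 -> `M2SD`, D3-D4 -> `S2ED`).
#' Wet-category months outside events are `WET`; everything else (NEUTRAL,
#' D0, and D1-D4 runs too short to qualify) is `NONE`. The six labels
#' partition the series.
#'
#' @inheritParams detect_events
#' @param events Optional event table from [detect_events()] on the same
#'   series; recomputed when missing.
#' @return Character vector of exposure labels, one per month.
#' @export
#' @examples
#' label_months(c("NEUTRAL", "D1", "D2", "D3", "D3", "D2", "D1", "W2"))
label_months <- function(categories, events = NULL,
                         min_duration = 2L) {
  if (is.null(events)) events <- detect_events(categories, min_duration)
  labels <- rep("NONE", length(categories))
  labels[grepl("^W", categories)] <- "WET"
  if (nrow(events)) {
    covered <- unlist(mapply(seq, events$start, events$end,
                             SIMPLIFY = FALSE))
    if (anyDuplicated(covered)) {
      stop("internal error: overlapping drought events", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(events))) {
    sev <- events$severities[[i]]
    cdi <- compute_cdi(sev)
    split_after <- split_phases(cdi$cdi_cumulative)
    phase <- ifelse(seq_along(sev) <= split_after, "WRS", "IMP")
    bucket <- ifelse(sev <= 2, "M2SD", "S2ED")
    labels[events$start[i]:events$end[i]] <- paste(bucket, phase, sep = "_")
  }
  labels
}

#' Label exposures for a multi-county panel
#'
#' Applies the full exposure chain (percentile binning, event detection,
#' CDI, phase split, labeling) per county to a county-month panel.
#'
#' @param panel Data frame with columns `county_id`, `month_index` and
#'   either `percentile` (dryness percentile) or `category`. Must be dense
#'   in `month_index` within each county.
#' @param bins Bin-edge table used when `category` is absent.
#' @param min_duration Minimum event duration in months.
#' @return `panel` with columns `category`, `event_id` (NA outside
#'   events), `phase` ("worsening"/"improving"/NA) and `exposure_label`
#'   added, in the original row order.
#' @export
label_exposure <- function(panel, bins = usdm_bins(), min_duration = 2L) {
  need <- c("county_id", "month_index")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns county_id and month_index", call. = FALSE)
  }
  if (!"category" %in% names(panel)) {
    if (!"percentile" %in% names(panel)) {
      stop("panel needs a percentile or category column", call. = FALSE)
    }
    panel$category <- categorize_percentile(panel$percentile, bins)
  }
  panel$event_id <- NA_integer_
  panel$phase <- NA_character_
  panel$exposure_label <- NA_character_
  for (cid in unique(panel$county_id)) {
    rows <- which(panel$county_id == cid)
    rows <- rows[order(panel$month_index[rows])]
    mi <- panel$month_index[rows]
    if (any(diff(mi) != 1L)) {
      stop("county ", cid, ": month_index must be consecutive",
           call. = FALSE)
    }
    cats <- panel$category[rows]
    events <- detect_events(cats, min_duration)
    panel$exposure_label[rows] <- label_months(cats, events, min_duration)
    for (i in seq_len(nrow(events))) {
      span <- events$start[i]:events$end[i]
      cdi <- compute_cdi(events$severities[[i]])
      sa <- split_phases(cdi$cdi_cumulative)
      panel$event_id[rows[span]] <- events$event_id[i]
      panel$phase[rows[span]] <-
        ifelse(seq_along(span) <= sa, "worsening", "improving")
    }
  }
  panel
}
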