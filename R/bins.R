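#' Drought category constants
#'
#' Category labels follow the U.S. Drought Monitor convention: `D0`
#' (abnormally dry) through `D4` (exceptional drought), mirrored wet
#' categories `W0`-`W4`, and `NEUTRAL` in between. Exposure labels combine
#' the event phase (worsening `WRS` / improving `IMP`) with the
#' contemporaneous severity bucket: moderate-to-severe (`M2SD`, D1-D2) or
#' severe-to-exceptional (`S2ED`, D3-D4).
#'
#' @format Character vectors.
#' @name category-constants
NULL

#' @rdname category-constants
#' @export
DROUGHT_CATEGORIES <- c("W4", "W3", "W2", "W1", "W0", "NEUTRAL",
                        "D0", "D1", "D2", "D3", "D4")

#' @rdname category-constants
#' @export
EXPOSURE_LEVELS <- c("NONE", "M2SD_WRS", "S2ED_WRS", "S2ED_IMP",
                     "M2SD_IMP", "WET")

#' Default percentile bin edges for drought categories
#'
#' Returns the bin-edge table mapping dryness percentiles (100 = driest
#' month on record relative to climatology) to drought categories. The
#' default follows the U.S. Drought Monitor percentile convention: D4 at or
#' above the 98th dryness percentile, D3 95-98, D2 90-95, D1 80-90, D0
#' 70-80, with the wet categories mirrored at the other tail and NEUTRAL in
#' between. Intervals are closed on the left, and the top interval includes
#' 100.
#'
#' @param breaks Numeric vector of interior break points, strictly
#'   increasing, within (0, 100); length must be `length(categories) - 1`.
#' @param categories Category labels ordered wet to dry.
#' @return A `data.frame` with columns `category`, `lower`, `upper`.
#' @export
#' @examples
#' usdm_bins()
usdm_bins <- function(breaks = c(2, 5, 10, 20, 30, 70, 80, 90, 95, 98),
                      categories = DROUGHT_CATEGORIES) {
  if (length(breaks) != length(categories) - 1L) {
    stop("need exactly one fewer break than categories", call. = FALSE)
  }
  edges <- c(0, breaks, 100)
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing and inside [0, 100]",
         call. = FALSE)
  }
  data.frame(category = categories,
             lower = edges[-length(edges)],
             upper = edges[-1L],
             stringsAsFactors = FALSE)
}

validate_bins <- function(bins) {
  req <- c("category", "lower", "upper")
  if (!is.data.frame(bins) || !all(req %in% names(bins))) {
    stop("bins must be a data.frame with columns category, lower, upper",
         call. = FALSE)
  }
  o <- order(bins$lower)
  b <- bins[o, , drop = FALSE]
  if (b$lower[1L] != 0 || b$upper[nrow(b)] != 100) {
    stop("bins must cover [0, 100]", call. = FALSE)
  }
  if (any(b$upper[-nrow(b)] != b$lower[-1L])) {
    stop("bins must be contiguous (no gaps or overlaps)", call. = FALSE)
  }
  if (any(b$upper <= b$lower)) stop("each bin must have positive width",
                                    call. = FALSE)
  b
}

#' Map dryness percentiles to drought categories
#'
#' Bins are left-closed (`lower <= p < upper`), except the driest bin which
#' also includes 100. Higher dryness percentiles never map to a wetter
#' category.
#'
#' @param percentile Numeric vector of dryness percentiles in \[0, 100\].
#' @param bins Bin-edge table, see [usdm_bins()].
#' @return Character vector of categories, same length as `percentile`.
#' @export
#' @examples
#' categorize_percentile(c(1, 50, 85, 99))
categorize_percentile <- function(percentile, bins = usdm_bins()) {
  b <- validate_bins(bins)
  if (!is.numeric(percentile) || anyNA(percentile) ||
      any(percentile < 0 | percentile > 100)) {
    stop("percentile must be numeric in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(percentile, c(b$lower, 100), rightmost.closed = TRUE)
  b$category[idx]
}

#' Convert raw index values to dryness percentiles by empirical climatology
#'
#' Drought-index categories are climatology-relative: a month's percentile
#' is its rank among all values observed for the same calendar month in the
#' same county. Ranks are midranks mapped to (0, 100) via (rank - 0.5) / n,
#' so ties share a percentile and the extremes stay inside the open
#' interval.
#'
#' @param values Numeric index values (positive = drier than normal).
#' @param calendar_month Integer 1-12 per value; percentiles are computed
#'   within calendar month. Use a constant to rank against the whole series.
#' @return Dryness percentiles in (0, 100).
#' @export
index_to_percentile <- function(values, calendar_month = rep(1L, length(values))) {
  if (length(values) != length(calendar_month)) {
    stop("values and calendar_month must have the same length", call. = FALSE)
  }
  out <- numeric(length(values))
  for (m in unique(calendar_month)) {
    i <- calendar_month == m
    r <- rank(values[i], ties.method = "average")
    out[i] <- 100 * (r - 0.5) / sum(i)
  }
  out
}
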