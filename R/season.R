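#' Detect monsoon windows from daily rainfall
#'
#' Defines, for each calendar year, the monsoon season as the period between
#' the first and last days on which the rolling `window_days`-day average
#' rainfall is at least `threshold_mm` (the convention used to stratify
#' cluster-randomized sanitation trial rounds into monsoon and dry analyses).
#'
#' @param rainfall data.frame with columns `date` (Date or ISO-8601 string)
#'   and `rainfall_mm` (non-negative); an optional `station` column triggers
#'   day-wise averaging across stations before detection.
#' @param threshold_mm rolling-average threshold in millimetres (default 10).
#' @param window_days width of the rolling window in days (default 5).
#' @param align `"trailing"` (window ends on the labelled day, default) or
#'   `"centered"`.
#' @param gap_tolerance maximum tolerated gap, in missing days, inside a
#'   year's series. Gaps up to the tolerance are filled by linear
#'   interpolation; larger gaps are an error. Default 0 (any gap errors).
#' @return data.frame of class `crt_season_windows` with columns `year`,
#'   `monsoon_start`, `monsoon_end` (Date; `NA` when no day qualifies).
#' @examples
#' rain <- data.frame(
#'   date = seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day"),
#'   rainfall_mm = 0
#' )
#' rain$rainfall_mm[rain$date >= as.Date("2015-04-01") &
#'                  rain$date <= as.Date("2015-09-30")] <- 15
#' detect_monsoon(rain)
#' @export
detect_monsoon <- function(rainfall, threshold_mm = 10, window_days = 5,
                           align = c("trailing", "centered"),
                           gap_tolerance = 0) {
  align <- match.arg(align)
  if (!all(c("date", "rainfall_mm") %in% names(rainfall))) {
    stopf("rainfall needs columns 'date' and 'rainfall_mm'")
  }
  dat <- rainfall
  dat$date <- as.Date(dat$date)
  if (anyNA(dat$date)) stopf("unparseable rainfall dates")
  if (any(dat$rainfall_mm < 0, na.rm = TRUE)) stopf("negative rainfall")

  # Multi-station series: average day-wise before detection.
  if ("station" %in% names(dat)) {
    agg <- stats::aggregate(rainfall_mm ~ date, data = dat, FUN = mean)
    dat <- agg[order(agg$date), ]
  } else {
    dat <- dat[order(dat$date), c("date", "rainfall_mm")]
    if (anyDuplicated(dat$date)) stopf("duplicate dates without station column")
  }

  years <- sort(unique(as.integer(format(dat$date, "%Y"))))
  out <- data.frame(
    year = years,
    monsoon_start = as.Date(rep(NA, length(years))),
    monsoon_end = as.Date(rep(NA, length(years)))
  )
  for (i in seq_along(years)) {
    yr <- years[i]
    sub <- dat[format(dat$date, "%Y") == as.character(yr), ]
    if (nrow(sub) < window_days) next
    full <- seq(min(sub$date), max(sub$date), by = "day")
    gap <- length(full) - nrow(sub)
    if (gap > 0) {
      if (gap > gap_tolerance) {
        stopf("rainfall series for %d has %d missing day(s); increase gap_tolerance",
              yr, gap)
      }
      x <- merge(data.frame(date = full), sub, all.x = TRUE)
      x$rainfall_mm <- stats::approx(x$date, x$rainfall_mm, xout = x$date,
                                     rule = 2)$y
      sub <- x
    }
    roll <- rolling_mean(sub$rainfall_mm, window_days, align)
    hit <- which(!is.na(roll) & roll >= threshold_mm)
    if (length(hit)) {
      out$monsoon_start[i] <- sub$date[min(hit)]
      out$monsoon_end[i] <- sub$date[max(hit)]
    }
  }
  class(out) <- c("crt_season_windows", "data.frame")
  out
}

# Rolling mean; trailing = window ends on labelled day, centered = window
# centred on it (requires odd k handled by floor offsets).
rolling_mean <- function(x, k, align = "trailing") {
  n <- length(x)
  cs <- cumsum(c(0, x))
  full <- rep(NA_real_, n)
  idx <- k:n
  means <- (cs[idx + 1] - cs[idx + 1 - k]) / k
  if (align == "trailing") {
    full[idx] <- means
  } else {
    shift <- floor((k - 1) / 2)
    lab <- idx - (k - 1) + shift
    full[lab] <- means
  }
  full
}

#' Construct season windows directly
#'
#' Convenience constructor when window dates are known rather than derived
#' from rainfall (e.g., in synthetic trials).
#'
#' @param year integer vector of calendar years.
#' @param monsoon_start,monsoon_end Date (or string) vectors, same length.
#' @return `crt_season_windows` data.frame.
#' @export
season_windows <- function(year, monsoon_start, monsoon_end) {
  ws <- data.frame(
    year = as.integer(year),
    monsoon_start = as.Date(monsoon_start),
    monsoon_end = as.Date(monsoon_end)
  )
  bad <- !is.na(ws$monsoon_start) & ws$monsoon_start > ws$monsoon_end
  if (any(bad)) stopf("monsoon_start after monsoon_end for year(s) %s",
                      paste(ws$year[bad], collapse = ", "))
  if (anyDuplicated(ws$year)) stopf("duplicate years in season windows")
  class(ws) <- c("crt_season_windows", "data.frame")
  ws
}

#' Assign monsoon/dry season to dates
#'
#' A date is monsoon iff `monsoon_start <= date <= monsoon_end` for its
#' calendar year (both boundaries inclusive).
#'
#' @param dates Date vector (or ISO-8601 strings).
#' @param windows a `crt_season_windows` object.
#' @return character vector, `"monsoon"` or `"dry"`.
#' @export
assign_season <- function(dates, windows) {
  dates <- as.Date(dates)
  yrs <- as.integer(format(dates, "%Y"))
  miss <- setdiff(unique(yrs), windows$year)
  if (length(miss)) {
    stopf("no season window covers year(s): %s", paste(miss, collapse = ", "))
  }
  m <- match(yrs, windows$year)
  s <- windows$monsoon_start[m]
  e <- windows$monsoon_end[m]
  ifelse(!is.na(s) & dates >= s & dates <= e, "monsoon", "dry")
}
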