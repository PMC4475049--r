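#' Daily degree-days above a threshold by the single-sine method
#'
#' Models the diurnal temperature course as a sine wave between the daily
#' minimum and maximum and integrates the area above the lower developmental
#' threshold. With midpoint `m = (t_max + t_min)/2` and half-amplitude
#' `w = (t_max - t_min)/2`: the whole day above the threshold contributes
#' `m - ldt`; a day entirely below it contributes 0; otherwise the partial-day
#' area is `(1/pi) * ((m - ldt) * (pi/2 - theta) + w * cos(theta))` with
#' `theta = asin((ldt - m)/w)`.
#'
#' @param t_min,t_max daily minimum and maximum temperature, degrees C
#'   (vectorised; recycled to common length).
#' @param ldt lower developmental threshold, degrees C.
#' @return degree-days (D) for each day, always >= 0.
#' @export
daily_degree_days_single_sine <- function(t_min, t_max, ldt) {
  n <- max(length(t_min), length(t_max))
  t_min <- rep_len(t_min, n); t_max <- rep_len(t_max, n)
  if (any(t_min > t_max))
    stop("t_min > t_max on day(s) ", paste(which(t_min > t_max), collapse = ", "))
  m <- (t_max + t_min) / 2
  w <- (t_max - t_min) / 2
  dd <- numeric(n)
  above <- t_min >= ldt
  below <- t_max <= ldt
  partial <- !above & !below
  dd[above] <- m[above] - ldt
  if (any(partial)) {
    th <- asin((ldt - m[partial]) / w[partial])
    dd[partial] <- ((m[partial] - ldt) * (pi / 2 - th) +
                      w[partial] * cos(th)) / pi
  }
  dd
}

#' Daily degree-days by the simple-average method
#'
#' `max(0, (t_max + t_min)/2 - ldt)`; kept as a sensitivity alternative to
#' the single-sine method, with which it agrees exactly whenever the whole
#' day stays above the threshold.
#'
#' @inheritParams daily_degree_days_single_sine
#' @return degree-days (D) for each day.
#' @export
daily_degree_days_average <- function(t_min, t_max, ldt) {
  if (any(t_min > t_max)) stop("t_min > t_max")
  pmax(0, (t_max + t_min) / 2 - ldt)
}

#' Accumulate degree-days to stage completion
#'
#' Sums daily degree-days above the LDT from a start date and finds the first
#' day on which the running total reaches the SET — the predicted completion
#' of the developmental stage. Completion is resolved at day granularity.
#'
#' @param weather data frame with columns `date` (Date or ISO-8601 string),
#'   `t_min_c`, `t_max_c`, chronologically ordered.
#' @param ldt lower developmental threshold, degrees C.
#' @param set_dd sum of effective temperatures, day-degrees.
#' @param start_date first day of accumulation (default: first weather row).
#' @param method `"single_sine"` (default) or `"average"`.
#' @return list of class `degree_day_series`: `dates`, `daily_dd`,
#'   `cumulative_dd`, `completion_date` (`NA` if the SET is never reached).
#' @export
accumulate_to_completion <- function(weather, ldt, set_dd, start_date = NULL,
                                     method = c("single_sine", "average")) {
  method <- match.arg(method)
  stopifnot(all(c("date", "t_min_c", "t_max_c") %in% names(weather)))
  dates <- as.Date(weather$date)
  if (is.unsorted(dates, strictly = TRUE)) stop("weather dates not ordered")
  if (!is.null(start_date)) {
    keep <- dates >= as.Date(start_date)
    weather <- weather[keep, , drop = FALSE]
    dates <- dates[keep]
  }
  if (nrow(weather) == 0L) stop("no weather rows on or after start_date")
  f <- if (method == "single_sine") daily_degree_days_single_sine
       else daily_degree_days_average
  daily <- f(weather$t_min_c, weather$t_max_c, ldt)
  cum <- cumsum(daily)
  hit <- which(cum >= set_dd)
  structure(list(
    dates = dates,
    daily_dd = daily,
    cumulative_dd = cum,
    completion_date = if (length(hit) > 0) dates[hit[1]] else as.Date(NA)
  ), class = "degree_day_series")
}

#' Temperature at which invasive and non-invasive rate lines cross
#'
#' Under the linear rate model the development rate of each species is
#' `(T - LDT) / SET`. A species with a higher LDT but a lower SET develops
#' slower at low temperatures but faster at high ones; the two rate lines
#' intersect at `T_c = (LDT_I * SET_N - LDT_N * SET_I) / (SET_N - SET_I)`.
#' Above `T_c` the species with the smaller SET (steeper line) is faster.
#'
#' @param inv,noninv `thermal_requirement` objects, or lists/named vectors
#'   with `ldt` and `set_dd`.
#' @return list: `t_c` (degrees C), `faster_above` (`"invasive"` or
#'   `"noninvasive"`), `rate_at_tc` (the common rate, 1/day).
#' @export
crossing_temperature <- function(inv, noninv) {
  g <- function(x) list(ldt = x[["ldt"]], set = x[["set_dd"]])
  i <- g(inv); n <- g(noninv)
  if (i$set == n$set)
    stop("parallel rate lines, no finite crossing (equal SETs)")
  t_c <- (i$ldt * n$set - n$ldt * i$set) / (n$set - i$set)
  list(t_c = t_c,
       faster_above = if (i$set < n$set) "invasive" else "noninvasive",
       rate_at_tc = (t_c - i$ldt) / i$set)
}
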