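# Thermal-time phenology: degree-day accumulation from the flowering date,
# regional Tsum characterisation, harvest-day prediction.

#' Daily thermal-time increment
#'
#' Degree-days contributed by one day: `max(tmean - tbase, 0)`. The base
#' temperature for cacao pod growth is 10 deg C, the minimum temperature at
#' which pods develop; days colder than that contribute nothing, never a
#' negative amount.
#'
#' @param tmean daily mean temperature, deg C (vectorised).
#' @param tbase base temperature, deg C (default 10).
#' @return Thermal time increment, deg C day.
#' @export
#' @examples
#' thermal_increment(26)  # 16
#' thermal_increment(8)   # 0, never negative
thermal_increment <- function(tmean, tbase = 10) {
  if (any(!is.finite(tmean))) stop("tmean must be finite")
  pmax(tmean - tbase, 0)
}

# Extract the daily mean temperatures for days fd+1 .. fd+horizon,
# erroring on gaps or missing values (explicit gap-fill is the caller's
# job via fill_weather_gaps()). With allow_partial = TRUE a series that
# ends early returns the covered prefix instead of erroring; interior
# gaps still error.
.window_tmean <- function(series, fd, horizon, allow_partial = FALSE) {
  fd <- as.Date(fd)
  wanted <- fd + seq_len(horizon)
  idx <- match(wanted, series$date)
  if (anyNA(idx)) {
    first_missing <- which(is.na(idx))[1]
    tail_only <- allow_partial && first_missing > 1 &&
      all(is.na(idx[first_missing:horizon]))
    if (!tail_only)
      stop("weather coverage insufficient: no record for ",
           format(wanted[first_missing]))
    idx <- idx[seq_len(first_missing - 1)]
    wanted <- wanted[seq_len(first_missing - 1)]
  }
  tmax <- series$tmax[idx]; tmin <- series$tmin[idx]
  if (anyNA(tmax) || anyNA(tmin))
    stop("missing temperature inside the simulation window (",
         format(wanted[which(is.na(tmax) | is.na(tmin))[1]]),
         "); use fill_weather_gaps() to interpolate short gaps explicitly")
  daily_mean_temperature(tmax, tmin)
}

#' Accumulate thermal time from a flowering date
#'
#' Cumulative degree-day sum indexed by days after flowering (DAF). The
#' flowering date itself is DAF 0 and contributes no thermal time; day d's
#' increment uses the mean temperature of the calendar day `fd + d`.
#'
#' @param series a [weather_series()] covering `fd + 1 .. fd + horizon`.
#' @param fd flowering date (Date or ISO string).
#' @param horizon number of days to accumulate (default 180, the
#'   traditional calendar harvest).
#' @param tbase base temperature, deg C.
#' @return A `thermal_time_trace`: numeric vector of length `horizon + 1`,
#'   element `d + 1` holding cumulative thermal time at DAF `d` (so the
#'   first element is 0), with attributes `fd` and `tbase`.
#' @export
# Plain double-precision running sum. cumsum() accumulates in extended
# precision; thermal time is defined as the day-by-day sum, so the
# accumulator adds one double per day exactly as the definition reads.
.running_sum <- function(x) {
  out <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) { acc <- acc + x[i]; out[i] <- acc }
  out
}

accumulate_thermal_time <- function(series, fd, horizon = 180, tbase = 10) {
  tmean <- .window_tmean(series, fd, horizon)
  tt <- c(0, .running_sum(thermal_increment(tmean, tbase)))
  structure(tt, fd = as.Date(fd), tbase = tbase,
            class = "thermal_time_trace")
}

#' @export
print.thermal_time_trace <- function(x, ...) {
  cat("Thermal time from flowering date ", format(attr(x, "fd")),
      " (Tb = ", attr(x, "tbase"), " C)\n", sep = "")
  cat("  ", length(x) - 1, " DAF, final accumulation ",
      round(unclass(x)[length(x)], 1), " C day\n", sep = "")
  invisible(x)
}

#' Characterise the regional thermal-time requirement (Tsum)
#'
#' For each flowering date, accumulates thermal time to `horizon` DAF
#' (farmers harvest at 180 DAF by calendar); the regional Tsum is the
#' arithmetic mean of those per-sample accumulations. The per-sample
#' distribution is returned so a median or box-plot summary is available
#' without recomputation.
#'
#' @param series a [weather_series()].
#' @param fds vector of flowering dates.
#' @param horizon DAF at which to read the accumulation (default 180).
#' @param tbase base temperature, deg C.
#' @param stat `"mean"` (default) or `"median"` aggregation.
#' @return List with `tsum` (the aggregate), `per_fd` (named vector of
#'   per-flowering-date accumulations) and `stat`.
#' @export
characterize_tsum <- function(series, fds, horizon = 180, tbase = 10,
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fds <- as.Date(fds)
  if (!length(fds)) stop("at least one flowering date required")
  per_fd <- vapply(seq_along(fds), function(i) {
    tt <- accumulate_thermal_time(series, fds[i], horizon, tbase)
    unclass(tt)[horizon + 1]
  }, numeric(1))
  names(per_fd) <- format(fds)
  tsum <- if (stat == "mean") mean(per_fd) else stats::median(per_fd)
  list(tsum = tsum, per_fd = per_fd, stat = stat)
}

#' Predict the harvest day for one flowering date
#'
#' The maturation day is the first DAF at which accumulated thermal time
#' reaches the regional requirement `tsum` (ties resolve to the earlier
#' day). If the requirement is not met by `cap` days (the 200-day crop
#' cycle), the cap is returned with `reached = FALSE`.
#'
#' @param series a [weather_series()] covering `fd + 1 .. fd + cap`.
#' @param fd flowering date.
#' @param tsum regional thermal-time requirement, deg C day (> 0).
#' @param tbase base temperature, deg C.
#' @param cap crop-cycle cap in days (default 200).
#' @return List with `daf` (integer), `reached` (logical) and
#'   `tt_at_harvest` (accumulated thermal time at that day).
#' @export
#' @examples
#' # constant 26 C: 16 C day per day, Tsum 2906 first crossed on day 182
#' w <- weather_series(data.frame(
#'   date = seq(as.Date("2019-01-01"), by = "day", length.out = 230),
#'   tmax = 26, tmin = 26, srad = 15, rain = 0))
#' predict_harvest_day(w, "2019-01-01", tsum = 2906)$daf
predict_harvest_day <- function(series, fd, tsum, tbase = 10, cap = 200) {
  if (!is.finite(tsum) || tsum <= 0) stop("tsum must be positive")
  # the loop stops as soon as the requirement is met, so a series ending
  # between the crossing day and the cap is still sufficient coverage
  tmean <- .window_tmean(series, fd, cap, allow_partial = TRUE)
  tt <- c(0, .running_sum(thermal_increment(tmean, tbase)))
  hit <- which(tt >= tsum)
  if (length(hit)) {
    daf <- hit[1] - 1L
    return(list(daf = as.integer(daf), reached = TRUE,
                tt_at_harvest = tt[daf + 1]))
  }
  if (length(tmean) < cap)
    stop("weather coverage insufficient: thermal requirement not met by ",
         format(as.Date(fd) + length(tmean)), " and series ends before the ",
         cap, "-day cap")
  list(daf = as.integer(cap), reached = FALSE, tt_at_harvest = tt[cap + 1])
}

#' Mean predicted harvest day by flowering month
#'
#' Groups flowering dates by calendar month, predicts each date's harvest
#' DAF against the regional `tsum`, and averages per month. Months with no
#' flowering date are absent from the result.
#'
#' @inheritParams predict_harvest_day
#' @param fds vector of flowering dates.
#' @return Data frame with `month` (1-12), `month_name`, `mean_daf`, `n`.
#' @export
monthly_harvest_table <- function(series, fds, tsum, tbase = 10, cap = 200) {
  fds <- as.Date(fds)
  daf <- vapply(seq_along(fds), function(i)
    as.numeric(predict_harvest_day(series, fds[i], tsum, tbase, cap)$daf),
    numeric(1))
  month <- as.integer(format(fds, "%m"))
  agg <- stats::aggregate(daf, by = list(month = month), FUN = mean)
  cnt <- as.vector(table(factor(month, levels = agg$month)))
  data.frame(month = agg$month,
             month_name = month.name[agg$month],
             mean_daf = agg$x,
             n = cnt,
             stringsAsFactors = FALSE)
}
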