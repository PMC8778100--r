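# Daily weather series: reading, validation, writing, synthesis.

#' Canonical weather column names
#'
#' Internal weather series are data frames with these columns (plus a
#' `location` attribute): `date` (Date), `tmax`, `tmin` (deg C), `srad`
#' (MJ m-2 day-1 all-sky shortwave), `rain` (mm day-1), `rh` (%),
#' `wind` (m s-1), `tdew` (deg C).
#' @keywords internal
.weather_cols <- c("date", "tmax", "tmin", "srad", "rain", "rh", "wind", "tdew")

#' Default NASA-POWER export column mapping
#'
#' Maps canonical names to the column names of a POWER Data Access Viewer
#' daily CSV export. Pass a modified copy to [read_power_weather()] to read
#' other dialects.
#'
#' @return Named character vector, canonical name -> file column name.
#' @export
#' @examples
#' power_column_map()
power_column_map <- function() {
  c(date = "YYYYMMDD", tmax = "T2M_MAX", tmin = "T2M_MIN",
    srad = "ALLSKY_SFC_SW_DWN", rain = "PRECTOTCORR",
    rh = "RH2M", wind = "WS2M", tdew = "T2MDEW")
}

#' Construct a validated weather series
#'
#' Low-level constructor: sorts by date, checks invariants, flags gaps.
#' Missing values stay `NA`; they are never silently filled.
#'
#' @param df data frame with at least `date`, `tmax`, `tmin`, `srad`, `rain`.
#' @param location region label.
#' @return A `weather_series`: a data frame with canonical columns, a
#'   `location` attribute and a `gaps` attribute (Dates absent from the
#'   covered range).
#' @export
weather_series <- function(df, location = "unknown") {
  required <- c("date", "tmax", "tmin", "srad", "rain")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("weather series missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.weather_cols, c("date", names(df))))
    df[[col]] <- NA_real_
  df <- df[.weather_cols]
  if (!inherits(df$date, "Date")) {
    d <- .parse_weather_dates(df$date)
    df$date <- d
  }
  if (anyNA(df$date)) stop("unparsable dates in weather input")
  if (anyDuplicated(df$date)) stop("duplicate dates in weather input")
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  bad <- !is.na(df$tmax) & !is.na(df$tmin) & df$tmax < df$tmin
  if (any(bad))
    stop("tmax < tmin on ", sum(bad), " row(s), first at ",
         format(df$date[which(bad)[1]]))
  if (any(df$srad < 0, na.rm = TRUE)) stop("negative srad")
  if (any(df$rain < 0, na.rm = TRUE)) stop("negative rain")
  if (any(df$rh < 0 | df$rh > 100, na.rm = TRUE)) stop("rh outside [0, 100]")
  full <- seq(min(df$date), max(df$date), by = "day")
  gaps <- full[!full %in% df$date]
  structure(df, location = location, gaps = gaps,
            class = c("weather_series", "data.frame"))
}

# Accepts Date, ISO strings, or POWER YYYYMMDD integers/strings.
.parse_weather_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  if (all(grepl("^[0-9]{8}$", x))) return(as.Date(x, format = "%Y%m%d"))
  as.Date(x)
}

#' Read a POWER-dialect daily weather CSV
#'
#' Reads a delimited daily weather table (NASA POWER export dialect by
#' default), maps columns to canonical names, converts the `-999` sentinel
#' to `NA`, validates, and returns a date-sorted [weather_series()].
#' Extra columns are ignored. POWER exports place comment headers before
#' the table; lines starting with `#` are skipped.
#'
#' @param path CSV file path.
#' @param location region label attached to the series.
#' @param column_map named vector mapping canonical names (`date`, `tmax`,
#'   `tmin`, `srad`, `rain`, optionally `rh`, `wind`, `tdew`) to file column
#'   names; default [power_column_map()]. Canonical names already present in
#'   the file are also accepted.
#' @param sentinel numeric missing-value sentinel (POWER uses -999).
#' @return A `weather_series`.
#' @export
read_power_weather <- function(path, location = "unknown",
                               column_map = power_column_map(),
                               sentinel = -999) {
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  out <- list()
  for (canon in .weather_cols) {
    src <- if (canon %in% names(raw)) canon
           else if (!is.na(column_map[canon]) && column_map[canon] %in% names(raw))
             column_map[[canon]]
           else NA_character_
    if (!is.na(src)) out[[canon]] <- raw[[src]]
  }
  required <- c("date", "tmax", "tmin", "srad", "rain")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols))
    stop("required weather column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "date")) {
    v <- as.numeric(df[[col]])
    v[!is.na(v) & v == sentinel] <- NA_real_
    df[[col]] <- v
  }
  weather_series(df, location = location)
}

#' Write a weather series as a normalized CSV
#'
#' Writes ISO dates and canonical column names. Numeric values are written
#' with 17 significant digits so [read_power_weather()] round-trips them
#' exactly.
#'
#' @param series a `weather_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path) {
  df <- as.data.frame(series)
  out <- data.frame(date = format(df$date, "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  for (col in setdiff(.weather_cols, "date"))
    out[[col]] <- ifelse(is.na(df[[col]]), "",
                         formatC(df[[col]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  cat("Daily weather series: ", attr(x, "location"), "\n", sep = "")
  cat("  ", nrow(x), " days, ", format(min(x$date)), " to ",
      format(max(x$date)), "\n", sep = "")
  ng <- length(attr(x, "gaps"))
  if (ng) cat("  ", ng, " missing calendar day(s) flagged\n", sep = "")
  nm <- sum(is.na(x$tmax) | is.na(x$tmin) | is.na(x$srad))
  if (nm) cat("  ", nm, " day(s) with missing driver values\n", sep = "")
  invisible(x)
}

#' Daily mean temperature
#'
#' The standard agro-meteorological convention `(tmax + tmin) / 2`.
#'
#' @param tmax,tmin daily maximum and minimum air temperature, deg C.
#' @return Mean temperature, deg C.
#' @export
#' @examples
#' daily_mean_temperature(30, 20)  # 25
daily_mean_temperature <- function(tmax, tmin) {
  if (any(!is.na(tmax) & !is.na(tmin) & tmax < tmin))
    stop("tmax < tmin")
  (tmax + tmin) / 2
}

#' Fill short weather gaps by linear interpolation
#'
#' Explicit opt-in gap fill: `NA` runs of at most `max_gap` days in the
#' numeric drivers are linearly interpolated; longer runs are left missing
#' (and simulation across them remains an error). Silent gap-fill would
#' corrupt thermal time, so nothing calls this automatically.
#'
#' @param series a `weather_series`.
#' @param max_gap longest run of consecutive missing days to fill (default 3).
#' @return A `weather_series` with short gaps filled.
#' @export
fill_weather_gaps <- function(series, max_gap = 3) {
  df <- as.data.frame(series)
  for (col in setdiff(.weather_cols, "date")) {
    v <- df[[col]]
    if (!anyNA(v) || all(is.na(v))) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    fillable <- r$values & r$lengths <= max_gap &
      starts > 1 & ends < length(v)
    idx <- unlist(mapply(seq, starts[fillable], ends[fillable],
                         SIMPLIFY = FALSE))
    if (length(idx)) {
      interp <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                              xout = idx)$y
      v[idx] <- interp
      df[[col]] <- v
    }
  }
  weather_series(df, location = attr(series, "location"))
}

#' Regional climate archetypes for synthetic weather
#'
#' Fixed constants describing the five study regions' climates: annual mean
#' temperature and seasonal amplitude, diurnal range, shortwave radiation
#' mean and amplitude, bimodal rainy seasons (Feb-Apr and Oct-Nov), and
#' near-constant high relative humidity. Apartado is the hottest region
#' (about 26 deg C year-round) and Caldas the coldest (about 16 deg C);
#' the cool Andean sites carry the highest radiation. These are fixtures
#' that emulate the regional patterns, not measured climatologies.
#'
#' @param name optional region name; if given, returns that single archetype
#'   as a list instead of the full table.
#' @return Data frame of archetype parameters (or a single-row list).
#' @export
#' @examples
#' region_archetypes()$mean_temp
region_archetypes <- function(name = NULL) {
  tab <- data.frame(
    name      = c("Apartado", "Arauca", "Santander", "Cali", "Caldas"),
    mean_temp = c(26.1, 25.4, 21.2, 20.6, 16.4),
    temp_seasonal_amplitude = c(0.5, 1.3, 0.8, 0.7, 0.8),
    temp_daily_noise_sd     = c(0.5, 0.8, 0.7, 0.6, 0.7),
    diurnal_range = c(8, 9, 9, 8, 10),
    mean_srad = c(16, 14.5, 19, 14, 18.5),
    srad_amplitude = c(1.5, 2.0, 2.5, 1.5, 2.5),
    srad_noise_sd  = c(2.0, 2.5, 3.0, 2.0, 3.0),
    rain_annual_mm = c(2600, 1900, 1200, 1400, 2100),
    rh_mean = c(86, 82, 83, 81, 85),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$mean_temp >= 14 & tab$mean_temp <= 30),
            all(tab$mean_srad >= 3 & tab$mean_srad <= 22))
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (!nrow(row)) stop("unknown region archetype: ", name)
  as.list(row)
}

# Monthly rain weights with the two Colombian rainy seasons
# (February-April and October-November).
.rain_month_weight <- c(0.5, 1.6, 1.8, 1.6, 0.9, 0.6,
                        0.5, 0.6, 0.9, 1.7, 1.6, 0.7)

#' Generate a seeded synthetic daily weather series
#'
#' Emulates a regional climate: daily mean temperature is the archetype
#' mean plus a seasonal sinusoid plus Gaussian noise, split into tmax/tmin
#' by the diurnal range; shortwave radiation is analogous (floored at
#' 0.5 MJ m-2 day-1); rain follows a wet-day Bernoulli/gamma scheme whose
#' intensity carries the bimodal Feb-Apr / Oct-Nov seasons; relative
#' humidity stays high and near-constant. The same seed always reproduces
#' the same series bit for bit; the RNG state of the session is restored
#' on exit.
#'
#' @param archetype a region name (see [region_archetypes()]) or a list with
#'   the archetype fields.
#' @param start,end first and last date (inclusive).
#' @param seed integer seed; required, for reproducibility.
#' @return A `weather_series`.
#' @export
#' @examples
#' w <- generate_synthetic_weather("Apartado", "2019-01-01", "2019-12-31", seed = 1)
#' mean(daily_mean_temperature(w$tmax, w$tmin))
generate_synthetic_weather <- function(archetype, start, end, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.character(archetype)) archetype <- region_archetypes(archetype)
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop("start must be before end")
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  season <- cos(2 * pi * (doy - 90) / 365.25)
  tmean <- archetype$mean_temp +
    archetype$temp_seasonal_amplitude * season +
    stats::rnorm(n, 0, archetype$temp_daily_noise_sd)
  half_range <- pmax(archetype$diurnal_range / 2 +
                       stats::rnorm(n, 0, 0.5), 0.5)
  tmax <- tmean + half_range
  tmin <- tmean - half_range

  srad <- archetype$mean_srad +
    archetype$srad_amplitude * cos(2 * pi * (doy - 30) / 365.25) +
    stats::rnorm(n, 0, archetype$srad_noise_sd)
  srad <- pmax(srad, 0.5)

  w <- .rain_month_weight[month]
  p_wet <- pmin(0.25 * w, 0.95)
  mean_daily <- archetype$rain_annual_mm / 365.25
  # wet-day mean chosen so the expected daily total is mean_daily * weight,
  # i.e. the annual total converges to rain_annual_mm
  intensity <- mean_daily * w / (mean(.rain_month_weight) * p_wet)
  rain <- stats::rbinom(n, 1, p_wet) *
    stats::rgamma(n, shape = 1.2, scale = intensity / 1.2)

  rh <- pmin(pmax(archetype$rh_mean + stats::rnorm(n, 0, 3), 50), 100)
  wind <- pmax(stats::rnorm(n, 1.5, 0.5), 0.1)
  tdew <- tmean - (100 - rh) / 5

  weather_series(
    data.frame(date = dates, tmax = tmax, tmin = tmin, srad = srad,
               rain = rain, rh = rh, wind = wind, tdew = tdew),
    location = archetype$name
  )
}
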