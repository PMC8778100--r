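# Shared fixture builders: everything is generated in code at test time.

# Constant-climate series: every day has the same mean temperature and
# radiation. tmax = tmin = tmean so the daily mean is exactly tmean.
constant_weather <- function(tmean, srad = 15, days = 230,
                             start = "2019-01-01", location = "const") {
  weather_series(data.frame(
    date = seq(as.Date(start), by = "day", length.out = days),
    tmax = tmean, tmin = tmean, srad = srad, rain = 0),
    location = location)
}

# Seeded random-but-plausible series for oracle comparisons.
random_weather <- function(days, seed, start = "2019-01-01",
                           mean_temp = 22, sd_temp = 4) {
  set.seed(seed)
  tmean <- rnorm(days, mean_temp, sd_temp)
  half <- runif(days, 2, 6)
  weather_series(data.frame(
    date = seq(as.Date(start), by = "day", length.out = days),
    tmax = tmean + half, tmin = tmean - half,
    srad = pmax(rnorm(days, 16, 3), 0.5), rain = 0))
}

# Independent scalar-loop oracle for thermal-time accumulation:
# deliberately written as a plain loop over single days.
oracle_thermal_time <- function(series, fd, horizon, tbase = 10) {
  fd <- as.Date(fd)
  tt <- numeric(horizon + 1)
  for (d in seq_len(horizon)) {
    row <- series[series$date == fd + d, ]
    inc <- (row$tmax + row$tmin) / 2 - tbase
    if (inc < 0) inc <- 0
    tt[d + 1] <- tt[d] + inc
  }
  tt
}

# Write a POWER-dialect CSV for reader tests.
write_power_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
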