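test_that("POWER-dialect reader parses, sorts, and maps columns", {
  path <- write_power_csv(data.frame(
    YYYYMMDD = c("20190713", "20190712"),  # out of order on purpose
    T2M_MAX = c(28, 30), T2M_MIN = c(22, 20),
    ALLSKY_SFC_SW_DWN = c(12, 15), PRECTOTCORR = c(3, 0),
    EXTRA_COLUMN = c(1, 2)))
  w <- read_power_weather(path, location = "testland")
  expect_s3_class(w, "weather_series")
  expect_equal(nrow(w), 2)
  expect_equal(w$date, as.Date(c("2019-07-12", "2019-07-13")))
  expect_equal(daily_mean_temperature(w$tmax[1], w$tmin[1]), 25)
  expect_equal(attr(w, "location"), "testland")
  expect_false("EXTRA_COLUMN" %in% names(w))
})

test_that("reader converts -999 sentinels to NA and simulation refuses gaps", {
  path <- write_power_csv(data.frame(
    YYYYMMDD = format(seq(as.Date("2019-01-01"), by = "day",
                          length.out = 40), "%Y%m%d"),
    T2M_MAX = 30, T2M_MIN = 20,
    ALLSKY_SFC_SW_DWN = c(rep(15, 10), -999, rep(15, 29)),
    PRECTOTCORR = 0))
  w <- read_power_weather(path)
  expect_true(is.na(w$srad[11]))
  expect_false(any(w$srad == -999, na.rm = TRUE))
  # temperature is intact, so thermal time works ...
  expect_silent(accumulate_thermal_time(w, "2019-01-01", horizon = 30))
  # ... but biomass simulation over the missing srad day refuses
  expect_error(
    simulate_cycle(w, "2019-01-01", list(region = "x", tsum = 300, rue = 0.6),
                   species_params(cycle_cap = 30L)),
    "missing srad")
})

test_that("reader and constructor reject malformed input", {
  bad_temp <- write_power_csv(data.frame(
    YYYYMMDD = c("20190712", "20190713"),
    T2M_MAX = c(30, 18), T2M_MIN = c(20, 22),  # second row inverted
    ALLSKY_SFC_SW_DWN = 15, PRECTOTCORR = 0))
  expect_error(read_power_weather(bad_temp), "tmax < tmin")

  no_srad <- write_power_csv(data.frame(
    YYYYMMDD = "20190712", T2M_MAX = 30, T2M_MIN = 20, PRECTOTCORR = 0))
  expect_error(read_power_weather(no_srad), "srad")

  expect_error(weather_series(data.frame(
    date = c("2019-01-01", "2019-01-01"), tmax = 30, tmin = 20,
    srad = 15, rain = 0)), "duplicate")
  expect_error(daily_mean_temperature(20, 30), "tmax < tmin")
})

test_that("weather round-trips through the normalized CSV exactly", {
  w <- generate_synthetic_weather("Santander", "2019-03-01", "2019-08-31",
                                  seed = 42)
  path <- tempfile(fileext = ".csv")
  write_weather(w, path)
  w2 <- read_power_weather(path, location = attr(w, "location"))
  for (col in c("tmax", "tmin", "srad", "rain", "rh", "wind", "tdew"))
    expect_identical(w2[[col]], w[[col]], label = col)
  expect_identical(w2$date, w$date)
})

test_that("synthetic generator reproduces the regional temperature regimes", {
  wa <- generate_synthetic_weather("Apartado", "2019-01-01", "2019-12-31",
                                   seed = 1)
  expect_lt(abs(mean(daily_mean_temperature(wa$tmax, wa$tmin)) - 26), 0.5)
  wc <- generate_synthetic_weather("Caldas", "2019-01-01", "2019-12-31",
                                   seed = 1)
  expect_lt(abs(mean(daily_mean_temperature(wc$tmax, wc$tmin)) - 16), 0.5)
})

test_that("generator is seed-deterministic and respects physical bounds", {
  a <- generate_synthetic_weather("Arauca", "2019-01-01", "2019-12-31",
                                  seed = 7)
  b <- generate_synthetic_weather("Arauca", "2019-01-01", "2019-12-31",
                                  seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_synthetic_weather("Arauca", "2019-01-01", "2019-12-31",
                                  seed = 8)
  expect_false(identical(a$tmax, c$tmax))

  # renaming the location changes the label only, never the numbers
  arch <- region_archetypes("Arauca")
  arch$name <- "elsewhere"
  d <- generate_synthetic_weather(arch, "2019-01-01", "2019-12-31", seed = 7)
  expect_equal(attr(d, "location"), "elsewhere")
  expect_identical(d$tmax, a$tmax)

  for (r in region_archetypes()$name) {
    w <- generate_synthetic_weather(r, "2018-01-01", "2020-12-31", seed = 3)
    expect_true(all(w$tmax >= w$tmin), label = r)
    expect_true(all(w$srad >= 0), label = r)
    expect_true(all(w$rain >= 0), label = r)
    expect_true(all(w$rh >= 0 & w$rh <= 100), label = r)
    # long-run empirical mean converges on the archetype mean
    expect_lt(abs(mean(daily_mean_temperature(w$tmax, w$tmin)) -
                    region_archetypes(r)$mean_temp), 0.3)
  }
})

test_that("generator restores the session RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_synthetic_weather("Cali", "2019-01-01", "2019-02-01",
                                       seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("explicit gap fill interpolates short runs only", {
  df <- data.frame(date = seq(as.Date("2019-01-01"), by = "day",
                              length.out = 20),
                   tmax = 30, tmin = 20, srad = 15, rain = 0)
  df$srad[5:6] <- NA      # 2-day gap: fillable
  df$srad[10:14] <- NA    # 5-day gap: stays missing
  w <- fill_weather_gaps(weather_series(df), max_gap = 3)
  expect_equal(w$srad[5:6], c(15, 15))
  expect_true(all(is.na(w$srad[10:14])))
})
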