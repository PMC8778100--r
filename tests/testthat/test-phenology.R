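test_that("daily thermal increment is (tmean - tbase) clamped at zero", {
  expect_equal(thermal_increment(26), 16)
  expect_equal(thermal_increment(10), 0)
  expect_equal(thermal_increment(8), 0)
  expect_true(all(thermal_increment(seq(-5, 45, by = 0.5)) >= 0))
  expect_error(thermal_increment(NaN), "finite")
})

test_that("thermal-time accumulation matches constants and the loop oracle", {
  w <- constant_weather(26)
  tt <- accumulate_thermal_time(w, "2019-01-01", horizon = 180)
  expect_length(tt, 181)
  expect_equal(unclass(tt)[1], 0)       # flowering day contributes nothing
  expect_equal(unclass(tt)[181], 2880)  # 180 x 16

  cold <- constant_weather(10)
  expect_true(all(unclass(accumulate_thermal_time(cold, "2019-01-01",
                                                  180)) == 0))

  for (seed in c(11, 12, 13)) {
    rw <- random_weather(40, seed = seed)
    got <- accumulate_thermal_time(rw, "2019-01-02", horizon = 30)
    expect_identical(as.vector(unclass(got)),
                     oracle_thermal_time(rw, "2019-01-02", 30))
  }
})

test_that("accumulation refuses insufficient or gappy coverage", {
  w <- constant_weather(26, days = 100)
  expect_error(accumulate_thermal_time(w, "2019-01-01", horizon = 180),
               "coverage")
  df <- as.data.frame(constant_weather(26, days = 100))
  df$tmax[50] <- NA
  wg <- weather_series(df)
  expect_error(accumulate_thermal_time(wg, "2019-01-01", horizon = 90),
               "missing temperature")
})

test_that("regional Tsum characterisation averages per-date accumulations", {
  w <- constant_weather(26, days = 400)
  one <- characterize_tsum(w, "2019-01-01")
  expect_equal(one$tsum, 2880)
  two <- characterize_tsum(w, c("2019-01-01", "2019-02-01"))
  expect_equal(two$tsum, 2880)  # mean of equal values

  syn <- generate_synthetic_weather("Santander", "2018-06-01", "2020-12-31",
                                    seed = 9)
  fds <- synthetic_flowering_dates()
  ch <- characterize_tsum(syn, fds)
  brute <- mean(vapply(fds, function(d)
    oracle_thermal_time(syn, d, 180)[181], numeric(1)))
  expect_equal(ch$tsum, brute)
  expect_length(ch$per_fd, 23)
  # median variant works off the same distribution
  expect_equal(characterize_tsum(syn, fds, stat = "median")$tsum,
               median(ch$per_fd))
})

test_that("harvest-day prediction crosses Tsum on the right day", {
  w <- constant_weather(26)
  expect_equal(predict_harvest_day(w, "2019-01-01", 2880)$daf, 180L)
  r <- predict_harvest_day(w, "2019-01-01", 2906)
  expect_equal(r$daf, 182L)  # 2906/16 = 181.6 -> first crossing day 182
  expect_true(r$reached)

  cold <- constant_weather(12)
  r2 <- predict_harvest_day(cold, "2019-01-01", 2906, cap = 200)
  expect_equal(r2$daf, 200L)
  expect_false(r2$reached)

  expect_error(predict_harvest_day(w, "2019-01-01", -5), "positive")
})

test_that("prediction is consistent, monotone in warming, and scales", {
  syn <- generate_synthetic_weather("Cali", "2018-06-01", "2020-12-31",
                                    seed = 21)
  tsum <- 1912
  for (fd in as.character(synthetic_flowering_dates(6))) {
    r <- predict_harvest_day(syn, fd, tsum)
    tt <- unclass(accumulate_thermal_time(syn, fd, horizon = r$daf))
    expect_gte(tt[r$daf + 1], tsum)
    expect_lt(tt[r$daf], tsum)

    # a uniformly warmer year never delays harvest
    warm <- as.data.frame(syn)
    warm$tmax <- warm$tmax + 1; warm$tmin <- warm$tmin + 1
    rw <- predict_harvest_day(weather_series(warm), fd, tsum)
    expect_lte(rw$daf, r$daf)
  }

  # doubling the increment halves the predicted day (integer rounding)
  base <- predict_harvest_day(constant_weather(18), "2019-01-01", 800)$daf
  dbl <- predict_harvest_day(constant_weather(26), "2019-01-01", 800)$daf
  expect_equal(dbl, ceiling(base / 2), tolerance = 1)

  # closed form under constant climate
  for (tmean in c(16, 20, 26)) for (tsum in c(1192, 2016, 2906)) {
    w <- constant_weather(tmean, days = 600)
    expect_equal(predict_harvest_day(w, "2019-01-01", tsum, cap = 500)$daf,
                 ceiling(tsum / (tmean - 10)))
  }
})

test_that("monthly harvest table groups and averages by flowering month", {
  w <- constant_weather(26, days = 600)
  one <- monthly_harvest_table(w, "2019-01-15", tsum = 2880)
  expect_equal(one$month, 1L)
  expect_equal(one$mean_daf, 180)

  # two January dates whose predictions differ average together
  syn <- generate_synthetic_weather("Arauca", "2018-06-01", "2020-12-31",
                                    seed = 4)
  fds <- synthetic_flowering_dates()
  tab <- monthly_harvest_table(syn, fds, tsum = 2764)
  brute <- vapply(fds, function(d)
    as.numeric(predict_harvest_day(syn, d, 2764)$daf), numeric(1))
  expected <- tapply(brute, as.integer(format(fds, "%m")), mean)
  expect_equal(tab$mean_daf, as.numeric(expected))
  expect_equal(sum(tab$n), 23)
  expect_true(all(tab$month %in% 1:12))
})
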