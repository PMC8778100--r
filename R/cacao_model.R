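# The model front end: fit (characterise + calibrate + evaluate) and the
# usual methods on the fitted object.

#' Fit the cacao harvest model to flowering-date samples
#'
#' The fitting procedure mirrors the field calibration workflow. Per
#' region: (1) *characterise* the thermal-time requirement Tsum as the
#' mean 180-DAF degree-day accumulation over the region's flowering dates;
#' (2) *calibrate* the radiation use efficiency RUE by grid search against
#' the observed yields (skipped when `rue` is supplied); (3) *evaluate* by
#' simulating every sample at the fitted parameters and scoring observed
#' vs predicted yield with the RRMSE, per region and pooled.
#'
#' @param samples data frame with columns `region`, `flowering_date` and,
#'   for calibration/evaluation, `observed_yield` (kg ha-1 yr-1).
#' @param weather a named list of [weather_series()] (names matching the
#'   regions in `samples`), or a single series if only one region is fit.
#' @param species a [species_params()] list.
#' @param rue optional fixed RUE: a single value or a named vector per
#'   region; when given, grid calibration is skipped.
#' @param rue_grid candidate RUE values for calibration, g MJ-1.
#' @param horizon DAF at which Tsum is characterised (default 180).
#' @param co2 atmospheric CO2, ppm.
#' @param variant RRMSE variant, see [rrmse()].
#' @return A `cacao_model` object with methods [print()], [summary()],
#'   [coef()], [predict()], [fitted()], [residuals()] and [plot()].
#' @export
#' @examples
#' w <- generate_synthetic_weather("Apartado", "2018-06-01", "2020-12-31", seed = 1)
#' s <- data.frame(region = "Apartado",
#'                 flowering_date = synthetic_flowering_dates(5),
#'                 observed_yield = 3378)
#' fit <- cacao_model(s, list(Apartado = w))
#' coef(fit)
cacao_model <- function(samples, weather, species = species_params(),
                        rue = NULL, rue_grid = seq(0.50, 0.70, by = 0.05),
                        horizon = 180, co2 = 400,
                        variant = c("quadmean", "obsmean")) {
  variant <- match.arg(variant)
  cl <- match.call()
  samples <- as.data.frame(samples)
  if (!all(c("region", "flowering_date") %in% names(samples)))
    stop("samples need columns 'region' and 'flowering_date'")
  samples$flowering_date <- as.Date(samples$flowering_date)
  regions <- unique(samples$region)
  if (inherits(weather, "weather_series")) {
    if (length(regions) > 1)
      stop("a single weather series cannot serve multiple regions")
    weather <- stats::setNames(list(weather), regions)
  }
  absent <- setdiff(regions, names(weather))
  if (length(absent))
    stop("no weather series for region(s): ", paste(absent, collapse = ", "))
  have_yield <- "observed_yield" %in% names(samples) &&
    !anyNA(samples$observed_yield)
  if (is.null(rue) && !have_yield)
    stop("observed_yield required to calibrate RUE; or supply rue =")

  coefs <- data.frame(region = regions, tsum = NA_real_, rue = NA_real_,
                      calibration_rrmse = NA_real_,
                      stringsAsFactors = FALSE)
  tsum_dist <- list()
  calibrations <- list()
  for (r in regions) {
    sel <- samples$region == r
    ch <- characterize_tsum(weather[[r]], samples$flowering_date[sel],
                            horizon = horizon, tbase = species$tbase)
    coefs$tsum[coefs$region == r] <- ch$tsum
    tsum_dist[[r]] <- ch$per_fd
    reg <- list(region = r, tsum = ch$tsum, rue = NA_real_)
    if (is.null(rue)) {
      cal <- calibrate_rue(weather[[r]], samples[sel, , drop = FALSE], reg,
                           grid = rue_grid, p = species, co2 = co2,
                           variant = variant)
      coefs$rue[coefs$region == r] <- cal$selected_rue
      coefs$calibration_rrmse[coefs$region == r] <- cal$selected_rrmse
      calibrations[[r]] <- cal
    } else {
      coefs$rue[coefs$region == r] <-
        if (length(rue) == 1 && is.null(names(rue))) rue else rue[[r]]
    }
  }

  fit <- structure(list(call = cl, coefficients = coefs,
                        tsum_distribution = tsum_dist,
                        calibrations = calibrations,
                        samples = samples, weather = weather,
                        species = species, co2 = co2, variant = variant,
                        horizon = horizon),
                   class = "cacao_model")
  pred <- predict(fit, samples, type = "both")
  fit$fitted <- pred
  if (have_yield)
    fit$evaluation <- evaluate_regions(samples, pred$yield, variant)
  fit
}

.region_list <- function(object, r) {
  co <- object$coefficients
  i <- match(r, co$region)
  if (is.na(i)) stop("model was not fit for region: ", r)
  list(region = r, tsum = co$tsum[i], rue = co$rue[i])
}

#' Predict harvest day and yield for new flowering dates
#'
#' @param object a fitted [cacao_model()].
#' @param newdata data frame with `region` and `flowering_date`; defaults
#'   to the fitting samples.
#' @param type `"harvest"` (predicted DAF), `"yield"` (kg ha-1), or
#'   `"both"` (data frame with `harvest_daf`, `reached`, `tt_at_harvest`,
#'   `yield`).
#' @param weather optional named list of weather series for regions or
#'   periods not seen at fit time; defaults to the fitting weather.
#' @param ... unused.
#' @return Numeric vector or data frame, one entry per `newdata` row.
#' @export
predict.cacao_model <- function(object, newdata = object$samples,
                                type = c("both", "harvest", "yield"),
                                weather = object$weather, ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  fds <- as.Date(newdata$flowering_date)
  out <- data.frame(region = newdata$region,
                    flowering_date = fds,
                    harvest_daf = NA_integer_, reached = NA,
                    tt_at_harvest = NA_real_, yield = NA_real_)
  for (i in seq_len(nrow(newdata))) {
    r <- newdata$region[i]
    reg <- .region_list(object, r)
    tr <- simulate_cycle(weather[[r]], fds[i], reg, object$species,
                         object$co2)
    out$harvest_daf[i] <- attr(tr, "harvest_daf")
    out$reached[i] <- attr(tr, "reached")
    out$tt_at_harvest[i] <- tr$tt[nrow(tr)]
    out$yield[i] <- attr(tr, "yield")
  }
  switch(type, both = out, harvest = out$harvest_daf, yield = out$yield)
}

#' @export
coef.cacao_model <- function(object, ...) {
  m <- as.matrix(object$coefficients[c("tsum", "rue")])
  rownames(m) <- object$coefficients$region
  m
}

#' @export
fitted.cacao_model <- function(object, ...) object$fitted$yield

#' @export
residuals.cacao_model <- function(object, ...) {
  if (is.null(object$samples$observed_yield))
    stop("no observed yields were supplied")
  object$samples$observed_yield - object$fitted$yield
}

#' @export
print.cacao_model <- function(x, ...) {
  cat("Cacao harvest model\n")
  cat("  ", nrow(x$samples), " flowering-date samples, ",
      nrow(x$coefficients), " region(s)\n", sep = "")
  co <- x$coefficients
  co$tsum <- round(co$tsum, 0)
  co$calibration_rrmse <- round(co$calibration_rrmse, 2)
  print.data.frame(co, row.names = FALSE)
  if (!is.null(x$evaluation))
    cat("Pooled yield RRMSE: ", round(x$evaluation$overall, 2), "%\n",
        sep = "")
  invisible(x)
}

#' Summarise a fitted cacao model
#'
#' Per-region coefficients (Tsum, RUE), the per-region and pooled RRMSE,
#' and the distribution of predicted harvest days.
#'
#' @param object a fitted [cacao_model()].
#' @param ... unused.
#' @export
summary.cacao_model <- function(object, ...) {
  daf <- object$fitted$harvest_daf
  structure(list(call = object$call,
                 coefficients = object$coefficients,
                 evaluation = object$evaluation,
                 harvest_daf_range = range(daf),
                 harvest_daf_mean = mean(daf),
                 n = nrow(object$samples)),
            class = "summary.cacao_model")
}

#' @export
print.summary.cacao_model <- function(x, ...) {
  cat("Cacao harvest model fit\n\nCoefficients (per region):\n")
  co <- x$coefficients
  co$tsum <- round(co$tsum, 0)
  co$calibration_rrmse <- round(co$calibration_rrmse, 2)
  print.data.frame(co, row.names = FALSE)
  cat("\nPredicted harvest: ", round(x$harvest_daf_mean, 1),
      " DAF on average (range ", x$harvest_daf_range[1], "-",
      x$harvest_daf_range[2], ") over ", x$n, " samples\n", sep = "")
  if (!is.null(x$evaluation)) { cat("\n"); print(x$evaluation) }
  invisible(x)
}

#' Plot a fitted cacao model
#'
#' Two base-graphics panels: the canopy interception curve over thermal
#' time for each region (logistic growth and senescence around the fitted
#' Tsum), and observed versus predicted yield when observations exist.
#'
#' @param x a fitted [cacao_model()].
#' @param which `1` (fSolar curves), `2` (observed vs predicted), or both.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cacao_model <- function(x, which = 1:2, ...) {
  co <- x$coefficients
  if (is.null(x$evaluation)) which <- setdiff(which, 2)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if (1 %in% which) {
    tt <- seq(0, max(co$tsum), length.out = 400)
    graphics::plot(NA, xlim = range(tt), ylim = c(0, 1),
                   xlab = "Thermal time (deg C day)",
                   ylab = "Intercepted fraction (fSolar)", ...)
    for (i in seq_len(nrow(co)))
      graphics::lines(tt, fsolar(tt, x$species, co$tsum[i]), col = i)
    graphics::legend("topright", legend = co$region, col = seq_len(nrow(co)),
                     lty = 1, cex = 0.8, bty = "n")
  }
  if (2 %in% which) {
    obs <- x$samples$observed_yield
    pred <- x$fitted$yield
    lim <- range(c(obs, pred))
    graphics::plot(pred, obs, xlim = lim, ylim = lim,
                   xlab = "Predicted yield (kg/ha)",
                   ylab = "Observed yield (kg/ha)", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
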