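# Model evaluation (RRMSE) and trial-and-error RUE calibration.

#' Relative root-mean-square error
#'
#' `100 * sqrt(mean((obs - pred)^2)) / sqrt(mean(pred^2))`: the RMSE
#' normalised by the quadratic mean of the predictions, a percentage
#' invariant to sample size and to common rescaling of both vectors.
#' The conventional crop-modelling variant normalising by the mean of the
#' observations is available via `variant = "obsmean"`.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @param variant `"quadmean"` (default) or `"obsmean"`.
#' @return RRMSE in percent.
#' @export
#' @examples
#' rrmse(c(110, 90), c(100, 100))  # 10
rrmse <- function(observed, predicted, variant = c("quadmean", "obsmean")) {
  variant <- match.arg(variant)
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (!length(observed)) stop("empty input")
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(variant,
                  quadmean = sqrt(mean(predicted^2)),
                  obsmean = mean(observed))
  if (!is.finite(denom) || denom == 0) stop("zero denominator")
  100 * rmse / denom
}

#' Evaluate yield predictions per region and overall
#'
#' RRMSE per region over that region's (observed, predicted) pairs, and
#' the overall RRMSE over all pairs pooled (not the average of the
#' regional values).
#'
#' @param samples data frame with columns `region` and `observed_yield`.
#' @param predicted numeric vector of predicted yields, one per sample row.
#' @param variant RRMSE variant, see [rrmse()].
#' @return An `evaluation_report`: list with `per_region` (data frame
#'   `region`, `rrmse`, `n`), `overall` (%), `n`, and the paired data.
#' @export
evaluate_regions <- function(samples, predicted,
                             variant = c("quadmean", "obsmean")) {
  variant <- match.arg(variant)
  if (nrow(samples) != length(predicted))
    stop("one prediction per sample required")
  if (anyNA(predicted)) stop("missing prediction")
  regions <- unique(samples$region)
  per <- do.call(rbind, lapply(regions, function(r) {
    sel <- samples$region == r
    data.frame(region = r,
               rrmse = rrmse(samples$observed_yield[sel], predicted[sel],
                             variant),
               n = sum(sel), stringsAsFactors = FALSE)
  }))
  pairs <- data.frame(region = samples$region,
                      observed = samples$observed_yield,
                      predicted = predicted, stringsAsFactors = FALSE)
  structure(list(per_region = per,
                 overall = rrmse(pairs$observed, pairs$predicted, variant),
                 n = nrow(pairs), pairs = pairs, variant = variant),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Yield evaluation (RRMSE %, ", x$n, " samples)\n", sep = "")
  tab <- x$per_region
  tab$rrmse <- round(tab$rrmse, 2)
  print.data.frame(tab, row.names = FALSE)
  cat("Overall (pooled): ", round(x$overall, 2), "%\n", sep = "")
  invisible(x)
}

#' Calibrate radiation use efficiency by grid search
#'
#' The reproducible analogue of trial-and-error calibration: each candidate
#' RUE on the grid (0.5 to 0.7 g MJ-1 by default, the plausible range for
#' shade-grown cacao) is used to simulate every flowering-date sample; the
#' RRMSE between observed and simulated yields is recorded; the RUE with
#' the smallest RRMSE is selected (ties resolve to the lowest RUE). The
#' whole grid is evaluated, so the "stops when the fit no longer improves"
#' rule is realised exactly.
#'
#' @param series a [weather_series()] for the region.
#' @param samples data frame with `flowering_date` and `observed_yield`.
#' @param region a [region_params()] list (or name); its `rue` is replaced
#'   by each grid value in turn, `tsum` is held fixed.
#' @param grid candidate RUE values, g MJ-1.
#' @param p a [species_params()] list.
#' @param co2 atmospheric CO2, ppm.
#' @param variant RRMSE variant, see [rrmse()].
#' @return A `calibration_result`: list with `region`, `grid`,
#'   `rrmse_per_rue`, `selected_rue`, `selected_rrmse`.
#' @export
calibrate_rue <- function(series, samples, region,
                          grid = seq(0.50, 0.70, by = 0.05),
                          p = species_params(), co2 = 400,
                          variant = c("quadmean", "obsmean")) {
  variant <- match.arg(variant)
  if (!length(grid)) stop("grid must be non-empty")
  if (is.character(region)) region <- region_params(region)
  grid <- sort(grid)
  fds <- as.Date(samples$flowering_date)
  # yield scales linearly in RUE, but simulate per grid point anyway:
  # the contract is exhaustive evaluation of the objective.
  scores <- vapply(grid, function(rue) {
    reg <- region; reg$rue <- rue
    pred <- vapply(seq_along(fds), function(i)
      attr(simulate_cycle(series, fds[i], reg, p, co2), "yield"),
      numeric(1))
    rrmse(samples$observed_yield, pred, variant)
  }, numeric(1))
  best <- which.min(scores)  # which.min takes the first, i.e. lowest RUE, on ties
  structure(list(region = region$region, grid = grid,
                 rrmse_per_rue = scores,
                 selected_rue = grid[best],
                 selected_rrmse = scores[best]),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("RUE calibration", if (!is.null(x$region)) paste0(": ", x$region),
      "\n", sep = "")
  print.data.frame(data.frame(rue = x$grid,
                              rrmse = round(x$rrmse_per_rue, 2)),
                   row.names = FALSE)
  cat("Selected RUE: ", x$selected_rue, " (RRMSE ",
      round(x$selected_rrmse, 2), "%)\n", sep = "")
  invisible(x)
}
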