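# Canopy light interception and RUE-driven biomass: the adapted
# SIMPLE-model core with cacao parameter values.

#' Species and cultivar parameter set
#'
#' Default physiological parameters shared by cultivars ICS95 and CCN51:
#' cardinal temperatures (base 10, optimum 26, heat-stress onset 35,
#' extreme 40 deg C), CO2 response slope per 100 ppm, drought sensitivity
#' (0: water stress disabled), logistic canopy parameters `i50a`/`i50b`
#' (thermal time to reach, respectively lose, 50% interception; 680 deg C
#' day each), maximum intercepted fraction `fsolar_max` (0.94), harvest
#' index (0.3), and the 200-day crop-cycle cap. `initial_fsolar` is carried
#' for the configuration file but the logistic itself governs the day-0
#' interception (about 0.001), which is not floored.
#'
#' @param ... named overrides of any default.
#' @return A `species_params` list.
#' @export
#' @examples
#' species_params(fsolar_max = 0.95)$fsolar_max
species_params <- function(...) {
  p <- list(tbase = 10, topt = 26, maxt = 35, extremet = 40,
            s_co2 = 0.09, s_water = 0, i50a = 680, i50b = 680,
            hi = 0.3, fsolar_max = 0.94, initial_fsolar = 0.01,
            cycle_cap = 200L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  validate_species_params(p)
  structure(p, class = "species_params")
}

#' @rdname species_params
#' @param p a parameter list to validate.
#' @export
validate_species_params <- function(p) {
  stopifnot(p$tbase < p$topt, p$topt < p$maxt, p$maxt < p$extremet)
  if (p$hi <= 0 || p$hi >= 1) stop("harvest index hi must be in (0, 1)")
  if (p$fsolar_max <= 0 || p$fsolar_max > 1)
    stop("fsolar_max must be in (0, 1]")
  if (p$i50a <= 0 || p$i50b <= 0) stop("i50a and i50b must be positive")
  if (p$s_water < 0 || p$s_water > 1) stop("s_water must be in [0, 1]")
  invisible(p)
}

#' Regional parameter table
#'
#' The three per-region model parameters: thermal-time requirement Tsum
#' (deg C day), radiation use efficiency RUE (g MJ-1, above-ground and
#' respiration-free), and the observed annual yield (kg dry beans ha-1
#' yr-1) used for evaluation.
#'
#' @param region optional region name; if given, returns that row as a list.
#' @return Data frame with columns `region`, `tsum`, `rue`, `observed_yield`
#'   (or a single-row list).
#' @export
#' @examples
#' region_params("Apartado")$tsum
region_params <- function(region = NULL) {
  tab <- data.frame(
    region = c("Apartado", "Arauca", "Santander", "Cali", "Caldas"),
    tsum   = c(2906, 2764, 2016, 1912, 1192),
    rue    = c(0.6, 0.7, 0.6, 0.5, 0.6),
    observed_yield = c(3378, 3981, 2687, 1900, 740),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$rue >= 0.4 & tab$rue <= 0.9), all(tab$tsum > 0))
  if (is.null(region)) return(tab)
  row <- tab[tab$region == region, ]
  if (!nrow(row)) stop("unknown region: ", region)
  as.list(row)
}

#' Fraction of solar radiation intercepted by the canopy
#'
#' The point-wise minimum of a logistic canopy growth curve (midpoint at
#' thermal time `i50a`) and a logistic senescence curve (midpoint at
#' `tsum - i50b`), scaled by `fsolar_max`:
#' `fsolar_max * min(1 / (1 + exp(-0.01 (tt - i50a))),
#'                   1 / (1 + exp(+0.01 (tt - (tsum - i50b)))))`.
#' The curve is unimodal in thermal time with its peak at
#' `tt* = (i50a + tsum - i50b) / 2`.
#'
#' @param tt thermal time since flowering, deg C day (vectorised, >= 0).
#' @param p a [species_params()] list.
#' @param tsum regional thermal-time requirement, deg C day.
#' @return Intercepted fraction in `[0, fsolar_max]`.
#' @export
#' @examples
#' fsolar(680, species_params(), tsum = 2906)  # fsolar_max / 2 at the midpoint
fsolar <- function(tt, p, tsum) {
  if (any(tt < 0)) stop("tt must be non-negative")
  growth <- 1 / (1 + exp(-0.01 * (tt - p$i50a)))
  senesc <- 1 / (1 + exp(0.01 * (tt - (tsum - p$i50b))))
  p$fsolar_max * pmin(growth, senesc)
}

#' Peak canopy interception (closed form)
#'
#' The maximum of [fsolar()] over thermal time, attained at
#' `tt* = (i50a + tsum - i50b) / 2` where the two logistics cross.
#'
#' @inheritParams fsolar
#' @return List with `tt_star` and `peak`.
#' @export
fsolar_peak <- function(p, tsum) {
  tt_star <- (p$i50a + tsum - p$i50b) / 2
  list(tt_star = tt_star,
       peak = p$fsolar_max / (1 + exp(-0.01 * (tt_star - p$i50a))))
}

#' Temperature response factor
#'
#' Linear ramp from 0 at the base temperature to 1 at the optimum;
#' 1 above the optimum, 0 below the base.
#'
#' @param tmean daily mean temperature, deg C (vectorised).
#' @param p a [species_params()] list.
#' @return Factor in `[0, 1]`.
#' @export
ftemp <- function(tmean, p) {
  pmin(pmax((tmean - p$tbase) / (p$topt - p$tbase), 0), 1)
}

#' CO2 response multiplier
#'
#' `1 + s_co2 * (co2 - 350) / 100` between 350 and 700 ppm; 1 below
#' 350 ppm and saturating at the 700 ppm value above. At the default
#' 400 ppm and slope 0.09 the multiplier is 1.045.
#'
#' @param co2 atmospheric CO2 concentration, ppm (vectorised, > 0).
#' @param p a [species_params()] list.
#' @return Multiplier >= 1.
#' @export
fco2 <- function(co2, p) {
  if (any(co2 <= 0)) stop("co2 must be positive")
  1 + p$s_co2 * (pmin(pmax(co2, 350), 700) - 350) / 100
}

#' Heat stress factor
#'
#' 1 up to the heat-stress onset `maxt`, declining linearly to 0 at
#' `extremet`, 0 beyond. Neutral (exactly 1) at Colombian canopy
#' temperatures, which stay below 35 deg C; carried so the simulation is
#' complete, not because the study conditions exercise it.
#'
#' @param tmax daily maximum temperature, deg C (vectorised).
#' @param p a [species_params()] list.
#' @return Factor in `[0, 1]`.
#' @export
fheat <- function(tmax, p) {
  pmin(pmax((p$extremet - tmax) / (p$extremet - p$maxt), 0), 1)
}

#' Water stress factor
#'
#' `1 - s_water * arid` for an ARID drought index in `[0, 1]`
#' (0 = no shortage, 1 = extreme shortage). With the default
#' `s_water = 0` the factor is always 1: drought stress is disabled.
#'
#' @param arid ARID index in `[0, 1]` (vectorised).
#' @param p a [species_params()] list.
#' @return Factor in `[0, 1]`.
#' @export
fwater <- function(arid, p) {
  if (any(arid < 0 | arid > 1)) stop("arid must be in [0, 1]")
  1 - p$s_water * arid
}

#' Daily biomass growth rate
#'
#' `srad * fsolar * rue * fco2 * ftemp * min(fheat, fwater) * 10`.
#' The unit chain: SRAD (MJ m-2 day-1) times RUE (g MJ-1) gives
#' g m-2 day-1; the factor 10 converts to kg ha-1 day-1.
#'
#' @param srad shortwave radiation, MJ m-2 day-1.
#' @param fsolar intercepted fraction.
#' @param rue radiation use efficiency, g MJ-1.
#' @param fco2,ftemp,fheat,fwater response factors.
#' @return Growth rate, kg ha-1 day-1.
#' @export
daily_biomass_rate <- function(srad, fsolar, rue, fco2 = 1, ftemp = 1,
                               fheat = 1, fwater = 1) {
  srad * fsolar * rue * fco2 * ftemp * pmin(fheat, fwater) * 10
}

#' Simulate one pod-development cycle
#'
#' The daily loop from flowering: thermal time accumulates (base 10 deg C),
#' the canopy interception fraction follows the logistic pair, biomass
#' grows at the RUE-driven rate, and the cycle stops on the first day
#' accumulated thermal time reaches the regional Tsum (or at the 200-day
#' cap). Yield is the harvest-index fraction of accumulated biomass at the
#' stop day.
#'
#' @param series a [weather_series()] covering `fd + 1 .. fd + cycle_cap`.
#' @param fd flowering date.
#' @param region a [region_params()] list (or region name) supplying `tsum`
#'   and `rue`.
#' @param p a [species_params()] list.
#' @param co2 atmospheric CO2, ppm (default 400).
#' @return A `simulation_trace`: data frame with one row per DAF 0..stop
#'   (`daf`, `date`, `tt`, `fsolar`, `biomass_rate`, `cumulative_biomass`)
#'   and attributes `harvest_daf`, `reached`, `yield`, `region`, `fd`.
#' @export
#' @examples
#' w <- generate_synthetic_weather("Apartado", "2019-01-01", "2019-12-31", seed = 1)
#' tr <- simulate_cycle(w, "2019-02-01", "Apartado")
#' attr(tr, "yield")
simulate_cycle <- function(series, fd, region, p = species_params(),
                           co2 = 400) {
  if (is.character(region)) region <- region_params(region)
  if (!is.finite(region$tsum) || region$tsum <= 0)
    stop("tsum must be positive")
  fd <- as.Date(fd)
  cap <- p$cycle_cap
  tmean <- .window_tmean(series, fd, cap, allow_partial = TRUE)
  idx <- match(fd + seq_along(tmean), series$date)
  srad <- series$srad[idx]
  if (anyNA(srad))
    stop("missing srad inside the simulation window; ",
         "use fill_weather_gaps() to interpolate short gaps explicitly")
  tmax <- series$tmax[idx]

  tt <- .running_sum(thermal_increment(tmean, p$tbase))
  hit <- which(tt >= region$tsum)
  if (length(hit)) { stop_day <- hit[1]; reached <- TRUE }
  else if (length(tmean) == cap) { stop_day <- cap; reached <- FALSE }
  else stop("weather coverage insufficient: thermal requirement not met by ",
            format(fd + length(tmean)),
            " and series ends before the ", cap, "-day cap")

  d <- seq_len(stop_day)
  fs <- fsolar(tt[d], p, region$tsum)
  rate <- daily_biomass_rate(srad[d], fs, region$rue,
                             fco2 = fco2(co2, p),
                             ftemp = ftemp(tmean[d], p),
                             fheat = fheat(tmax[d], p),
                             fwater = fwater(0, p))
  cum <- cumsum(rate)

  trace <- data.frame(
    daf = 0:stop_day,
    date = fd + 0:stop_day,
    tt = c(0, tt[d]),
    fsolar = c(fsolar(0, p, region$tsum), fs),
    biomass_rate = c(0, rate),
    cumulative_biomass = c(0, cum)
  )
  structure(trace,
            harvest_daf = as.integer(stop_day), reached = reached,
            yield = p$hi * cum[stop_day],
            region = region$region, fd = fd, rue = region$rue,
            hi = p$hi,
            class = c("simulation_trace", "data.frame"))
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("Cacao pod development cycle: ",
      if (!is.null(attr(x, "region"))) attr(x, "region") else "",
      ", flowering ", format(attr(x, "fd")), "\n", sep = "")
  cat("  harvest at ", attr(x, "harvest_daf"), " DAF (",
      if (attr(x, "reached")) "thermal requirement met"
      else "cycle cap, requirement not met", ")\n", sep = "")
  cat("  accumulated biomass ",
      round(x$cumulative_biomass[nrow(x)], 1), " kg/ha, yield ",
      round(attr(x, "yield"), 1), " kg/ha (HI = ", attr(x, "hi"),
      ")\n", sep = "")
  invisible(x)
}
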