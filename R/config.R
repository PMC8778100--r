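# Seven-file CSV configuration bundle and offline fixture generation.
#
# The model reads its inputs from seven small CSVs: soil (inert metadata),
# treatment (weather file, CO2, sowing date = flowering date, cycle cap),
# observation (LAI, observed fSolar, per-plant biomass, harvest index,
# initial fSolar), cultivar (i50a/i50b per cultivar), species (cardinal
# temperatures, CO2/water response), region (Tsum, RUE, observed yield)
# and samples (flowering dates with observed yields).

.default_config_files <- c(
  soil = "soil.csv", treatment = "treatment.csv",
  observation = "observation.csv", cultivar = "cultivar.csv",
  species = "species.csv", region = "region.csv",
  samples = "samples_synthetic.csv"
)

.read_kv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variable", "value") %in% names(df)))
    stop(basename(path), " must have columns 'variable' and 'value'")
  stats::setNames(as.list(df$value), df$variable)
}

.num <- function(kv, key, file) {
  v <- suppressWarnings(as.numeric(kv[[key]]))
  if (is.null(kv[[key]]) || is.na(v))
    stop("missing or non-numeric required key '", key, "' in ", file)
  v
}

#' Load the seven-file configuration bundle
#'
#' Reads, validates and assembles the configuration directory. Missing
#' files or required keys are fatal; unknown keys produce a warning and
#' are carried through untouched. Out-of-range values (e.g. a harvest
#' index of 1.3) fail validation with the field named.
#'
#' @param directory configuration directory. The package ships a default
#'   bundle under `system.file("extdata", "config", package = "cacaoharvest")`;
#'   its samples file is a synthetic reconstruction (the field flowering
#'   dates are not published).
#' @param files named character vector overriding the default file names
#'   (names `soil`, `treatment`, `observation`, `cultivar`, `species`,
#'   `region`, `samples`).
#' @return A `config_bundle` list with elements `soil`, `treatment`,
#'   `observation`, `cultivar`, `species` (a [species_params()] object),
#'   `region` (data frame), `samples` (data frame).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "config", package = "cacaoharvest"))
#' cfg$species$tbase
load_config <- function(directory, files = .default_config_files) {
  files <- utils::modifyList(as.list(.default_config_files), as.list(files))
  paths <- vapply(names(.default_config_files),
                  function(k) file.path(directory, files[[k]]), character(1))
  names(paths) <- names(.default_config_files)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("missing configuration file(s): ",
         paste(basename(absent), collapse = ", "))

  soil <- .read_kv(paths["soil"])
  treatment <- .read_kv(paths["treatment"])
  observation <- .read_kv(paths["observation"])
  species_kv <- .read_kv(paths["species"])

  known <- list(
    soil = "soil_name",
    treatment = c("weather", "co2", "sowing_date", "cycle_cap"),
    observation = c("lai", "fsolar_obs", "biomass_per_plant",
                    "harvest_index", "initial_fsolar", "fsolar_max"),
    species = c("tbase", "topt", "maxt", "extremet", "co2rue", "s_water")
  )
  for (sec in names(known)) {
    kv <- switch(sec, soil = soil, treatment = treatment,
                 observation = observation, species = species_kv)
    extra <- setdiff(names(kv), known[[sec]])
    if (length(extra))
      warning("unknown key(s) in ", basename(paths[sec]), ": ",
              paste(extra, collapse = ", "))
  }

  cultivar <- utils::read.csv(paths["cultivar"], stringsAsFactors = FALSE)
  if (!all(c("cultivar", "i50a", "i50b") %in% names(cultivar)))
    stop("cultivar file must have columns cultivar, i50a, i50b")

  region <- utils::read.csv(paths["region"], stringsAsFactors = FALSE)
  if (!all(c("region", "tsum", "rue", "observed_yield") %in% names(region)))
    stop("region file must have columns region, tsum, rue, observed_yield")

  samples <- utils::read.csv(paths["samples"], stringsAsFactors = FALSE)
  if (!all(c("region", "flowering_date") %in% names(samples)))
    stop("samples file must have columns region, flowering_date")
  samples$flowering_date <- as.Date(samples$flowering_date)
  if (anyNA(samples$flowering_date))
    stop("unparsable flowering_date in samples file")

  hi <- .num(observation, "harvest_index", "observation")
  if (hi <= 0 || hi >= 1)
    stop("harvest_index out of range (0, 1): ", hi)
  fsmax <- if (!is.null(observation$fsolar_max))
    .num(observation, "fsolar_max", "observation") else 0.94

  species <- species_params(
    tbase = .num(species_kv, "tbase", "species"),
    topt = .num(species_kv, "topt", "species"),
    maxt = .num(species_kv, "maxt", "species"),
    extremet = .num(species_kv, "extremet", "species"),
    s_co2 = .num(species_kv, "co2rue", "species"),
    s_water = .num(species_kv, "s_water", "species"),
    i50a = as.numeric(cultivar$i50a[1]),
    i50b = as.numeric(cultivar$i50b[1]),
    hi = hi,
    fsolar_max = fsmax,
    initial_fsolar = .num(observation, "initial_fsolar", "observation"),
    cycle_cap = as.integer(.num(treatment, "cycle_cap", "treatment"))
  )

  structure(list(
    soil = soil, treatment = treatment, observation = observation,
    cultivar = cultivar, species = species, region = region,
    samples = samples, co2 = .num(treatment, "co2", "treatment"),
    directory = directory
  ), class = "config_bundle")
}

#' @export
print.config_bundle <- function(x, ...) {
  cat("Cacao model configuration (", x$directory, ")\n", sep = "")
  cat("  regions: ", paste(x$region$region, collapse = ", "), "\n", sep = "")
  cat("  samples: ", nrow(x$samples), " flowering dates\n", sep = "")
  cat("  CO2 ", x$co2, " ppm, HI ", x$species$hi, ", cycle cap ",
      x$species$cycle_cap, " days\n", sep = "")
  invisible(x)
}

#' Reconstructed flowering dates
#'
#' The study design sampled 23 flowering dates per farm between 2019-07-12
#' and 2020-06-23; the individual dates are unpublished, so fixtures use
#' 23 evenly spaced dates across that window (endpoints included).
#'
#' @param n number of dates (default 23).
#' @param start,end window endpoints.
#' @return Vector of Dates.
#' @export
synthetic_flowering_dates <- function(n = 23, start = "2019-07-12",
                                      end = "2020-06-23") {
  start <- as.Date(start); end <- as.Date(end)
  offsets <- round(seq(0, as.numeric(end - start), length.out = n))
  start + offsets
}

#' Generate the offline fixture set
#'
#' Writes everything needed to run the full pipeline without network
#' access: per region, archetype-driven synthetic weather covering
#' 2018-01-01 to 2021-03-31 (the 2018-2020 study window extended far
#' enough that the latest flowering date supports a full 200-day
#' simulation cap); a samples table of 23 evenly spaced flowering dates
#' per region (115 in total) with observed annual yields near the regional
#' reference values under seeded multiplicative noise of up to +/-10%; and
#' the seven-file configuration bundle. The same seed reproduces the same
#' directory byte for byte.
#'
#' @param directory output directory (created if absent).
#' @param seed integer seed.
#' @param regions region names (default all five archetypes).
#' @param yield_noise half-width of the uniform multiplicative noise on
#'   observed yields (default 0.10).
#' @return Invisibly, the named vector of files written.
#' @export
make_fixtures <- function(directory, seed, regions = region_archetypes()$name,
                          yield_noise = 0.10) {
  if (missing(seed)) stop("seed is required")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  for (i in seq_along(regions)) {
    w <- generate_synthetic_weather(regions[i], "2018-01-01", "2021-03-31",
                                    seed = seed + i)
    f <- file.path(directory, paste0("weather_", tolower(regions[i]), ".csv"))
    write_weather(w, f)
    written <- c(written, f)
  }

  fds <- synthetic_flowering_dates()
  reg_tab <- region_params()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  samples <- do.call(rbind, lapply(regions, function(r) {
    base_yield <- reg_tab$observed_yield[match(r, reg_tab$region)]
    data.frame(
      region = r,
      flowering_date = format(fds, "%Y-%m-%d"),
      observed_harvest_date = format(fds + 180, "%Y-%m-%d"),
      observed_yield = round(base_yield *
                               (1 + stats::runif(length(fds), -yield_noise,
                                                 yield_noise)), 1),
      plant_density = 1100L,
      tree_age = 8L,
      stringsAsFactors = FALSE
    )
  }))
  sf <- file.path(directory, "samples_synthetic.csv")
  utils::write.csv(samples, sf, row.names = FALSE, quote = FALSE)
  written <- c(written, sf)

  kv <- function(name, ...) {
    pairs <- list(...)
    f <- file.path(directory, name)
    utils::write.csv(data.frame(variable = names(pairs),
                                value = unlist(pairs)),
                     f, row.names = FALSE, quote = FALSE)
    f
  }
  written <- c(
    written,
    kv("soil.csv", soil_name = "Loamy sand4"),
    kv("treatment.csv", weather = "weather_{region}.csv", co2 = 400,
       sowing_date = "FD", cycle_cap = 200),
    kv("observation.csv", lai = 1.8, fsolar_obs = 0.70,
       biomass_per_plant = 40, harvest_index = 0.3,
       initial_fsolar = 0.01, fsolar_max = 0.94),
    kv("species.csv", tbase = 10, topt = 26, maxt = 35, extremet = 40,
       co2rue = 0.09, s_water = 0)
  )
  cf <- file.path(directory, "cultivar.csv")
  utils::write.csv(data.frame(cultivar = c("ICS95", "CCN51"),
                              i50a = 680, i50b = 680),
                   cf, row.names = FALSE, quote = FALSE)
  rf <- file.path(directory, "region.csv")
  utils::write.csv(reg_tab[reg_tab$region %in% regions, ],
                   rf, row.names = FALSE, quote = FALSE)
  written <- c(written, cf, rf)
  invisible(written)
}

#' Read the weather series of a fixture directory
#'
#' @param directory fixture directory written by [make_fixtures()].
#' @param region region name.
#' @return A `weather_series`.
#' @export
read_fixture_weather <- function(directory, region) {
  read_power_weather(
    file.path(directory, paste0("weather_", tolower(region), ".csv")),
    location = region)
}
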