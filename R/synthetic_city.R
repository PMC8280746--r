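#' Baseline age-specific mortality schedule
#'
#' Gompertz-Makeham hazard evaluated at band midpoints,
#' `M(x) = c + A exp(B x)`, with an added infant-band excess.  The
#' constants (`A = 6.377e-5`, `B = 0.09`, `c = 4e-4`, infant excess
#' `8e-4`) are calibrated so that the baseline city-level life expectancy
#' at birth is 73.0 years, the order of magnitude of a large US city with
#' marked health inequities; the implied crude death rate is about 10.6
#' per 1,000.
#'
#' @param schema An [age_band_schema()].
#' @return Numeric vector of central death rates, one per band.
#' @export
baseline_hazard <- function(schema = age_band_schema()) {
  k <- n_bands(schema)
  mid <- ifelse(is.finite(schema$width),
                schema$lower + schema$width / 2,
                schema$lower + 2.5)
  M <- 4e-4 + 6.377e-5 * exp(0.09 * mid)
  M[1L] <- M[1L] + 8e-4
  M
}

# plausible urban age structure: proportion of residents per 5-year band
default_age_structure <- function() {
  p <- c(0.065, 0.065, 0.065, 0.070, 0.080, 0.080, 0.075, 0.070, 0.065,
         0.065, 0.065, 0.060, 0.055, 0.045, 0.030, 0.020, 0.015, 0.010)
  p / sum(p)
}

#' Configuration for the synthetic city generator
#'
#' Defaults emulate the structure of a mid-sized US city's neighborhood
#' vital statistics: 55 geounits of 5,000-20,000 residents, five calendar
#' years, 5-year age bands to 85+, and a cause mix in which the leading
#' cause (heart disease) accounts for about 24% of deaths.  Geounit
#' mortality heterogeneity enters as a multiplicative rate factor driven
#' by geounit covariates (racial composition, median income, educational
#' attainment) plus log-normal noise, giving roughly a 15-year spread in
#' true life expectancy across geounits.
#'
#' @param n_geounits Number of geographic units (default 55).
#' @param pop_range Total residents per geounit, drawn uniformly
#'   (default 5,000-20,000).
#' @param years Calendar years (default 2012-2016).
#' @param schema An [age_band_schema()].
#' @param cause_shares Named shares of deaths by cause; must sum to < 1,
#'   the remainder going to `"other"`.  Default: heart_disease 0.244,
#'   cancer 0.213, stroke 0.049, injury 0.080.
#' @param dispersion Negative binomial size parameter for cell death
#'   counts (default 10; larger = closer to Poisson).
#' @param sigma Standard deviation of residual log-normal geounit rate
#'   noise (default 0.10).
#' @param coef_black,coef_income,coef_educ Covariate effects on log rate
#'   multiplier: per unit proportion Black (centred at 0.5), per SD of
#'   log median income, per SD of education proportion.
#' @param age_structure Proportion of residents per band.
#' @param seed Root seed; generation is fully deterministic given it.
#' @return A `city_config` list.
#' @export
city_config <- function(n_geounits = 55L, pop_range = c(5000, 20000),
                        years = 2012:2016, schema = age_band_schema(),
                        cause_shares = c(heart_disease = 0.244,
                                         cancer = 0.213,
                                         stroke = 0.049,
                                         injury = 0.080),
                        dispersion = 10, sigma = 0.08,
                        coef_black = 0.40, coef_income = -0.10,
                        coef_educ = -0.06,
                        age_structure = default_age_structure(),
                        seed = 42L) {
  if (sum(cause_shares) >= 1)
    stop("cause shares must sum to < 1 (remainder is 'other')")
  if (any(cause_shares < 0)) stop("cause shares must be non-negative")
  if (length(age_structure) != n_bands(schema))
    stop("age_structure must have one entry per band")
  structure(
    list(n_geounits = as.integer(n_geounits), pop_range = pop_range,
         years = as.integer(years), schema = schema,
         cause_shares = cause_shares, dispersion = dispersion,
         sigma = sigma, coef_black = coef_black,
         coef_income = coef_income, coef_educ = coef_educ,
         age_structure = age_structure / sum(age_structure),
         seed = as.integer(seed)),
    class = "city_config"
  )
}

#' Generate a synthetic city with known ground truth
#'
#' Per geounit: draws demographic covariates, derives a multiplicative
#' all-cause rate factor
#' `log m_g = coef_black (propBlack - 0.5) + coef_income z_income +`
#' `coef_educ z_educ + sigma eps`, splits the baseline hazard into causes
#' by the configured shares (constant across bands), draws death counts
#' per (year, band, cause) from a negative binomial around
#' `population x rate`, and expands counts to individual records with
#' uniformly drawn integer ages within bands.  The returned ground truth
#' (true per-geounit rate schedules and life expectancies) backs the
#' package's parameter-recovery tests.
#'
#' @param config A [city_config()].
#' @return A `synthetic_city` list: `records` (`death_records`),
#'   `population` (`population_table`), `covariates` (geounit-level),
#'   `truth` (list with `rates` bands x geounits matrix, `e0` per
#'   geounit, `multiplier`), and `config`.
#' @export
generate_city <- function(config = city_config()) {
  schema <- config$schema
  k <- n_bands(schema)
  geos <- sprintf("G%02d", seq_len(config$n_geounits))
  shares <- c(config$cause_shares, other = 1 - sum(config$cause_shares))
  M0 <- baseline_hazard(schema)
  with_seed(config$seed, {
    income <- stats::rlnorm(config$n_geounits, log(52000), 0.35)
    z_inc <- (log(income) - log(52000)) / 0.35
    educ <- stats::plogis(stats::qlogis(0.55) + 0.5 * z_inc +
                            stats::rnorm(config$n_geounits, 0, 0.3))
    prop_black <- stats::runif(config$n_geounits, 0.05, 0.95)
    prop_white <- (1 - prop_black) * stats::runif(config$n_geounits,
                                                  0.70, 0.95)
    z_educ <- (educ - 0.55) / 0.12
    logm <- config$coef_black * (prop_black - 0.5) +
      config$coef_income * z_inc + config$coef_educ * z_educ +
      stats::rnorm(config$n_geounits, 0, config$sigma)
    mult <- exp(logm)
    totals <- round(stats::runif(config$n_geounits, config$pop_range[1L],
                                 config$pop_range[2L]))
    pop_band <- vapply(totals, function(tot)
      round(tot * config$age_structure), numeric(k))   # k x n_geo
    covariates <- data.frame(
      geounit = geos, prop_black = prop_black, prop_white = prop_white,
      median_income = income, prop_above_hs = educ,
      stringsAsFactors = FALSE
    )
    true_rates <- outer(M0, mult)                      # k x n_geo
    dimnames(true_rates) <- list(schema$labels, geos)
    rec_list <- list()
    for (g in seq_along(geos)) {
      for (y in config$years) {
        for (b in seq_len(k)) {
          mu_all <- pop_band[b, g] * true_rates[b, g]
          for (cz in names(shares)) {
            mu <- mu_all * shares[[cz]]
            if (mu <= 0) next
            cnt <- stats::rnbinom(1L, size = config$dispersion, mu = mu)
            if (cnt == 0L) next
            ages <- sample(band_ages(schema, b), cnt, replace = TRUE)
            rec_list[[length(rec_list) + 1L]] <- data.frame(
              geounit = geos[g], year = y, age = ages, cause = cz,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    records <- do.call(rbind, rec_list)
    records$sex <- sample(c("F", "M"), nrow(records), replace = TRUE)
    records$age <- as.integer(records$age)
    records$pseudo <- FALSE
    records <- as_death_records(records, schema)
    population <- do.call(rbind, lapply(seq_along(geos), function(g) {
      expand.grid(geounit = geos[g], year = config$years,
                  band = schema$labels, KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)
    }))
    population$population <-
      pop_band[cbind(band_of_label(schema, population$band),
                     match(population$geounit, geos))]
    population <- structure(population, schema = schema,
                            class = c("population_table", "data.frame"))
    e0 <- apply(true_rates, 2L, function(M)
      life_expectancy_at_birth(build_chiang_table(M, schema)))
    structure(
      list(records = records, population = population,
           covariates = covariates,
           truth = list(rates = true_rates, e0 = e0, multiplier = mult,
                        baseline = M0, cause_shares = shares),
           config = config),
      class = "synthetic_city"
    )
  })
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("synthetic_city:", x$config$n_geounits, "geounits,",
      nrow(x$records), "death records,",
      length(x$config$years), "years; true e0 range",
      paste(sprintf("%.1f", range(x$truth$e0)), collapse = "-"), "\n")
  invisible(x)
}

#' Export a synthetic city to CSV files
#'
#' Writes the individual deaths, an aggregate death table, the population
#' table and the covariates in the package's CSV dialects, so that
#' reading them back reproduces the city's counts exactly.
#'
#' @param city A `synthetic_city`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
export_city <- function(city, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    deaths = file.path(dir, "deaths_individual.csv"),
    aggregate = file.path(dir, "deaths_aggregate.csv"),
    population = file.path(dir, "population.csv"),
    covariates = file.path(dir, "covariates.csv")
  )
  write_individual_deaths(city$records, paths[["deaths"]])
  write_aggregate_deaths(
    aggregate_individual(city$records, city$config$schema),
    paths[["aggregate"]])
  write_population(city$population, paths[["population"]])
  write_covariates(city$covariates, paths[["covariates"]])
  invisible(paths)
}

#' Bundle a synthetic city for analysis
#'
#' Convenience wrapper building a [make_bundle()] straight from a
#' generated city.
#'
#' @param city A `synthetic_city`.
#' @return A `city_bundle`.
#' @export
city_bundle <- function(city) {
  make_bundle(city$records, city$population, city$covariates,
              city$config$schema, city$config$years)
}
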