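#' Pooled central death rates by age band
#'
#' Computes all-cause central death rates M_x for one geounit by pooling
#' deaths and person-years over a multi-year observation window:
#' `M_x = sum_years D_x / sum_years P_x`.  Pooling over the window (rather
#' than averaging per-year tables) is the default behaviour throughout the
#' package; per-year rates for the simulation are built with
#' [rate_matrix()].
#'
#' @param deaths A `death_table` for one geounit (all causes; any `cause`
#'   column is summed over).
#' @param population A `population_table` for the same geounit.
#' @param geounit Geounit id to select (required if tables hold several).
#' @param years Integer vector of calendar years to pool (default: all
#'   years present in `population`).
#' @param schema An [age_band_schema()].
#' @return A data frame with one row per band: `band`, `deaths`,
#'   `person_years`, `M`.  A band with deaths but zero person-years is an
#'   error naming the cell.
#' @export
compute_rates <- function(deaths, population, geounit = NULL, years = NULL,
                          schema = attr(population, "schema")) {
  if (is.null(schema)) schema <- age_band_schema()
  if (!is.null(geounit)) {
    deaths <- deaths[deaths$geounit == geounit, , drop = FALSE]
    population <- population[population$geounit == geounit, , drop = FALSE]
  }
  if (is.null(years)) years <- sort(unique(population$year))
  deaths <- deaths[deaths$year %in% years, , drop = FALSE]
  population <- population[population$year %in% years, , drop = FALSE]
  k <- n_bands(schema)
  tally <- function(values, idx) {
    out <- numeric(k)
    if (length(values)) {
      s <- rowsum(values, idx)
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  D <- tally(deaths$deaths, band_of_label(schema, deaths$band))
  P <- tally(population$population,
             band_of_label(schema, population$band))
  bad <- which(D > 0 & P == 0)
  if (length(bad))
    stop("rate undefined (deaths > 0 with zero population) in band ",
         paste(schema$labels[bad], collapse = ", "),
         if (!is.null(geounit)) paste0(" of geounit ", geounit))
  M <- ifelse(P > 0, D / P, 0)
  data.frame(band = schema$labels, deaths = D, person_years = P, M = M,
             stringsAsFactors = FALSE)
}

#' Per-year central death-rate matrix
#'
#' All-cause M for each (band, year), used as the peer mortality the
#' lives-saved simulation applies to survivors in follow-up years.
#'
#' @inheritParams compute_rates
#' @return A numeric matrix, bands x years, with year columns.
#' @export
rate_matrix <- function(deaths, population, geounit = NULL, years = NULL,
                        schema = attr(population, "schema")) {
  if (is.null(schema)) schema <- age_band_schema()
  if (!is.null(geounit)) {
    deaths <- deaths[deaths$geounit == geounit, , drop = FALSE]
    population <- population[population$geounit == geounit, , drop = FALSE]
  }
  if (is.null(years)) years <- sort(unique(population$year))
  k <- n_bands(schema)
  M <- matrix(0, k, length(years), dimnames = list(schema$labels, years))
  for (j in seq_along(years)) {
    r <- compute_rates(deaths, population, years = years[j], schema = schema)
    M[, j] <- r$M
  }
  M
}

# default a_x: fraction of the interval lived by those dying in it.
# 0.5 for 5-year bands; conventional infant adjustment when the schema
# separates <1 (a=0.1) and 1-4 (a=0.4).
default_ax <- function(schema) {
  k <- n_bands(schema)
  a <- rep(0.5, k)
  if (k >= 2L && schema$lower[2L] == 1L) {
    a[1L] <- 0.1
    if (k >= 3L && schema$lower[2L] == 1L && schema$lower[3L] == 5L)
      a[2L] <- 0.4
  }
  a
}

#' Build an abridged life table (Chiang method)
#'
#' Converts central death rates M_x on the schema's age bands into a full
#' abridged period life table.  For closed bands the conditional
#' probability of death is
#' `q_x = n_x M_x / (1 + n_x (1 - a_x) M_x)`; the terminal band has
#' `q = 1` and person-years `L = l / M`.  Survivorship starts from a radix
#' of 100,000; `T_x` is the reverse cumulative sum of `L_x` and
#' `e_x = T_x / l_x`.
#'
#' @param M Numeric vector of central death rates, one per band.
#' @param schema An [age_band_schema()].
#' @param a Optional per-band fractions of interval lived by decedents;
#'   defaults to 0.5 per band, with the conventional infant adjustment
#'   (a=0.1 for a `<1` band, 0.4 for `1-4`) when the schema has one.
#' @param radix Survivors at age 0 (default 100,000; `e_x` is invariant to
#'   this choice).
#' @return An `abridged_life_table` data frame with columns
#'   `band, n, a, M, q, l, d, L, T, e`.
#' @examples
#' lt <- build_chiang_table(c(rep(0, 17), 0.1))
#' life_expectancy_at_birth(lt)  # 95: survive to 85, then live 1/0.1 years
#' @export
build_chiang_table <- function(M, schema = age_band_schema(), a = NULL,
                               radix = 1e5) {
  k <- n_bands(schema)
  if (length(M) != k) stop("M must have one rate per band")
  if (any(M < 0)) stop("negative central death rate")
  if (M[k] <= 0)
    stop("open-interval rate zero: terminal band needs M > 0 ",
         "(small-cell smoothing upstream should prevent this)")
  if (is.null(a)) a <- default_ax(schema)
  if (length(a) == 1L) a <- rep(a, k)
  n <- schema$width
  q <- numeric(k)
  if (k > 1L) {
    cl <- seq_len(k - 1L)
    q[cl] <- n[cl] * M[cl] / (1 + n[cl] * (1 - a[cl]) * M[cl])
    q[cl] <- pmin(q[cl], 1)
  }
  q[k] <- 1
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- numeric(k)
  if (k > 1L) {
    cl <- seq_len(k - 1L)
    L[cl] <- n[cl] * (l[cl + 1L] + a[cl] * d[cl])
  }
  L[k] <- l[k] / M[k]
  TT <- rev(cumsum(rev(L)))
  e <- TT / l
  structure(
    data.frame(band = schema$labels, n = n, a = a, M = M, q = q, l = l,
               d = d, L = L, T = TT, e = e, stringsAsFactors = FALSE),
    schema = schema,
    class = c("abridged_life_table", "data.frame")
  )
}

#' Life expectancy at birth from an abridged life table
#'
#' @param table An `abridged_life_table` from [build_chiang_table()].
#' @return `e_0 = T_0 / l_0`, in years.
#' @export
life_expectancy_at_birth <- function(table) {
  stopifnot(inherits(table, "abridged_life_table"))
  table$e[1L]
}

#' @rdname writers
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.abridged_life_table <- function(x, digits = 4, ...) {
  cat("Abridged life table (Chiang), e0 =",
      format(x$e[1L], digits = 6), "years\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
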