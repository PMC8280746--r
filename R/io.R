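#' Read individual-level death records
#'
#' Reads a CSV of de-identified decedent records (one row per death) with
#' columns for calendar year, age at death in completed years, cause-group
#' code, and geographic unit, plus optional sex and race.  Rows with a
#' missing geounit or cause are dropped and tallied in the validation
#' report attached to the result; non-numeric or fractional ages are
#' row-level errors collected the same way.
#'
#' @param path Path to a UTF-8, comma-delimited, headered CSV.
#' @param schema An [age_band_schema()]; ages must map into it.
#' @param columns Named character vector mapping the canonical names
#'   (`year`, `age`, `cause`, `geounit`, `sex`, `race`) to the file's
#'   column names.  Defaults to identity.
#' @param years Optional integer vector: the observation window.  Records
#'   outside it are dropped with a report entry.
#' @param causes Optional character vector of admissible cause codes;
#'   records with other codes are dropped with a report entry.
#' @param age_policy How to treat ages above `max_age` or missing:
#'   `"drop"` (default) or `"clamp"` (to `max_age`).
#' @param max_age Upper admissible age, default 110.
#' @return A `death_records` data frame with columns `geounit`, `year`,
#'   `age`, `cause` (plus `sex`/`race` when present) and a logical
#'   `pseudo` column (all `FALSE` here).  The validation report is in
#'   `attr(x, "report")`: a list with `n_read`, `n_kept`, `n_dropped`
#'   and an `issues` data frame (`row`, `issue`).
#' @export
read_individual_deaths <- function(path, schema = age_band_schema(),
                                   columns = NULL, years = NULL,
                                   causes = NULL,
                                   age_policy = c("drop", "clamp"),
                                   max_age = 110L) {
  age_policy <- match.arg(age_policy)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cmap <- c(year = "year", age = "age", cause = "cause", geounit = "geounit",
            sex = "sex", race = "race")
  if (!is.null(columns)) cmap[names(columns)] <- columns
  for (req in c("year", "age", "cause", "geounit")) {
    if (!cmap[[req]] %in% names(raw))
      stop("missing required column: ", cmap[[req]])
  }
  df <- data.frame(
    geounit = as.character(raw[[cmap[["geounit"]]]]),
    year = suppressWarnings(as.integer(raw[[cmap[["year"]]]])),
    age = suppressWarnings(as.numeric(raw[[cmap[["age"]]]])),
    cause = as.character(raw[[cmap[["cause"]]]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("sex", "race")) {
    if (cmap[[opt]] %in% names(raw))
      df[[opt]] <- as.character(raw[[cmap[[opt]]]])
  }
  n_read <- nrow(df)
  issues <- list()
  note <- function(rows, what) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(row = rows, issue = what)
  }
  bad_geo <- which(is.na(df$geounit) | df$geounit == "")
  note(bad_geo, "missing geounit")
  bad_cause <- which(is.na(df$cause) | df$cause == "")
  note(bad_cause, "missing cause")
  bad_age <- which(is.na(df$age) | df$age < 0 | df$age != floor(df$age))
  note(bad_age, "invalid age")
  over_age <- setdiff(which(!is.na(df$age) & df$age > max_age), bad_age)
  if (age_policy == "clamp") {
    df$age[over_age] <- max_age
    over_age <- integer(0)
  } else {
    note(over_age, "age above maximum")
  }
  drop <- unique(c(bad_geo, bad_cause, bad_age, over_age))
  if (!is.null(years)) {
    bad_year <- setdiff(which(is.na(df$year) | !(df$year %in% years)), drop)
    note(bad_year, "year outside observation window")
    drop <- c(drop, bad_year)
  } else {
    bad_year <- setdiff(which(is.na(df$year)), drop)
    note(bad_year, "missing year")
    drop <- c(drop, bad_year)
  }
  if (!is.null(causes)) {
    bad_code <- setdiff(which(!(df$cause %in% causes)), drop)
    note(bad_code, "cause not in configured cause list")
    drop <- c(drop, bad_code)
  }
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df$age <- as.integer(df$age)
  df$pseudo <- FALSE
  rownames(df) <- NULL
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(row = integer(0), issue = character(0))
  structure(df,
            report = list(n_read = n_read, n_kept = nrow(df),
                          n_dropped = n_read - nrow(df), issues = issues),
            schema = schema,
            class = c("death_records", "data.frame"))
}

#' Validation report of a reader result
#' @param x A result of one of the `read_*` functions.
#' @return The attached report list, or `NULL`.
#' @export
validation_report <- function(x) attr(x, "report")

as_death_records <- function(df, schema) {
  df$pseudo <- df$pseudo %||% FALSE
  structure(as.data.frame(df),
            schema = schema,
            class = c("death_records", "data.frame"))
}

#' Aggregate individual death records into band-level counts
#'
#' Bins records by geounit, calendar year, age band, and cause (optionally
#' sex and race), producing one row per non-empty cell.  The total count is
#' conserved: the cell counts sum to the number of records.
#'
#' @param records A `death_records` data frame.
#' @param schema An [age_band_schema()].
#' @param by_sex,by_race Include the stratum in the cell key.
#' @return A `death_table` data frame with columns `geounit`, `year`,
#'   `band` (label), `cause`, optional `sex`/`race`, and integer `deaths`.
#' @export
aggregate_individual <- function(records, schema = attr(records, "schema"),
                                 by_sex = FALSE, by_race = FALSE) {
  if (is.null(schema)) schema <- age_band_schema()
  keys <- list(
    geounit = records$geounit,
    year = records$year,
    band = schema$labels[band_of_age(schema, records$age)],
    cause = records$cause
  )
  if (by_sex) keys$sex <- records$sex
  if (by_race) keys$race <- records$race
  if (nrow(records) == 0L) {
    out <- data.frame(geounit = character(0), year = integer(0),
                      band = character(0), cause = character(0),
                      deaths = integer(0))
    if (by_sex) out$sex <- character(0)
    if (by_race) out$race <- character(0)
    return(structure(out, schema = schema,
                     class = c("death_table", "data.frame")))
  }
  tab <- stats::aggregate(list(deaths = rep(1L, nrow(records))),
                          by = keys, FUN = sum)
  tab <- tab[do.call(order, tab[setdiff(names(tab), "deaths")]), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab$deaths <- as.integer(tab$deaths)
  structure(tab, schema = schema, class = c("death_table", "data.frame"))
}

#' Expand aggregate death counts into pseudo-individual records
#'
#' Inverts [aggregate_individual()] on counts: each counted death becomes a
#' pseudo-record whose integer age is spread uniformly across the band's
#' single-year ages.  A cell of k deaths over a width-w band assigns
#' `floor(k/w)` deaths to every single-year age deterministically; the
#' remaining `k mod w` deaths are placed on ages drawn without replacement
#' under the given seed.  The open terminal band uses the schema's
#' `open_span` single-year ages (default 85-89).  Stratified cells (sex,
#' race) expand independently, so stratum totals are preserved exactly and
#' within each stratum ages are again uniform.  Re-aggregating the result
#' returns the input table exactly.
#'
#' @param table A `death_table` data frame (cells with non-negative counts).
#' @param seed Integer seed controlling remainder placement; the same seed
#'   yields an identical record set.
#' @param schema An [age_band_schema()].
#' @return A `death_records` data frame with `pseudo = TRUE`.
#' @export
make_pseudo_individuals <- function(table, seed = 1L,
                                    schema = attr(table, "schema")) {
  if (is.null(schema)) schema <- age_band_schema()
  if (any(table$deaths < 0)) stop("negative death count in aggregate table")
  tab <- table[table$deaths > 0, , drop = FALSE]
  bidx <- band_of_label(schema, tab$band)
  has_sex <- "sex" %in% names(tab)
  has_race <- "race" %in% names(tab)
  with_seed(seed, {
    rows <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      k <- tab$deaths[i]
      ages <- band_ages(schema, bidx[i])
      w <- length(ages)
      base <- rep(ages, k %/% w)
      r <- k %% w
      extra <- if (r > 0L) sort(sample(ages, r)) else integer(0)
      rec <- data.frame(
        geounit = tab$geounit[i], year = tab$year[i],
        age = c(base, extra), cause = tab$cause[i],
        stringsAsFactors = FALSE
      )
      if (has_sex) rec$sex <- tab$sex[i]
      if (has_race) rec$race <- tab$race[i]
      rows[[i]] <- rec
    }
    out <- if (length(rows)) {
      o <- do.call(rbind, rows)
      o$age <- as.integer(o$age)
      o$pseudo <- TRUE
      o
    } else {
      data.frame(geounit = character(0), year = integer(0),
                 age = integer(0), cause = character(0),
                 pseudo = logical(0))
    }
    rownames(out) <- NULL
    as_death_records(out, schema)
  })
}

# shared CSV table reader with duplicate-key detection
read_keyed_csv <- function(path, required, key_cols, value_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column: ", paste(miss, collapse = ", "))
  key_cols <- intersect(c(key_cols, c("sex", "race")), names(df))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), key_cols, drop = FALSE][1L, , drop = FALSE]
    stop("duplicated key in ", basename(path), ": ",
         paste(names(dup), unlist(dup), sep = "=", collapse = ", "))
  }
  df
}

#' Read an aggregate death table CSV
#'
#' Columns: `geounit,year,age_band,cause[,sex,race],deaths` with bands
#' encoded `"0-4"`, ..., `"85+"`.  Duplicate cell keys are an error.
#'
#' @inheritParams read_individual_deaths
#' @return A `death_table` data frame (see [aggregate_individual()]).
#' @export
read_aggregate_deaths <- function(path, schema = age_band_schema()) {
  df <- read_keyed_csv(path,
                       required = c("geounit", "year", "age_band",
                                    "cause", "deaths"),
                       key_cols = c("geounit", "year", "age_band", "cause"))
  band_of_label(schema, df$age_band)   # validates labels
  out <- data.frame(geounit = as.character(df$geounit),
                    year = as.integer(df$year),
                    band = as.character(df$age_band),
                    cause = as.character(df$cause),
                    stringsAsFactors = FALSE)
  for (opt in c("sex", "race"))
    if (opt %in% names(df)) out[[opt]] <- as.character(df[[opt]])
  out$deaths <- as.integer(df$deaths)
  if (any(is.na(out$deaths)) || any(out$deaths < 0))
    stop("death counts must be non-negative integers")
  structure(out, schema = schema, class = c("death_table", "data.frame"))
}

#' Read a population table CSV
#'
#' Columns: `geounit,year,age_band[,sex,race],population`.
#'
#' @inheritParams read_individual_deaths
#' @return A `population_table` data frame with columns `geounit`, `year`,
#'   `band`, optional strata, and numeric `population`.
#' @export
read_population <- function(path, schema = age_band_schema()) {
  df <- read_keyed_csv(path,
                       required = c("geounit", "year", "age_band",
                                    "population"),
                       key_cols = c("geounit", "year", "age_band"))
  band_of_label(schema, df$age_band)
  out <- data.frame(geounit = as.character(df$geounit),
                    year = as.integer(df$year),
                    band = as.character(df$age_band),
                    stringsAsFactors = FALSE)
  for (opt in c("sex", "race"))
    if (opt %in% names(df)) out[[opt]] <- as.character(df[[opt]])
  out$population <- as.numeric(df$population)
  if (any(is.na(out$population)) || any(out$population < 0))
    stop("population must be non-negative")
  structure(out, schema = schema,
            class = c("population_table", "data.frame"))
}

#' Read geounit-level covariates CSV
#'
#' Columns: `geounit,prop_black,prop_white,median_income,prop_above_hs`.
#' Proportions must lie in `[0, 1]`.
#'
#' @param path CSV path.
#' @return A data frame, one row per geounit.
#' @export
read_covariates <- function(path) {
  df <- read_keyed_csv(path,
                       required = c("geounit", "prop_black", "prop_white",
                                    "median_income", "prop_above_hs"),
                       key_cols = "geounit")
  df$geounit <- as.character(df$geounit)
  for (p in c("prop_black", "prop_white", "prop_above_hs")) {
    if (any(df[[p]] < 0 | df[[p]] > 1))
      stop(p, " must lie in [0, 1]")
  }
  df
}

#' Writers for the package's CSV dialects
#'
#' Emit the same comma-delimited, headered, UTF-8 files the readers accept,
#' so that export followed by import is the identity on counts.
#'
#' @param records,table,population,covariates Objects to write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_individual_deaths <- function(records, path) {
  cols <- intersect(c("year", "age", "cause", "geounit", "sex", "race"),
                    names(records))
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writers
#' @export
write_aggregate_deaths <- function(table, path) {
  df <- as.data.frame(table)
  names(df)[names(df) == "band"] <- "age_band"
  cols <- intersect(c("geounit", "year", "age_band", "cause", "sex", "race",
                      "deaths"), names(df))
  utils::write.csv(df[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writers
#' @export
write_population <- function(population, path) {
  df <- as.data.frame(population)
  names(df)[names(df) == "band"] <- "age_band"
  cols <- intersect(c("geounit", "year", "age_band", "sex", "race",
                      "population"), names(df))
  utils::write.csv(df[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writers
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(as.data.frame(covariates), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
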