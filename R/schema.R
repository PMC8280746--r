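#' Age-band schema for abridged life tables
#'
#' Defines the ordered, contiguous age bands on which deaths and population
#' are tabulated.  Bands start at age 0, are non-overlapping, and end with a
#' single open-ended terminal band.  The default is the conventional abridged
#' schema 0-4, 5-9, ..., 80-84, 85+ (width 5).
#'
#' @param lower Integer vector of band lower bounds, starting at 0 and
#'   strictly increasing.  The last bound opens the terminal band.
#' @param open_span Width in years used when an integer age must be imputed
#'   inside the open terminal band (e.g. when expanding aggregate counts to
#'   pseudo-individuals).  Default 5, mirroring the closed bands.
#' @return An object of class `age_band_schema`: a list with elements
#'   `lower`, `upper` (terminal `Inf`), `width` (terminal `Inf`), `labels`
#'   (e.g. `"0-4"`, `"85+"`), and `open_span`.
#' @examples
#' sch <- age_band_schema()
#' sch$labels[c(1, 18)]
#' @export
age_band_schema <- function(lower = seq(0L, 85L, by = 5L), open_span = 5L) {
  lower <- as.integer(lower)
  if (length(lower) < 1L || lower[1L] != 0L)
    stop("age bands must start at 0")
  if (is.unsorted(lower, strictly = TRUE))
    stop("band lower bounds must be strictly increasing")
  k <- length(lower)
  upper <- c(lower[-1L] - 1L, Inf)
  width <- c(diff(lower), Inf)
  labels <- c(
    if (k > 1L) paste0(lower[-k], "-", upper[-k]),
    paste0(lower[k], "+")
  )
  structure(
    list(lower = lower, upper = upper, width = width, labels = labels,
         open_span = as.integer(open_span)),
    class = "age_band_schema"
  )
}

#' @export
print.age_band_schema <- function(x, ...) {
  cat("Age-band schema:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname age_band_schema
#' @param x Object to test.
#' @export
is_age_band_schema <- function(x) inherits(x, "age_band_schema")

n_bands <- function(schema) length(schema$lower)

#' Map integer ages to band indices
#'
#' @param schema An [age_band_schema()].
#' @param age Integer ages (completed years).
#' @return Integer band indices (1-based).  Ages beyond the terminal bound
#'   fall in the terminal band; negative ages are an error.
#' @export
band_of_age <- function(schema, age) {
  if (any(age < 0, na.rm = TRUE)) stop("negative age")
  findInterval(age, schema$lower)
}

#' Parse age-band labels ("0-4", "85+") to band indices
#'
#' @param schema An [age_band_schema()].
#' @param labels Character labels as written by this package's CSV writers.
#' @return Integer band indices; unknown labels raise an error naming them.
#' @export
band_of_label <- function(schema, labels) {
  idx <- match(labels, schema$labels)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown age band label(s): ", paste(bad, collapse = ", "))
  }
  idx
}

# integer ages available for imputation within a band (terminal band uses
# open_span single-year ages)
band_ages <- function(schema, band) {
  lo <- schema$lower[band]
  w <- schema$width[band]
  if (!is.finite(w)) w <- schema$open_span
  lo:(lo + w - 1L)
}
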