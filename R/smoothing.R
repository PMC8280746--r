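#' Per-cell covariates for small-cell smoothing
#'
#' Builds the design table on which the smoothing regression is fitted:
#' one row per (geounit, age band), holding the age at the start of the
#' interval, the mean annual age-specific population, and the geounit's
#' demographic covariates (proportion non-Hispanic Black, proportion
#' non-Hispanic white, median household income, proportion with
#' educational attainment above high school).
#'
#' @param population A `population_table` (all geounits).
#' @param covariates Geounit-level covariates as from [read_covariates()].
#' @param schema An [age_band_schema()].
#' @param years Years to average population over (default: all present).
#' @return A data frame with columns `geounit`, `band`, `age_start`,
#'   `population`, `prop_black`, `prop_white`, `median_income`,
#'   `prop_above_hs`.
#' @export
cell_covariates <- function(population, covariates,
                            schema = attr(population, "schema"),
                            years = NULL) {
  if (is.null(schema)) schema <- age_band_schema()
  if (is.null(years)) years <- sort(unique(population$year))
  pop <- population[population$year %in% years, , drop = FALSE]
  geos <- sort(unique(pop$geounit))
  k <- n_bands(schema)
  grid <- expand.grid(band_idx = seq_len(k), geounit = geos,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(pop$geounit, band_of_label(schema, pop$band))
  psum <- rowsum(pop$population, key)
  grid$population <- as.numeric(
    psum[match(paste(grid$geounit, grid$band_idx), rownames(psum))]
  ) / length(years)
  grid$population[is.na(grid$population)] <- 0
  out <- data.frame(
    geounit = grid$geounit,
    band = schema$labels[grid$band_idx],
    age_start = schema$lower[grid$band_idx],
    population = grid$population,
    stringsAsFactors = FALSE
  )
  m <- match(out$geounit, covariates$geounit)
  if (anyNA(m))
    stop("covariates missing for geounit(s): ",
         paste(unique(out$geounit[is.na(m)]), collapse = ", "))
  for (v in c("prop_black", "prop_white", "median_income", "prop_above_hs"))
    out[[v]] <- covariates[[v]][m]
  out
}

smoothing_covars <- c("age_start", "population", "prop_black", "prop_white",
                      "median_income", "prop_above_hs")

#' Fit the small-cell smoothing regression
#'
#' Maximum-likelihood negative binomial regression (log link) of
#' cause-specific death counts per (geounit, age band) cell on six
#' cell-level covariates: age at interval start, age-specific population,
#' proportion Black, proportion white, median household income, and
#' proportion with education above high school.  One model is fitted per
#' cause, pooled across all geounits and bands.  Predictors are centred
#' and scaled internally for numerical stability; reported coefficients
#' are back-transformed to the raw covariate scale.  If the negative
#' binomial dispersion estimate degenerates (or the fit fails), the model
#' falls back to Poisson and records that in the object.
#'
#' @param counts Data frame with columns `geounit`, `band`, `count`:
#'   cause-specific deaths per cell, pooled over the observation window.
#' @param covariates Output of [cell_covariates()] covering every cell.
#' @param offset_population If `TRUE`, `log(population)` enters as an
#'   offset instead of a covariate (variant behind a flag; the default
#'   keeps population as a listed covariate).
#' @return A `smoothing_model` object: list with the fitted `glm`
#'   (`fit`), `family` (`"negbin"` or `"poisson"`), `theta` (NB size, or
#'   `Inf` under Poisson), raw-scale `coefficients` and `se`, and the
#'   centring/scaling used.
#' @export
fit_smoothing_model <- function(counts, covariates,
                                offset_population = FALSE) {
  df <- merge(counts, covariates, by = c("geounit", "band"), sort = FALSE)
  if (nrow(df) < nrow(counts))
    stop("covariates missing for some count cells")
  vars <- smoothing_covars
  if (offset_population) {
    vars <- setdiff(vars, "population")
    if (any(df$population <= 0))
      stop("population offset requires positive population in every cell")
  }
  X <- as.matrix(df[vars])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) {
    # fully degenerate design: intercept-only fit
    ctr <- ctr[0]; scl <- scl[0]
    Xs <- matrix(numeric(0), nrow(df), 0)
  } else {
    ctr <- ctr[keep]; scl <- scl[keep]
    Xs <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)
  }
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1L) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    drop_cols <- setdiff(seq_len(ncol(Xs) + 1L), piv) - 1L
    stop("singular design; collinear covariate(s): ",
         paste(colnames(Xs)[drop_cols], collapse = ", "))
  }
  dat <- data.frame(count = df$count, Xs, check.names = FALSE)
  rhs <- if (ncol(Xs) > 0L) paste(colnames(Xs), collapse = "+") else "1"
  if (offset_population) {
    dat$.off <- log(df$population)
    rhs <- paste(rhs, "+ offset(.off)")
  }
  fml <- stats::as.formula(paste("count ~", rhs))
  family <- "negbin"
  fit <- tryCatch({
    f <- withCallingHandlers(
      MASS::glm.nb(fml, data = dat, link = log,
                   control = stats::glm.control(maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!is.finite(f$theta) || f$theta <= 0) stop("degenerate dispersion")
    f
  }, error = function(e) {
    family <<- "poisson"
    message("negative binomial dispersion degenerated (",
            conditionMessage(e), "); falling back to Poisson")
    stats::glm(fml, data = dat, family = stats::poisson())
  })
  # back-transform coefficients/SEs from the standardized to the raw scale
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  p <- length(ctr)
  Tm <- diag(p + 1L)
  if (p > 0L) {
    Tm[1L, -1L] <- -ctr / scl
    diag(Tm)[-1L] <- 1 / scl
  }
  b_raw <- drop(Tm %*% b)
  V_raw <- Tm %*% V %*% t(Tm)
  names(b_raw) <- c("(Intercept)", names(ctr))
  structure(
    list(fit = fit, family = family,
         theta = if (family == "negbin") fit$theta else Inf,
         coefficients = b_raw, se = sqrt(diag(V_raw)), vcov = V_raw,
         center = ctr, scale = scl,
         offset_population = offset_population),
    class = "smoothing_model"
  )
}

#' @export
coef.smoothing_model <- function(object, ...) object$coefficients

#' @export
print.smoothing_model <- function(x, ...) {
  cat("Small-cell smoothing model (", x$family, " regression, log link)\n",
      sep = "")
  print(data.frame(estimate = x$coefficients, se = x$se))
  if (x$family == "negbin") cat("dispersion (theta):", x$theta, "\n")
  invisible(x)
}

#' Predict expected cell counts from a smoothing model
#'
#' @param object A `smoothing_model`.
#' @param newdata Data frame holding the covariate columns (and
#'   `population` if the model used an offset).
#' @param ... Unused.
#' @return Expected counts on the response scale.
#' @export
predict.smoothing_model <- function(object, newdata, ...) {
  p <- length(object$center)
  eta <- rep(object$coefficients[[1L]], nrow(newdata))
  if (p > 0L) {
    X <- as.matrix(newdata[names(object$center)])
    eta <- eta + drop(X %*% object$coefficients[-1L])
  }
  if (object$offset_population) eta <- eta + log(newdata$population)
  exp(eta)
}

#' Replace small death cells with model predictions
#'
#' Every (geounit, band) cell of the cause-specific table with fewer than
#' `threshold` deaths is replaced by the smoothing model's prediction;
#' cells at or above the threshold are untouched.  Predictions are capped:
#' when a prediction exceeds the total number of deaths from the cause in
#' that age band (study-area-wide by default), the cap value is used
#' instead.  A replacement log records every substitution.
#'
#' @param counts Data frame `geounit`, `band`, `count` (cause-specific,
#'   pooled over the window; must contain every geounit x band cell,
#'   zeros included).
#' @param model A fitted [fit_smoothing_model()].
#' @param covariates Output of [cell_covariates()].
#' @param threshold Cells with `count < threshold` are replaced
#'   (default 5; 0 makes smoothing the identity).
#' @param cap `"area"` (default) caps a prediction at the study-area-wide
#'   total of the cause in that band; `"geounit"` caps at the geounit's own
#'   observed count for the cell; `"none"` disables the cap.
#' @return A list: `smoothed` (the counts data frame with a numeric
#'   `count`, fractional where replaced) and `log` (data frame
#'   `geounit, band, observed, predicted, capped, final`).
#' @export
smooth_small_cells <- function(counts, model, covariates, threshold = 5,
                               cap = c("area", "geounit", "none")) {
  cap <- match.arg(cap)
  df <- merge(counts, covariates, by = c("geounit", "band"), sort = FALSE)
  if (nrow(df) < nrow(counts)) stop("covariates missing for some cells")
  df <- df[match(paste(counts$geounit, counts$band),
                 paste(df$geounit, df$band)), , drop = FALSE]
  pred <- predict(model, df)
  if (any(!is.finite(pred))) {
    bad <- which(!is.finite(pred))[1L]
    stop("non-finite prediction for cell geounit=", df$geounit[bad],
         " band=", df$band[bad])
  }
  band_tot <- tapply(counts$count, counts$band, sum)
  cap_val <- switch(cap,
    area = as.numeric(band_tot[df$band]),
    geounit = df$count,
    none = Inf
  )
  small <- counts$count < threshold
  final <- counts$count
  capped <- pred > cap_val
  repl <- ifelse(capped, cap_val, pred)
  final[small] <- repl[small]
  out <- counts
  out$count <- as.numeric(final)
  log <- data.frame(
    geounit = counts$geounit[small], band = counts$band[small],
    observed = counts$count[small], predicted = pred[small],
    capped = capped[small], final = final[small],
    stringsAsFactors = FALSE
  )
  rownames(log) <- NULL
  list(smoothed = out, log = log)
}
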