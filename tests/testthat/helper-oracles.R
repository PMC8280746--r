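# Independent oracles and shared fixtures.

# Agent-based cohort microsimulation of the abridged life-table model.
# Shares no arithmetic with build_chiang_table(): the band death
# probability is recovered NUMERICALLY from the person-years identity
#   M = q / (n(1-q) + a n q)
# by root finding, each closed band kills agents by Bernoulli draws (those
# dying live a*n years of the interval), and survivors of the terminal
# band live exponential(M) remaining lifetimes.  The mean simulated
# lifespan estimates e0; its Monte-Carlo standard error is returned.
microsim_e0 <- function(M, schema = age_band_schema(), a = 0.5,
                        n_agents = 1e6) {
  k <- length(M)
  if (length(a) == 1L) a <- rep(a, k)
  n <- schema$width
  # closed bands: every agent alive at the band start faces the same
  # Bernoulli death draw, so the band's death count is one binomial draw
  # over the survivors -- identical in distribution to per-agent draws --
  # and decedents live a*n years of the interval
  alive <- n_agents
  sum_t <- 0
  sum_t2 <- 0
  for (x in seq_len(k - 1L)) {
    if (alive == 0L || M[x] == 0) next
    q <- uniroot(function(q) q / (n[x] * (1 - q) + a[x] * n[x] * q) - M[x],
                 c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    d <- rbinom(1L, alive, q)
    t_die <- schema$lower[x] + a[x] * n[x]
    sum_t <- sum_t + d * t_die
    sum_t2 <- sum_t2 + d * t_die^2
    alive <- alive - d
  }
  if (alive > 0L) {
    life85 <- schema$lower[k] + rexp(alive, rate = M[k])
    sum_t <- sum_t + sum(life85)
    sum_t2 <- sum_t2 + sum(life85^2)
  }
  e0 <- sum_t / n_agents
  v <- sum_t2 / n_agents - e0^2
  c(e0 = e0, se = sqrt(v / n_agents))
}

# Human-plausible random rate schedule: perturbed Gompertz-Makeham on the
# default 18-band schema.
random_schedule <- function() {
  mid <- c(seq(0, 80, 5) + 2.5, 87.5)
  M <- 4e-4 + 6e-5 * exp(0.088 * mid) * exp(rnorm(18, 0, 0.3))
  M[1] <- M[1] + runif(1, 2e-4, 1.5e-3)
  M
}

# Random aggregate death tables for round-trip checks; about half carry a
# sex stratum.
random_death_table <- function(schema = age_band_schema()) {
  n <- sample(3:25, 1)
  tab <- data.frame(
    geounit = sample(c("A", "B", "C"), n, replace = TRUE),
    year = sample(2012:2016, n, replace = TRUE),
    band = sample(schema$labels, n, replace = TRUE),
    cause = sample(c("heart", "cancer", "other"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (runif(1) < 0.5) tab$sex <- sample(c("F", "M"), n, replace = TRUE)
  keyc <- intersect(c("geounit", "year", "band", "cause", "sex"),
                    names(tab))
  tab <- tab[!duplicated(tab[keyc]), , drop = FALSE]
  tab$deaths <- sample(0:12, nrow(tab), replace = TRUE)
  structure(tab, schema = schema, class = c("death_table", "data.frame"))
}

# Two-band toy system with hand-computable survival products: band 0-4
# plus open band 5+.  Cause decedents all aged 0-2, so nobody crosses the
# band boundary inside the window.
toy_schema <- function() age_band_schema(c(0L, 5L))

toy_system <- function(deaths_per_year = 200L, years = 2000:2002,
                       m_young = 0.05, m_old = 0.2) {
  schema <- toy_schema()
  recs <- do.call(rbind, lapply(years, function(y) {
    data.frame(geounit = "T", year = y,
               age = rep(0:2, length.out = deaths_per_year),
               cause = "target", pseudo = FALSE,
               stringsAsFactors = FALSE)
  }))
  recs <- structure(recs, schema = schema,
                    class = c("death_records", "data.frame"))
  rates <- matrix(c(rep(m_young, length(years)),
                    rep(m_old, length(years))),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(schema$labels, years))
  list(records = recs, rates = rates, schema = schema, years = years)
}

# closed-form expected net lives saved for the toy system under
# within-age reduction: agents saved in year y survive follow-up years
# independently with probability prod_{y' > y} (1 - m_young)
toy_expected_net <- function(target_per_year, years, m_young) {
  sum(vapply(seq_along(years), function(j) {
    target_per_year * prod(rep(1 - m_young, length(years) - j))
  }, numeric(1)))
}

# Simulate cell counts from a stated negative binomial model on the
# synthetic city's covariate design (55 geounits x 18 bands).
# Raw-scale coefficients; dispersion (size) 1.5.
nb_truth <- c(`(Intercept)` = 0.5, age_start = 0.035,
              population = 3e-4, prop_black = 0.5, prop_white = -0.3,
              median_income = -8e-6, prop_above_hs = -0.5)
nb_theta <- 1.5

simulate_nb_cells <- function(bundle, seed = 5) {
  covs <- cell_covariates(bundle$population, bundle$covariates,
                          bundle$schema, bundle$years)
  X <- cbind(1, as.matrix(covs[c("age_start", "population", "prop_black",
                                 "prop_white", "median_income",
                                 "prop_above_hs")]))
  mu <- exp(drop(X %*% nb_truth))
  set.seed(seed)
  counts <- data.frame(geounit = covs$geounit, band = covs$band,
                       count = rnbinom(nrow(covs), size = nb_theta,
                                       mu = mu),
                       stringsAsFactors = FALSE)
  list(counts = counts, covs = covs)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# memoised cities so several test files can share one generation
.city_cache <- new.env(parent = emptyenv())

default_city <- function() {
  if (is.null(.city_cache$default))
    .city_cache$default <- generate_city(city_config())
  .city_cache$default
}

default_bundle <- function() {
  if (is.null(.city_cache$default_bundle))
    .city_cache$default_bundle <- city_bundle(default_city())
  .city_cache$default_bundle
}

small_city <- function() {
  if (is.null(.city_cache$small))
    .city_cache$small <- generate_city(
      city_config(n_geounits = 8L, seed = 11L))
  .city_cache$small
}

small_bundle <- function() {
  if (is.null(.city_cache$small_bundle))
    .city_cache$small_bundle <- city_bundle(small_city())
  .city_cache$small_bundle
}
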