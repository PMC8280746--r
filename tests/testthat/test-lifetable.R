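test_that("pooled rates divide summed deaths by summed person-years", {
  sch <- age_band_schema()
  deaths <- structure(
    data.frame(geounit = "G1", year = c(2014L, 2015L), band = "60-64",
               cause = "all", deaths = c(1L, 1L)),
    schema = sch, class = c("death_table", "data.frame"))
  pop <- structure(
    data.frame(geounit = "G1", year = c(2014L, 2015L), band = "60-64",
               population = c(500, 500)),
    schema = sch, class = c("population_table", "data.frame"))
  r <- compute_rates(deaths, pop, geounit = "G1", schema = sch)
  expect_equal(r$M[r$band == "60-64"], 2 / 1000)
  # single-year case is the plain ratio
  r1 <- compute_rates(deaths[1, ], pop[1, ], schema = sch, years = 2014L)
  expect_equal(r1$M[r1$band == "60-64"], 0.002)
  # deaths without population are an error naming the band
  pop0 <- pop
  pop0$population <- 0
  expect_error(compute_rates(deaths, pop0, schema = sch),
               "rate undefined.*60-64")
})

test_that("single open interval gives e0 = 1/M and zero mortality delays it", {
  one_band <- age_band_schema(0L)
  lt <- build_chiang_table(0.02, schema = one_band)
  expect_equal(life_expectancy_at_birth(lt), 50)
  # no mortality below 85, then constant hazard 0.1: e0 = 85 + 10
  lt <- build_chiang_table(c(rep(0, 17), 0.1))
  expect_equal(life_expectancy_at_birth(lt), 95)
  expect_error(build_chiang_table(c(rep(0, 17), 0)), "open-interval")
  expect_error(build_chiang_table(c(rep(0.001, 17), -1)), "negative")
})

test_that("life-table identities hold and e0 is monotone in rates", {
  set.seed(4)
  for (i in 1:25) {
    M <- random_schedule()
    lt <- build_chiang_table(M)
    expect_equal(sum(lt$d), lt$l[1])           # deaths exhaust the cohort
    expect_equal(lt$T[1], sum(lt$L))
    expect_true(all(diff(lt$l) <= 0))
    expect_true(all(lt$q >= 0 & lt$q <= 1))
    expect_equal(lt$q[18], 1)
    expect_true(all(diff(lt$T) <= 0))
    e0 <- life_expectancy_at_birth(lt)
    expect_gt(e0, 0)
    expect_lt(life_expectancy_at_birth(build_chiang_table(2 * M)), e0)
  }
})

test_that("e0 is invariant to the radix", {
  M <- with_seed_test(9, random_schedule())
  e1 <- life_expectancy_at_birth(build_chiang_table(M, radix = 1e5))
  e2 <- life_expectancy_at_birth(build_chiang_table(M, radix = 1))
  expect_equal(e1, e2)
})

test_that("infant a_x adjustment activates only for a <1 band", {
  sch <- age_band_schema(c(0L, 1L, 5L, seq(10L, 85L, 5L)))
  M <- c(0.006, 0.0005, rep(0.002, 16), 0.15)
  lt <- build_chiang_table(M, schema = sch)
  expect_equal(lt$a[1:3], c(0.1, 0.4, 0.5))
  lt5 <- build_chiang_table(random_schedule())
  expect_true(all(lt5$a == 0.5))
})

test_that("Chiang e0 agrees with an agent-based cohort microsimulation", {
  set.seed(7)
  for (i in 1:4) {
    M <- random_schedule()
    sim <- microsim_e0(M, n_agents = 2e5)
    e0 <- life_expectancy_at_birth(build_chiang_table(M))
    expect_lt(abs(e0 - sim["e0"]), 3 * sim["se"])
  }
  # US-style schedule with e0 near 79 years
  mid <- c(seq(0, 80, 5) + 2.5, 87.5)
  M_us <- 1.5e-4 + 2.8e-5 * exp(0.095 * mid)
  M_us[1] <- M_us[1] + 6e-4
  e0 <- life_expectancy_at_birth(build_chiang_table(M_us))
  expect_gt(e0, 77)
  expect_lt(e0, 81)
  sim <- microsim_e0(M_us, n_agents = 1e6)
  expect_lt(abs(e0 - sim["e0"]), 0.1)
})

test_that("synthetic-city death counts match true rates within NB error", {
  city <- default_city()
  cfg <- city$config
  sch <- cfg$schema
  agg <- aggregate_individual(city$records)
  # city-wide observed deaths per band vs. the generator's expectation,
  # using the configured negative binomial variance mu + mu^2/size
  pop <- city$population[city$population$year == cfg$years[1], ]
  key <- paste(pop$geounit, pop$band)
  for (b in c("55-59", "70-74", "85+")) {
    obs <- sum(agg$deaths[agg$band == b])
    mu_g <- vapply(seq_len(cfg$n_geounits), function(g) {
      gid <- city$covariates$geounit[g]
      p <- pop$population[key == paste(gid, b)]
      p * city$truth$rates[b, gid]
    }, numeric(1))
    # one NB cell per (geounit, year, cause): mean share_c * mu_g
    mu_cells <- as.numeric(outer(city$truth$cause_shares, mu_g))
    mu_tot <- sum(mu_g) * length(cfg$years)
    var_tot <- sum(length(cfg$years) *
                     (mu_cells + mu_cells^2 / cfg$dispersion))
    expect_lt(abs(obs - mu_tot), 5 * sqrt(var_tot))
  }
})
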