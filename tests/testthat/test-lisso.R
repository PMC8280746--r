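test_that("targeted averted counts follow the two reduction modes", {
  sch <- toy_schema()
  D <- matrix(c(100L, 0L), 2, 1, dimnames = list(sch$labels, 2000))
  sc <- reduction_scenario("c", 0.20, mode = "within-age")
  expect_equal(target_averted_counts(D, sc)[, 1], c(`0-4` = 20L, `5+` = 0L))
  # overall mode with symmetric bands splits evenly
  D2 <- matrix(c(50L, 50L), 2, 1, dimnames = list(sch$labels, 2000))
  sc2 <- reduction_scenario("c", 0.20, mode = "overall")
  expect_equal(unname(target_averted_counts(D2, sc2)[, 1]), c(10L, 10L))
  # null scenario targets nothing
  sc0 <- reduction_scenario("c", 0, mode = "overall")
  expect_true(all(target_averted_counts(D2, sc0) == 0L))
})

test_that("overall-mode apportionment conserves the rounded yearly total", {
  set.seed(21)
  sch <- age_band_schema()
  for (i in 1:50) {
    D <- matrix(rpois(18 * 3, lambda = runif(1, 0.5, 8)), 18, 3,
                dimnames = list(sch$labels, 2012:2014))
    p <- sample(c(.05, .1, .15, .2), 1)
    sc <- reduction_scenario("c", p, mode = "overall")
    tg <- target_averted_counts(D, sc)
    expect_true(all(tg <= D))           # never avert more than occurred
    expect_equal(colSums(tg), round(p * colSums(D)))
    # within-age totals agree with overall totals up to the worst-case
    # sum of per-band rounding remainders
    tw <- target_averted_counts(D, reduction_scenario("c", p,
                                                      mode = "within-age"))
    nz <- colSums(D > 0)
    expect_true(all(abs(colSums(tw) - colSums(tg)) <= 0.5 * nz + 0.5))
  }
})

test_that("no attrition means every targeted life is saved", {
  sys <- toy_system(deaths_per_year = 50L, m_young = 0, m_old = 0)
  sc <- reduction_scenario("target", 0.20, mode = "within-age", seed = 3)
  rep <- run_replicate(sys$records, sys$rates, sc, sys$schema, seed = 3)
  expect_equal(sum(rep$net), sum(rep$targeted))
  expect_equal(rep$targeted[["0-4"]], 30)  # 10 per year x 3 years
  # and the expected table equals observed minus the averted deaths
  res <- run_lisso(sys$records, sys$rates,
                   reduction_scenario("target", 0.20, n_replicates = 5,
                                      seed = 3))
  expect_equal(res$expected, res$observed - res$median_net)
})

test_that("null scenario leaves the death table untouched", {
  sys <- toy_system()
  res <- run_lisso(sys$records, sys$rates,
                   reduction_scenario("target", 0, n_replicates = 5,
                                      seed = 1))
  expect_equal(res$lives_saved, 0)
  expect_equal(res$expected, res$observed)
})

test_that("net lives saved never exceed the target in any replicate", {
  sys <- toy_system(deaths_per_year = 120L, m_young = 0.1, m_old = 0.3)
  res <- run_lisso(sys$records, sys$rates,
                   reduction_scenario("target", 0.15, n_replicates = 50,
                                      seed = 8))
  tg <- res$targeted
  expect_true(all(res$net >= 0))
  expect_true(all(res$net <= tg))
  # positive peer rates over a multi-year window: attrition bites
  expect_lt(res$lives_saved, sum(tg))
})

test_that("same seed gives bit-identical results, one replicate is itself", {
  sys <- toy_system()
  sc <- reduction_scenario("target", 0.10, n_replicates = 10, seed = 77)
  a <- run_lisso(sys$records, sys$rates, sc)
  b <- run_lisso(sys$records, sys$rates, sc)
  expect_identical(a, b)
  sc1 <- reduction_scenario("target", 0.10, n_replicates = 1, seed = 5)
  r1 <- run_lisso(sys$records, sys$rates, sc1)
  single <- run_replicate(sys$records, sys$rates, sc1,
                          seed = r1$seeds[1])
  expect_equal(as.numeric(r1$net[, 1]), single$net)
})

test_that("median net lives saved matches the survival-product formula", {
  sys <- toy_system(deaths_per_year = 200L, m_young = 0.05)
  p <- 0.20
  target_py <- round(p * 200)
  expected <- toy_expected_net(target_py, sys$years, 0.05)
  sc <- reduction_scenario("target", p, mode = "within-age",
                           n_replicates = 500, seed = 30)
  res <- run_lisso(sys$records, sys$rates, sc)
  totals <- colSums(res$net)
  # each saved agent survives follow-up independently -> binomial variance
  var1 <- sum(vapply(seq_along(sys$years), function(j) {
    s <- prod(rep(1 - 0.05, length(sys$years) - j))
    target_py * s * (1 - s)
  }, numeric(1)))
  se_mean <- sqrt(var1 / 500)
  expect_lt(abs(mean(totals) - expected), 3 * se_mean)
  # the median of the integer replicate totals sits on the same value up
  # to lattice resolution
  expect_lt(abs(stats::median(totals) - expected),
            0.5 + 3 * 1.26 * sqrt(var1) / sqrt(500))
})

test_that("deterministic mode reproduces the expectation exactly", {
  sys <- toy_system(deaths_per_year = 200L, m_young = 0.05)
  sc <- reduction_scenario("target", 0.20, mode = "within-age",
                           n_replicates = 1, seed = 1,
                           deterministic = TRUE)
  res <- run_lisso(sys$records, sys$rates, sc)
  expect_equal(res$lives_saved,
               toy_expected_net(40, sys$years, 0.05))
})

test_that("survivors age across band boundaries and die in later bands", {
  # agents saved at age 4 in 2000 cross into the open band by 2001 and
  # face its (certain) mortality there
  sch <- toy_schema()
  recs <- structure(
    data.frame(geounit = "T", year = 2000L, age = 4L, cause = "target",
               pseudo = FALSE)[rep(1, 10), ],
    schema = sch, class = c("death_records", "data.frame"))
  rates <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE,
                  dimnames = list(sch$labels, 2000:2002))
  sc <- reduction_scenario("target", 0.5, n_replicates = 3, seed = 2)
  res <- run_lisso(recs, rates, sc)
  expect_equal(res$median_net[["0-4"]], 0)       # all die by window end
  expect_equal(res$median_delta[["0-4"]], -5)    # averted at 0-4
  expect_equal(res$median_delta[["5+"]], 5)      # re-added deaths at 5+
})

test_that("a shortfall is logged when the target exceeds the pool", {
  sch <- toy_schema()
  recs <- structure(
    data.frame(geounit = "T", year = 2000L, age = 1L, cause = "target",
               pseudo = FALSE)[rep(1, 4), ],
    schema = sch, class = c("death_records", "data.frame"))
  rates <- matrix(0, 2, 1, dimnames = list(sch$labels, 2000))
  D <- matrix(c(10L, 0L), 2, 1, dimnames = list(sch$labels, 2000))
  sc <- reduction_scenario("target", 0.5, seed = 1)
  rep <- lifegain:::replicate_core(recs, rates,
                                   target_averted_counts(D, sc),
                                   sch, 2000L)
  expect_equal(sum(rep$net), 4)  # averted all that were available
  expect_equal(rep$shortfall$targeted, 5)
  expect_equal(rep$shortfall$available, 4)
})
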