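test_that("generation is deterministic given the seed", {
  a <- sim_population(10, 100, seed = 1)
  b <- sim_population(10, 100, seed = 1)
  expect_identical(a, b)
  ma <- sim_measurements(a, seed = 2)
  mb <- sim_measurements(b, seed = 2)
  expect_identical(ma, mb)
  expect_false(identical(ma, sim_measurements(a, seed = 3)$measurements))
})

test_that("generated tables pass io schema validation", {
  dir <- withr::local_tempdir()
  sim <- sim_scenario(n_cases = 15, n_pool = 80, seed = 5)
  write_simulation(sim, dir)
  for (schema in c("persons", "measurements", "events")) {
    got <- read_ehr_table(file.path(dir, paste0(schema, ".tsv")), schema)
    expect_equal(nrow(got$rejected), 0)
  }
})

test_that("sex ratio is respected within binomial error", {
  pop <- sim_population(2500, 10000, sex_ratio = 0.405, seed = 7)
  n <- nrow(pop$persons)
  frac <- mean(pop$persons$sex == "male")
  expect_lt(abs(frac - 0.405), 3 * sqrt(0.405 * 0.595 / n))
})

test_that("every case has exactly one index diagnosis", {
  pop <- sim_population(30, 150, seed = 3)
  i63 <- pop$events[pop$events$code == "I63", ]
  expect_setequal(i63$person_id,
                  pop$anchors$person_id[pop$anchors$role == "case"])
  expect_false(any(duplicated(i63$person_id)))
})

test_that("zero exclusion fraction leaves every pool member eligible", {
  pop <- sim_population(10, 60, exclusion_frac = 0, seed = 4)
  pool_ids <- pop$anchors$person_id[pop$anchors$role == "pool"]
  ev <- split(pop$events, pop$events$person_id)
  ok <- vapply(pool_ids, function(id) {
    e <- ev[[id]]
    if (is.null(e)) e <- pop$events[0, ]
    eligible_control(e)
  }, logical(1))
  expect_true(all(ok))
})

test_that("with no planted drift, case and control values are exchangeable", {
  # flat panel (no sex/age structure) so raw values can be compared directly
  panel <- data.frame(analyte_code = "X1", unit = "U/L", unit_weight = 1,
                      intercept = 10, sex_effect = 0, age_slope = 0,
                      noise_sd = 2, rate = 2.5, stringsAsFactors = FALSE)
  trends <- data.frame(analyte_code = character(), onset = integer(),
                       slope_z = numeric())
  miss <- data.frame(analyte_code = "X1", case_multiplier = 1)
  pop <- sim_population(250, 1000, seed = 11)
  m <- sim_measurements(pop, panel, trends, miss, horizon_days = 1500,
                        seed = 12)$measurements
  roles <- stats::setNames(pop$anchors$role, pop$anchors$person_id)
  x <- m$value[roles[m$person_id] == "case"]
  y <- m$value[roles[m$person_id] == "pool"]
  expect_gt(min(length(x), length(y)), 2000)
  expect_gt(suppressWarnings(stats::ks.test(x, y)$p.value), 0.01)
})

test_that("informative missingness multiplies the case measurement rate", {
  panel <- default_panel(1)
  trends <- data.frame(analyte_code = character(), onset = integer(),
                       slope_z = numeric())
  miss <- data.frame(analyte_code = panel$analyte_code[1],
                     case_multiplier = 3)
  pop <- sim_population(2000, 8000, seed = 21)
  m <- sim_measurements(pop, panel, trends, miss, horizon_days = 1000,
                        seed = 22)$measurements
  roles <- stats::setNames(pop$anchors$role, pop$anchors$person_id)
  per_case <- sum(roles[m$person_id] == "case") / 2000
  per_ctrl <- sum(roles[m$person_id] == "pool") / 8000
  expect_lt(abs(per_case / per_ctrl - 3), 0.3)
})

test_that("rate zero produces no measurement rows", {
  panel <- default_panel(1)
  panel$rate <- 0
  pop <- sim_population(2, 8, seed = 1)
  m <- sim_measurements(pop, panel,
                        trends = data.frame(analyte_code = character(),
                                            onset = integer(),
                                            slope_z = numeric()),
                        missingness = data.frame(analyte_code = character(),
                                                 case_multiplier = numeric()),
                        horizon_days = 1000, seed = 2)$measurements
  expect_equal(nrow(m), 0)
})

test_that("unknown analyte in a trend spec is a configuration error", {
  pop <- sim_population(2, 8, seed = 1)
  expect_error(
    sim_measurements(pop, default_panel(2),
                     trends = data.frame(analyte_code = "nope", onset = 100L,
                                         slope_z = 1),
                     horizon_days = 1000, seed = 1),
    "unknown analyte")
})

test_that("survival scenario recovers a planted hazard ratio", {
  d <- sim_survival_scenario(2000, hr = c(ref = 1, exposed = 2),
                             baseline_rate = 1 / 2000, censor_time = 2000,
                             seed = 31)
  fit <- survival::coxph(survival::Surv(time, event) ~ I(stratum == "exposed"),
                         data = d)
  expect_gt(exp(stats::coef(fit)), 1.8)
  expect_lt(exp(stats::coef(fit)), 2.2)
})

test_that("zero censor time yields no events", {
  d <- sim_survival_scenario(100, hr = c(a = 1, b = 1), censor_time = 0,
                             seed = 5)
  expect_equal(sum(d$event), 0)
})

test_that("planted transaction pairs hit their marginal and joint rates", {
  tx <- sim_transactions(20000, 0.35, 0.35, 0.30, seed = 9)
  a <- mean(vapply(tx, function(t) "A_HIGH" %in% t, logical(1)))
  b <- mean(vapply(tx, function(t) "B_LOW" %in% t, logical(1)))
  j <- mean(vapply(tx, function(t) length(t) == 2, logical(1)))
  expect_lt(abs(a - 0.35), 0.015)
  expect_lt(abs(b - 0.35), 0.015)
  expect_lt(abs(j - 0.30), 0.015)
  expect_error(sim_transactions(10, 0.2, 0.2, 0.5, seed = 1), "infeasible")
})
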