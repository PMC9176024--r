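test_that("scenario validation rejects impossible parameters", {
  expect_error(survival_scenario("exponential", n_subjects = 10, rate = -1),
               class = "rmstgain_error")
  expect_error(survival_scenario("weibull", n_subjects = 10, shape = 0,
                                 scale = 2), class = "rmstgain_error")
  expect_error(survival_scenario("piecewise-exponential", n_subjects = 10,
                                 breakpoints = c(1, 3), rates = c(0.1, 0.2)),
               "start at 0", class = "rmstgain_error")
  expect_error(survival_scenario("exponential", n_subjects = 10, rate = 0.1,
                                 admin_cutoff = 0), class = "rmstgain_error")
})

test_that("simulation is seed-deterministic and leaves the global RNG alone", {
  sc <- survival_scenario("exponential", n_subjects = 50, rate = 0.2,
                          censor_rate = 0.05, admin_cutoff = 18, seed = 13)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a$time, b$time)
  expect_identical(a$event, b$event)
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(simulate_cohort(sc))
  expect_identical(stats::runif(1), x1) # global RNG state untouched
})

test_that("without censoring every subject is an event", {
  sc <- survival_scenario("exponential", n_subjects = 200, rate = 0.1,
                          censor_rate = 0, admin_cutoff = 1e9, seed = 2)
  ipd <- simulate_cohort(sc)
  expect_true(all(ipd$event))
  expect_true(all(ipd$time >= 0))
})

test_that("large-cohort KM medians land near the model medians", {
  for (m in c(3.5, 11.3)) {
    sc <- survival_scenario("exponential", n_subjects = 5000,
                            rate = log(2) / m, censor_rate = 0,
                            admin_cutoff = 60, seed = 31)
    emp <- median_survival(km_from_ipd(simulate_cohort(sc)))
    expect_lt(abs(emp - m) / m, 0.05)
  }
})

test_that("analytic RMST matches the closed forms and their limits", {
  sc <- survival_scenario("exponential", n_subjects = 10, rate = 0.1)
  expect_equal(as.numeric(analytic_rmst(sc, 18)), (1 - exp(-1.8)) / 0.1)
  expect_identical(attr(analytic_rmst(sc, 18), "oracle"), "closed-form")
  # lambda -> 0: RMST approaches the milestone (flat survival)
  tiny <- survival_scenario("exponential", n_subjects = 10, rate = 1e-9)
  expect_equal(as.numeric(analytic_rmst(tiny, 18)), 18, tolerance = 1e-6)
  # one-segment piecewise equals the exponential form
  pw1 <- survival_scenario("piecewise-exponential", n_subjects = 10,
                           breakpoints = 0, rates = 0.1)
  expect_equal(as.numeric(analytic_rmst(pw1, 18)),
               as.numeric(analytic_rmst(sc, 18)))
  # piecewise with equal rates in both segments also collapses to it
  pw2 <- survival_scenario("piecewise-exponential", n_subjects = 10,
                           breakpoints = c(0, 6), rates = c(0.1, 0.1))
  expect_equal(as.numeric(analytic_rmst(pw2, 18)),
               as.numeric(analytic_rmst(sc, 18)))
  # weibull(shape = 1, scale = 1/lambda) is exponential(lambda)
  wb <- survival_scenario("weibull", n_subjects = 10, shape = 1, scale = 10)
  expect_equal(as.numeric(analytic_rmst(wb, 18)), (1 - exp(-1.8)) / 0.1,
               tolerance = 1e-8)
  expect_identical(attr(analytic_rmst(wb, 18), "oracle"), "numeric")
})

test_that("piecewise simulation agrees with its own analytic RMST", {
  sc <- survival_scenario("piecewise-exponential", n_subjects = 20000,
                          breakpoints = c(0, 3, 9), rates = c(0.05, 0.12, 0.2),
                          censor_rate = 0, admin_cutoff = 1e9, seed = 8)
  ipd <- simulate_cohort(sc)
  emp <- mean(pmin(ipd$time, 18))
  expect_equal(emp, as.numeric(analytic_rmst(sc, 18)), tolerance = 0.05)
})

test_that("noiseless corner digitization integrates exactly to the step RMST", {
  step <- random_step(n_drops = 10, seed = 5)
  curve <- digitize_emulator(step, n_points = 60, jitter_sd = 0, seed = 1,
                             t_max = 18, min_drop = 0)
  cleaned <- enforce_km_shape(curve)
  expect_equal(rmst_trapezoid(cleaned, 18)$rmst, rmst_step_exact(step, 18))
})

test_that("the digitize emulator is deterministic and point-budgeted", {
  step <- random_step(n_drops = 8, seed = 12)
  a <- digitize_emulator(step, n_points = 75, jitter_sd = 0.01, seed = 99)
  b <- digitize_emulator(step, n_points = 75, jitter_sd = 0.01, seed = 99)
  expect_identical(a$survival, b$survival)
  expect_equal(nrow(a), 75)
  c2 <- digitize_emulator(step, n_points = 75, jitter_sd = 0.01, seed = 100)
  expect_false(identical(a$survival, c2$survival))
})

test_that("jittered digitization stays within 0.3 months of the exact RMST", {
  t_star <- 18
  # digitize the model survival function itself sampled as a fine step curve
  tt <- seq(0.05, 18, length.out = 150)
  step <- km_step(tt, exp(-0.1 * tt))
  exact <- rmst_step_exact(step, t_star)
  for (seed in 1:20) {
    raw <- digitize_emulator(step, n_points = 75, jitter_sd = 0.01,
                             seed = seed, t_max = 18)
    est <- rmst_trapezoid(enforce_km_shape(raw), t_star)$rmst
    expect_lt(abs(est - exact), 0.3)
  }
})

test_that("demo scenarios encode the published two-arm geometry", {
  sc <- demo_scenarios(seed = 4)
  expect_equal(sc$treated$n_subjects, 128L)
  expect_equal(sc$control$n_subjects, 190L)
  expect_equal(sc$treated$admin_cutoff, 18)
  # model medians sit at 11.3 and 3.5 months by construction
  h <- function(s, t) { # cumulative hazard of a scenario at t
    if (s$model == "exponential") return(s$rate * t)
    b <- s$breakpoints; r <- s$rates
    sum(r * pmax(0, pmin(c(b[-1], Inf), t) - pmin(b, t)))
  }
  expect_equal(h(sc$treated, 11.3), log(2))
  expect_equal(h(sc$control, 3.5), log(2))
})

test_that("scenario configs round-trip through YAML and JSON", {
  cfg <- list(model = "piecewise-exponential", n_subjects = 30,
              breakpoints = c(0, 3), rates = c(0.1, 0.2),
              censor_rate = 0.02, admin_cutoff = 18, seed = 7,
              arm_label = "pw")
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, ypath)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE, digits = NA)
  for (path in c(ypath, jpath)) {
    sc <- read_scenario(path)
    expect_s3_class(sc, "survival_scenario")
    expect_equal(sc$rates, c(0.1, 0.2))
    expect_identical(simulate_cohort(sc)$time,
                     simulate_cohort(sc)$time)
  }
})
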