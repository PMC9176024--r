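test_that("product-limit inversion recovers hand-computed event counts", {
  curve <- km_curve(c(0, 5, 10), c(1, 0.8, 0.4), n_subjects = 10)
  ipd <- reconstruct_events(curve)
  # 10 * (1 - 0.8) = 2 events at 5; 8 * (1 - 0.4/0.8) = 4 events at 10
  expect_equal(sum(ipd$event & ipd$time == 5), 2)
  expect_equal(sum(ipd$event & ipd$time == 10), 4)
  expect_equal(sum(!ipd$event & ipd$time == 10), 4)
  expect_equal(nrow(ipd), 10)
})

test_that("degenerate cohorts reconstruct correctly", {
  flat <- km_curve(c(0, 18), c(1, 1), n_subjects = 50)
  ipd <- reconstruct_events(flat)
  expect_equal(sum(ipd$event), 0)
  expect_equal(unique(ipd$time), 18)
  all_event <- km_curve(c(0, 4, 9), c(1, 0.6, 0), n_subjects = 7)
  ipd2 <- reconstruct_events(all_event)
  expect_equal(sum(ipd2$event), 7)
  expect_equal(sum(!ipd2$event), 0)
})

test_that("events and censorings always sum to the cohort size", {
  for (seed in 1:8) {
    curve <- random_cohort_curve(n = 35, seed = seed)
    ipd <- reconstruct_events(curve)
    expect_equal(sum(ipd$event) + sum(!ipd$event), attr(curve, "n_subjects"))
    expect_true(all(ipd$time >= 0 & ipd$time <= max(curve$time)))
  }
})

test_that("a curve inconsistent with its cohort size is rejected by name", {
  # with n = 1 the first drop consumes the whole risk set, so the second
  # drop has no subjects left to assign
  bad <- km_curve(c(0, 2, 4), c(1, 0.4, 0.3), n_subjects = 1)
  expect_error(reconstruct_events(bad), "inconsistent with n = 1",
               class = "rmstgain_error")
  expect_error(reconstruct_events(km_curve(c(0, 5), c(1, 0.5))),
               "n_subjects", class = "rmstgain_error")
})

test_that("reconstruction round-trips through the KM estimate within 1/(2n)", {
  for (seed in 1:10) {
    curve <- random_cohort_curve(n = 25 + 5 * seed, seed = seed)
    n <- attr(curve, "n_subjects")
    ipd <- reconstruct_events(curve)
    back <- km_from_ipd(ipd)
    src_step <- as_km_step(curve)
    back_step <- as_km_step(back)
    at_drops <- eval_km_step(back_step, src_step$drop_times)
    expect_true(all(abs(at_drops - src_step$drop_probs) <= 1 / (2 * n) + 1e-12))
  }
})

test_that("km_from_ipd matches the survival package's product-limit estimate", {
  for (seed in c(2, 9)) {
    sc <- survival_scenario("exponential", n_subjects = 60, rate = 0.15,
                            censor_rate = 0.05, admin_cutoff = 18, seed = seed)
    ipd <- simulate_cohort(sc)
    fit <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1)
    mine <- as_km_step(km_from_ipd(ipd))
    ref_times <- fit$time[fit$n.event > 0]
    ref_surv <- fit$surv[fit$n.event > 0]
    expect_equal(mine$drop_times, ref_times)
    expect_equal(mine$drop_probs, ref_surv)
  }
})

test_that("single-subject and all-censored cohorts yield the expected curves", {
  one <- km_from_ipd(tibble::tibble(subject_id = 1, time = 4, event = TRUE))
  expect_equal(one$time, c(0, 4, 4))
  expect_equal(one$survival, c(1, 1, 0))
  cens <- km_from_ipd(tibble::tibble(subject_id = 1:5, time = rep(6, 5),
                                     event = rep(FALSE, 5)))
  expect_equal(max(cens$survival), 1)
  expect_equal(min(cens$survival), 1)
})

test_that("bootstrap CIs are seed-deterministic and collapse for flat curves", {
  curve <- random_cohort_curve(n = 80, seed = 4)
  a <- bootstrap_rmst_ci(curve, 15, n_bootstrap = 300, seed = 42)
  b <- bootstrap_rmst_ci(curve, 15, n_bootstrap = 300, seed = 42)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_true(a$ci_low <= a$rmst && a$rmst <= a$ci_high)
  flat <- km_curve(c(0, 18), c(1, 1), n_subjects = 40)
  fb <- bootstrap_rmst_ci(flat, 18, n_bootstrap = 200, seed = 1)
  expect_equal(fb$ci_low, 18)
  expect_equal(fb$ci_high, 18)
  expect_error(bootstrap_rmst_ci(curve, 15, n_bootstrap = 50, seed = 1),
               "at least 100", class = "rmstgain_error")
})

test_that("bootstrap CI width shrinks as the cohort grows", {
  widths <- vapply(c(50, 200, 800), function(n) {
    sc <- survival_scenario("exponential", n_subjects = n, rate = 0.1,
                            censor_rate = 0, admin_cutoff = 18, seed = 77)
    curve <- km_from_ipd(simulate_cohort(sc))
    est <- bootstrap_rmst_ci(curve, 18, n_bootstrap = 400, seed = 5)
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("identical arms give a null comparison, deterministically", {
  curve <- random_cohort_curve(n = 100, seed = 6)
  cmp <- compare_arms(curve, curve, n_bootstrap = 300, seed = 9)
  expect_equal(glance(cmp)$rmst_gain, 0)
  expect_equal(glance(cmp)$median_gain, 0)
  expect_gt(glance(cmp)$p_value, 0.9)
  cmp2 <- compare_arms(curve, curve, n_bootstrap = 300, seed = 9)
  expect_identical(glance(cmp), glance(cmp2))
  expect_identical(cmp$boot$gain, cmp2$boot$gain)
})

test_that("arms with separated medians yield a positive, significant gain", {
  sc_t <- survival_scenario("exponential", n_subjects = 128,
                            rate = log(2) / 11.3, censor_rate = 0,
                            admin_cutoff = 18, seed = 21, arm_label = "treated")
  sc_c <- survival_scenario("exponential", n_subjects = 190,
                            rate = log(2) / 3.5, censor_rate = 0,
                            admin_cutoff = 18, seed = 22, arm_label = "control")
  cmp <- compare_arms(km_from_ipd(simulate_cohort(sc_t)),
                      km_from_ipd(simulate_cohort(sc_c)),
                      t_star = 18, n_bootstrap = 500, seed = 3)
  g <- glance(cmp)
  expect_gt(g$rmst_gain, 0)
  expect_lt(g$p_value, 0.001)
  expect_true(g$gain_ci_low <= g$rmst_gain && g$rmst_gain <= g$gain_ci_high)
  expect_equal(tidy(cmp)$n, c(128L, 190L))
})

test_that("gain confidence intervals bracket the estimate on the null too", {
  # the CI-brackets-estimate invariant holds even for sparse digitizations,
  # where the bootstrap distribution is recentred on the trapezoid estimate
  sparse <- km_curve(c(0, 5, 10, 15), c(1, 0.7, 0.45, 0.3), n_subjects = 60)
  est <- bootstrap_rmst_ci(sparse, 15, n_bootstrap = 400, seed = 11)
  expect_true(est$ci_low <= est$rmst && est$rmst <= est$ci_high)
})

test_that("pseudo-IPD exports the subject_id,time,event CSV dialect", {
  ipd <- reconstruct_events(km_curve(c(0, 5, 10), c(1, 0.8, 0.4),
                                     n_subjects = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pseudo_ipd(ipd, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("subject_id", "time", "event"))
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, as.integer(ipd$event))
})
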