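# Shared fixtures: all test inputs are built in code.

# A random non-degenerate survival step function on [0, t_max].
random_step <- function(n_drops = 6, t_max = 18, seed = 1) {
  withr::with_seed(seed, {
    dt <- sort(stats::runif(n_drops, 0.2, t_max))
    dp <- sort(stats::runif(n_drops, 0.02, 0.98), decreasing = TRUE)
  })
  km_step(dt, dp)
}

# A random digitizer-consistent curve with n_subjects, via the product-limit
# of a small simulated cohort (so reconstruction is exactly invertible).
random_cohort_curve <- function(n = 40, rate = 0.12, cutoff = 18, seed = 1) {
  sc <- survival_scenario("exponential",
    n_subjects = n, rate = rate,
    censor_rate = 0.03, admin_cutoff = cutoff, seed = seed
  )
  km_from_ipd(simulate_cohort(sc))
}

write_curve_file <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Three-point textbook curve: AUC at 12 is 6.75 by hand.
textbook_curve <- function(n = NULL) {
  km_curve(c(0, 6, 12), c(1, 0.5, 0.25), arm_label = "textbook", n_subjects = n)
}
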