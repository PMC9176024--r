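#' Common milestone for a two-arm comparison
#'
#' The milestone `t*` at which both restricted means are evaluated is the
#' longest follow-up reached by both curves, i.e. the minimum of the two
#' maximum digitized times. RMST gains are only comparable at a shared `t*`.
#'
#' @param curve_a,curve_b `km_curve` objects.
#' @return The milestone in months.
#' @examples
#' a <- km_curve(c(0, 18.4), c(1, 0.4))
#' b <- km_curve(c(0, 21.0), c(1, 0.2))
#' common_milestone(a, b) # 18.4
#' @export
common_milestone <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "km_curve"), inherits(curve_b, "km_curve"))
  if (!nrow(curve_a) || !nrow(curve_b)) {
    abort_rmstgain("cannot choose a milestone from an empty curve.")
  }
  min(max(curve_a$time), max(curve_b$time))
}

#' Truncate ("restrict") a digitized curve at a milestone
#'
#' Drops all points beyond `t_star` and, when the curve extends past it,
#' appends a point exactly at `t_star` whose probability is the linear
#' interpolation between the bracketing digitized points (the plateau value
#' when `t_star` falls inside a plateau) — consistent with the piecewise-linear
#' geometry that the trapezoidal rule assumes.
#'
#' @param curve A valid `km_curve`.
#' @param t_star Milestone in months; must not exceed the curve's follow-up,
#'   since the milestone rule requires both curves to reach it.
#' @return A `km_curve` ending exactly at `t_star`.
#' @export
truncate_curve <- function(curve, t_star) {
  validate_km_curve(curve)
  tt <- curve$time
  pp <- curve$survival
  if (length(t_star) != 1L || is.na(t_star) || t_star <= 0) {
    abort_rmstgain("`t_star` must be a single positive time.")
  }
  if (t_star > max(tt)) {
    abort_rmstgain(sprintf(
      "milestone %.4g mo exceeds the follow-up of curve '%s' (%.4g mo).",
      t_star, attr(curve, "arm_label"), max(tt)
    ))
  }
  keep <- tt <= t_star
  tt_k <- tt[keep]
  pp_k <- pp[keep]
  if (max(tt_k) < t_star) {
    i_lo <- length(tt_k)                 # bottom corner of last kept time
    i_hi <- which(tt > t_star)[1]        # top corner of first time beyond
    p_star <- pp_k[i_lo] +
      (pp[i_hi] - pp_k[i_lo]) * (t_star - tt_k[i_lo]) / (tt[i_hi] - tt_k[i_lo])
    tt_k <- c(tt_k, t_star)
    pp_k <- c(pp_k, p_star)
  }
  validate_km_curve(new_km_curve(tt_k, pp_k, attr(curve, "arm_label"),
                                 attr(curve, "n_subjects")))
}

#' Restricted mean survival time by the trapezoidal rule
#'
#' Truncates the digitized curve at the milestone `t_star` and applies the
#' trapezoidal rule to the coordinate pairs as digitized: the area under the
#' curve on `[0, t_star]` equals the RMST. This integrates the digitized
#' points directly rather than a refitted step function, mirroring how the
#' AUC of a concentration-time profile is computed in pharmacokinetics.
#'
#' @inheritParams truncate_curve
#' @return A one-row tibble (class `rmst_estimate`) with columns `arm`,
#'   `rmst`, `milestone`, `ci_low`, `ci_high` (NA until bootstrap inference
#'   is run, see [bootstrap_rmst_ci()]) and `method`.
#' @examples
#' curve <- km_curve(c(0, 6, 12), c(1, 0.5, 0.25))
#' rmst_trapezoid(curve, t_star = 12)$rmst # 6.75
#' @export
rmst_trapezoid <- function(curve, t_star) {
  tr <- truncate_curve(curve, t_star)
  tt <- tr$time
  pp <- tr$survival
  auc <- sum(diff(tt) * (pp[-length(pp)] + pp[-1]) / 2)
  new_rmst_estimate(attr(curve, "arm_label"), auc, t_star, method = "trapezoid")
}

new_rmst_estimate <- function(arm, rmst, milestone, ci_low = NA_real_,
                              ci_high = NA_real_, method = "trapezoid") {
  out <- tibble::tibble(
    arm = arm, rmst = rmst, milestone = milestone,
    ci_low = ci_low, ci_high = ci_high, method = method
  )
  class(out) <- c("rmst_estimate", class(out))
  out
}

#' Exact RMST of a survival step function
#'
#' Exact integral of the right-continuous step function over `[0, t_star]`.
#' Serves as the integration oracle for [rmst_trapezoid()]: on a curve that
#' records both corners of every drop the two agree to machine precision.
#' The step is carried flat beyond its last drop.
#'
#' @param step A `km_step`.
#' @param t_star Milestone in months, positive.
#' @return RMST in months.
#' @examples
#' s <- km_step(c(5, 10), c(0.8, 0.4))
#' rmst_step_exact(s, 12) # 5 + 0.8*5 + 0.4*2 = 9.8
#' @export
rmst_step_exact <- function(step, t_star) {
  stopifnot(inherits(step, "km_step"))
  if (length(t_star) != 1L || is.na(t_star) || t_star <= 0) {
    abort_rmstgain("`t_star` must be a single positive time.")
  }
  bounds <- pmin(c(step$drop_times, Inf), t_star)
  lower <- pmin(c(0, step$drop_times), t_star)
  sum((bounds - lower) * c(1, step$drop_probs))
}

#' Median survival from a digitized curve
#'
#' The smallest digitized time at which the survival probability is at most
#' 0.5, under the right-continuous step convention — the way medians are
#' conventionally read off Kaplan-Meier output. `NA` when the curve never
#' reaches 0.5 within follow-up (the median is then undefined, not an error).
#'
#' @param curve A valid `km_curve`.
#' @return Median in months, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  validate_km_curve(curve)
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

#' Between-arm survival gain from RMSTs and medians
#'
#' Forms the two gain statistics that summarise a two-arm comparison: the
#' RMST gain (treated minus control restricted mean, both at the same
#' milestone) and the median gain (difference of medians, `NA` when either
#' median is undefined). The RMST gain reflects the whole curve up to `t*`;
#' the median gain reflects only the crossing of 0.5.
#'
#' @param treated,control `rmst_estimate` rows sharing the same milestone.
#' @param median_treated,median_control Medians in months, possibly `NA`.
#' @return A one-row tibble (class `gain_estimate`) with `rmst_gain`,
#'   `median_gain` and `milestone`.
#' @examples
#' t_est <- rmst_trapezoid(km_curve(c(0, 6, 12), c(1, 0.8, 0.6)), 12)
#' c_est <- rmst_trapezoid(km_curve(c(0, 6, 12), c(1, 0.5, 0.25)), 12)
#' rmst_gain(t_est, c_est, median_treated = NA, median_control = 6)
#' @export
rmst_gain <- function(treated, control, median_treated = NA_real_,
                      median_control = NA_real_) {
  stopifnot(inherits(treated, "rmst_estimate"), inherits(control, "rmst_estimate"))
  if (abs(treated$milestone - control$milestone) > 1e-8) {
    abort_rmstgain(sprintf(
      "milestone mismatch (%.4g vs %.4g mo): gains are only defined at a common t*.",
      treated$milestone, control$milestone
    ))
  }
  out <- tibble::tibble(
    rmst_gain = treated$rmst - control$rmst,
    median_gain = if (is.na(median_treated) || is.na(median_control)) {
      NA_real_
    } else {
      median_treated - median_control
    },
    milestone = treated$milestone
  )
  class(out) <- c("gain_estimate", class(out))
  out
}
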