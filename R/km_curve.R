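#' Digitized Kaplan-Meier curves
#'
#' A `km_curve` is a tibble of (time, survival) coordinate pairs read off a
#' published Kaplan-Meier plot, one per treatment arm, carrying the arm label
#' and the cohort size at time zero as attributes. Times are in months,
#' survival probabilities in `[0, 1]`. Duplicate times are permitted only as
#' adjacent pairs, which encode the top and bottom corner of one vertical KM
#' drop.
#'
#' @param time Numeric vector of follow-up times (months, non-negative,
#'   non-decreasing).
#' @param survival Numeric vector of survival probabilities, same length as
#'   `time`.
#' @param arm_label Character label for the arm.
#' @param n_subjects Cohort size at time zero (positive integer), or `NULL`
#'   when not yet known. Required by [reconstruct_events()].
#' @param clean If `TRUE`, pass the result through [enforce_km_shape()].
#' @return A `km_curve`: a tibble with columns `time` and `survival` and
#'   attributes `arm_label` and `n_subjects`.
#' @examples
#' km_curve(c(0, 6, 12), c(1, 0.5, 0.25), arm_label = "control", n_subjects = 10)
#' @export
km_curve <- function(time, survival, arm_label = "arm", n_subjects = NULL,
                     clean = FALSE) {
  curve <- new_km_curve(time, survival, arm_label, n_subjects)
  if (clean) curve <- enforce_km_shape(curve)
  curve
}

# Low-level constructor: no shape invariants enforced, so raw digitizer output
# (jittered, non-monotone) can be represented before repair.
new_km_curve <- function(time, survival, arm_label, n_subjects) {
  if (length(time) != length(survival)) {
    abort_rmstgain("`time` and `survival` must have the same length.")
  }
  if (!is.null(n_subjects)) {
    if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1 ||
        n_subjects != round(n_subjects)) {
      abort_rmstgain("`n_subjects` must be a single positive integer.")
    }
    n_subjects <- as.integer(n_subjects)
  }
  curve <- tibble::tibble(time = as.numeric(time), survival = as.numeric(survival))
  structure(curve,
    class = c("km_curve", class(curve)),
    arm_label = as.character(arm_label),
    n_subjects = n_subjects
  )
}

#' @export
print.km_curve <- function(x, ...) {
  n <- attr(x, "n_subjects")
  cat(sprintf(
    "<km_curve> arm '%s', %d points, follow-up %.2f mo%s\n",
    attr(x, "arm_label"), nrow(x), max(x$time),
    if (is.null(n)) "" else sprintf(", n = %d", n)
  ))
  NextMethod()
}

#' Validate the Kaplan-Meier shape invariants of a digitized curve
#'
#' Checks that the curve has at least two points, starts at `(0, 1)`, has
#' non-decreasing times with duplicates only as adjacent corner pairs, and
#' non-increasing survival probabilities within `[0, 1]`. Curves fresh from a
#' digitizer usually fail monotonicity; repair them with [enforce_km_shape()].
#'
#' @param curve A `km_curve`.
#' @return `curve`, invisibly; aborts with an informative message otherwise.
#' @export
validate_km_curve <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tt <- curve$time
  pp <- curve$survival
  lbl <- attr(curve, "arm_label")
  if (nrow(curve) < 2L) {
    abort_rmstgain(sprintf("curve '%s' needs at least 2 points.", lbl))
  }
  if (anyNA(tt) || anyNA(pp)) {
    abort_rmstgain(sprintf("curve '%s' contains missing values.", lbl))
  }
  if (any(tt < 0)) {
    abort_rmstgain(sprintf("curve '%s' has negative times.", lbl))
  }
  if (is.unsorted(tt)) {
    abort_rmstgain(sprintf("curve '%s' has decreasing times.", lbl))
  }
  runs <- rle(tt)$lengths
  if (any(runs > 2L)) {
    abort_rmstgain(sprintf(
      "curve '%s' repeats a time more than twice; duplicate times may only encode one vertical drop.",
      lbl
    ))
  }
  if (any(pp < 0 | pp > 1)) {
    abort_rmstgain(sprintf("curve '%s' has probabilities outside [0, 1].", lbl))
  }
  if (tt[1] != 0 || pp[1] != 1) {
    abort_rmstgain(sprintf("curve '%s' must start at (0, 1).", lbl))
  }
  if (is.unsorted(rev(pp))) {
    abort_rmstgain(sprintf(
      "curve '%s' has increasing survival probabilities; repair with enforce_km_shape().", lbl
    ))
  }
  invisible(curve)
}

#' Read a digitized Kaplan-Meier curve from delimited text
#'
#' Reads the two-column `time, survival` export of a plot digitizer. The
#' delimiter (comma, tab or semicolon) is sniffed, a header line is optional,
#' and probabilities may be on either the `[0, 1]` or the percent `[0, 100]`
#' scale: if any probability exceeds 1.5 the whole column is divided by 100.
#' Rows are sorted by time. The returned curve is unrepaired; digitization
#' jitter is removed downstream by [enforce_km_shape()] (applied automatically
#' by [run_analysis()]).
#'
#' @param path Path to the delimited text file.
#' @inheritParams km_curve
#' @return A `km_curve`.
#' @export
read_km_curve <- function(path, arm_label = "arm", n_subjects = NULL,
                          clean = FALSE) {
  if (!file.exists(path)) {
    abort_rmstgain(sprintf("file '%s' does not exist.", path))
  }
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, col_names = FALSE, col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, comment = "#", progress = FALSE,
    show_col_types = FALSE
  )
  if (ncol(raw) < 2L) {
    abort_rmstgain(sprintf("file '%s' does not have two columns.", path))
  }
  raw <- raw[, 1:2]
  names(raw) <- c("time", "survival")
  # optional header: drop the first row when it is not numeric
  first_numeric <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  if (anyNA(first_numeric)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) < 2L) {
    abort_rmstgain(sprintf("file '%s' has fewer than 2 data rows.", path))
  }
  tt <- suppressWarnings(as.numeric(raw$time))
  pp <- suppressWarnings(as.numeric(raw$survival))
  bad <- which(is.na(tt) | is.na(pp))
  if (length(bad)) {
    abort_rmstgain(sprintf("file '%s': non-numeric value in row %d.", path, bad[1]))
  }
  if (any(tt < 0)) {
    abort_rmstgain(sprintf(
      "file '%s': negative time in row %d.", path, which(tt < 0)[1]
    ))
  }
  if (any(pp < 0 | pp > 100)) {
    abort_rmstgain(sprintf(
      "file '%s': survival probability outside [0, 100] in row %d.",
      path, which(pp < 0 | pp > 100)[1]
    ))
  }
  if (any(pp > 1.5)) pp <- pp / 100 # percent-scale axis
  ord <- order(tt) # stable: preserves corner order within a duplicated time
  new_km_curve(tt[ord], pp[ord], arm_label, n_subjects)
}

sniff_delim <- function(path) {
  lines <- readLines(path, n = 5L, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    abort_rmstgain(sprintf("file '%s' is empty.", path))
  }
  counts <- vapply(
    c("," = ",", "\t" = "\t", ";" = ";"),
    function(d) sum(lengths(regmatches(lines, gregexpr(d, lines, fixed = TRUE)))),
    numeric(1)
  )
  if (all(counts == 0)) {
    abort_rmstgain(sprintf(
      "file '%s': no comma, tab or semicolon delimiter found.", path
    ))
  }
  c(",", "\t", ";")[which.max(counts)]
}

#' Repair digitization noise in a curve
#'
#' Manual digitization of a published plot carries pixel noise that can make
#' the point sequence non-monotone or push probabilities slightly outside
#' `[0, 1]`. This repairs the curve into a valid Kaplan-Meier shape:
#' a `(0, 1)` anchor is prepended when absent, probabilities are clamped to
#' `[0, 1]` and replaced by their running minimum, and runs of more than two
#' points at one time are collapsed to the corner pair. Idempotent.
#'
#' @param curve A `km_curve` (possibly raw digitizer output).
#' @return A `km_curve` satisfying all shape invariants (see
#'   [validate_km_curve()]).
#' @examples
#' raw <- km_curve(c(0, 4, 8, 12), c(1, 0.82, 0.84, 0.60))
#' enforce_km_shape(raw)$survival
#' @export
enforce_km_shape <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tt <- curve$time
  pp <- curve$survival
  if (anyNA(tt) || anyNA(pp) || any(tt < 0)) {
    abort_rmstgain("curve has missing values or negative times; cannot repair.")
  }
  ord <- order(tt)
  tt <- tt[ord]
  pp <- pp[ord]
  if (tt[1] != 0 || pp[1] != 1) {
    tt <- c(0, tt)
    pp <- c(1, pp)
  }
  pp <- cummin(pmin(1, pmax(0, pp)))
  # collapse >2 points at one time to the (max, min) corner pair
  if (any(rle(tt)$lengths > 2L)) {
    keep <- !duplicated(tt) | !duplicated(tt, fromLast = TRUE)
    tt <- tt[keep]
    pp <- pp[keep]
  }
  # a duplicated time with equal probabilities is a redundant point, not a drop
  dup <- duplicated(tt, fromLast = TRUE) & pp == c(pp[-1], NA_real_)
  dup[is.na(dup)] <- FALSE
  out <- new_km_curve(tt[!dup], pp[!dup], attr(curve, "arm_label"),
                      attr(curve, "n_subjects"))
  validate_km_curve(out)
}

#' Convert a digitized curve to a right-continuous step function
#'
#' Each strict decrease in the digitized probabilities becomes one drop. A
#' duplicated time (corner pair) yields a single drop at that time to the
#' lower corner. The step function is the exact-integration counterpart of
#' the trapezoid estimate: see [rmst_step_exact()].
#'
#' @param curve A valid `km_curve`.
#' @return A `km_step` object (see [km_step()]).
#' @export
as_km_step <- function(curve) {
  validate_km_curve(curve)
  tt <- curve$time
  pp <- curve$survival
  last <- !duplicated(tt, fromLast = TRUE) # bottom corner at each time
  tt <- tt[last]
  pp <- pp[last]
  prev <- c(1, pp[-length(pp)])
  is_drop <- pp < prev
  km_step(tt[is_drop], pp[is_drop])
}

#' Right-continuous survival step function
#'
#' Piecewise-constant, non-increasing survival function starting at 1, the
#' canonical form of a Kaplan-Meier estimate. Used as the exact-integration
#' oracle for the trapezoid AUC and as the input to the digitization emulator.
#'
#' @param drop_times Strictly increasing times (months) at which the survival
#'   drops.
#' @param drop_probs Survival value immediately after each drop,
#'   non-increasing, in `[0, 1]`.
#' @return A `km_step` object.
#' @export
km_step <- function(drop_times = numeric(), drop_probs = numeric()) {
  if (length(drop_times) != length(drop_probs)) {
    abort_rmstgain("`drop_times` and `drop_probs` must have the same length.")
  }
  if (length(drop_times)) {
    if (any(diff(drop_times) <= 0)) {
      abort_rmstgain("`drop_times` must be strictly increasing.")
    }
    if (any(drop_times < 0)) abort_rmstgain("`drop_times` must be non-negative.")
    if (any(diff(drop_probs) > 0) || any(drop_probs < 0 | drop_probs > 1)) {
      abort_rmstgain("`drop_probs` must be non-increasing within [0, 1].")
    }
  }
  structure(
    list(drop_times = as.numeric(drop_times), drop_probs = as.numeric(drop_probs)),
    class = "km_step"
  )
}

#' @export
print.km_step <- function(x, ...) {
  cat(sprintf("<km_step> %d drops\n", length(x$drop_times)))
  if (length(x$drop_times)) {
    print(tibble::tibble(drop_time = x$drop_times, survival_after = x$drop_probs))
  }
  invisible(x)
}

#' Evaluate a survival step function
#'
#' Right-continuous evaluation: at a drop time the post-drop value is
#' returned; before the first drop the value is 1.
#'
#' @param step A `km_step`.
#' @param t Numeric vector of times (months, non-negative).
#' @return Numeric vector of survival probabilities.
#' @export
eval_km_step <- function(step, t) {
  stopifnot(inherits(step, "km_step"))
  idx <- findInterval(t, step$drop_times)
  out <- rep(1, length(t))
  out[idx > 0] <- step$drop_probs[idx[idx > 0]]
  out
}

#' Emit the corner points of a step function as a digitized curve
#'
#' The inverse of [as_km_step()] for curves that record both corners of every
#' drop: the round trip step -> corners -> step is exact. The emitted curve
#' runs from `(0, 1)` to `t_max` (default: the last drop time).
#'
#' @param step A `km_step`.
#' @param t_max Follow-up end for the emitted curve.
#' @inheritParams km_curve
#' @return A `km_curve` with a corner pair at every drop.
#' @export
km_step_corners <- function(step, t_max = NULL, arm_label = "arm",
                            n_subjects = NULL) {
  stopifnot(inherits(step, "km_step"))
  dt <- step$drop_times
  dp <- step$drop_probs
  if (is.null(t_max)) {
    t_max <- if (length(dt)) max(dt) else
      abort_rmstgain("`t_max` is required for a step function with no drops.")
  }
  keep <- dt <= t_max
  dt <- dt[keep]
  dp <- dp[keep]
  pre <- if (length(dp)) c(1, dp[-length(dp)]) else numeric()
  tt <- rep(dt, each = 2L)
  pp <- as.vector(rbind(pre, dp))
  if (!length(dt) || dt[1] > 0) { # anchor unless the first drop is at 0
    tt <- c(0, tt)
    pp <- c(1, pp)
  }
  if (!length(dt) || max(dt) < t_max) {
    tt <- c(tt, t_max)
    pp <- c(pp, if (length(dp)) dp[length(dp)] else 1)
  }
  validate_km_curve(new_km_curve(tt, pp, arm_label, n_subjects))
}

#' Write a digitized curve as CSV
#'
#' Two columns, `time,survival`, with a header — the same dialect
#' [read_km_curve()] accepts, so curves round-trip through disk.
#'
#' @param curve A `km_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  readr::write_csv(tibble::tibble(time = curve$time, survival = curve$survival),
                   path, progress = FALSE)
  invisible(path)
}

abort_rmstgain <- function(message) {
  rlang::abort(message, class = "rmstgain_error")
}
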