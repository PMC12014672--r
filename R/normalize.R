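#' Construct a PWT time course
#'
#' Bundles one animal-by-session paw withdrawal threshold series on the
#' 15-min assessment grid. The grid runs from 0 (pre-stimulation
#' baseline) through `t_stim` minutes of stimulation plus 30 min
#' post-stimulation, i.e. `0, 15, ..., t_stim + 30`: 7 observations for a
#' 60-min session and 9 for a 90-min session.
#'
#' @param pwt paw withdrawal thresholds in grams, one per timepoint; all > 0.
#' @param t_stim stimulation-on duration in minutes (60 or 90 in the
#'   designs modelled here; other positive values are accepted with a
#'   warning).
#' @param times observation times in minutes; defaults to the standard
#'   grid `seq(0, t_stim + 30, by = 15)`.
#' @param animal_id,pattern,cohort optional design metadata carried along
#'   to fit tables.
#' @return An object of class `"pwt_timecourse"`.
#' @examples
#' tc <- pwt_timecourse(c(6, 6, 12, 12, 12, 9, 6), t_stim = 60)
#' normalize_timecourse(tc)
#' @export
pwt_timecourse <- function(pwt, t_stim, times = NULL, animal_id = NA_character_,
                           pattern = NA_character_, cohort = NA_integer_) {
  if (!is.numeric(t_stim) || length(t_stim) != 1L || !is.finite(t_stim) ||
      t_stim <= 0) {
    stop_scs("`t_stim` must be a single positive duration", "invalid_input")
  }
  if (is.null(times)) times <- seq(0, t_stim + 30, by = 15)
  if (!is.numeric(times) || any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    stop_scs("`times` must be a strictly increasing finite numeric grid",
             "invalid_input")
  }
  if (length(pwt) != length(times)) {
    stop_scs("`pwt` and `times` must have the same length", "invalid_input")
  }
  if (!is.numeric(pwt) || any(!is.finite(pwt)) || any(pwt <= 0)) {
    stop_scs("`pwt` must be finite and positive (grams)", "invalid_input")
  }
  structure(
    list(animal_id = animal_id, pattern = pattern, cohort = cohort,
         t_stim = t_stim, times = as.numeric(times), pwt = as.numeric(pwt)),
    class = "pwt_timecourse"
  )
}

#' @export
print.pwt_timecourse <- function(x, ...) {
  cat(sprintf("PWT time course: animal %s, pattern %s, T_stim = %g min\n",
              x$animal_id, x$pattern, x$t_stim))
  print(data.frame(time_min = x$times, pwt_g = x$pwt), row.names = FALSE)
  invisible(x)
}

#' Baseline-normalize a PWT time course
#'
#' Converts grams to the unitless relative change from the
#' pre-stimulation baseline:
#' \deqn{f_{target}(t) = [PWT(t) - PWT(0)] / PWT(0)}
#' The first element is exactly 0 by construction, and multiplying the
#' raw series by any positive constant leaves the result unchanged, so
#' baseline differences across animals cancel. Typical responses fall in
#' (0, 2) on this scale.
#'
#' @param tc a [pwt_timecourse()], or a numeric vector of PWT values in
#'   grams whose first element is the `t = 0` baseline.
#' @param times observation times; only used (and required to start at 0)
#'   when `tc` is a bare numeric vector.
#' @return An object of class `"pwt_normalized"`: list with `times`,
#'   `f_target` and `baseline_pwt` (g).
#' @export
normalize_timecourse <- function(tc, times = NULL) {
  if (inherits(tc, "pwt_timecourse")) {
    times <- tc$times
    pwt <- tc$pwt
  } else {
    pwt <- as.numeric(tc)
    if (is.null(times)) times <- seq_along(pwt) * 15 - 15
  }
  if (length(times) != length(pwt)) {
    stop_scs("`times` and PWT series must have the same length", "invalid_input")
  }
  if (!isTRUE(times[1] == 0)) {
    stop_scs("the series must include the t = 0 baseline observation",
             "invalid_input")
  }
  b <- pwt[1]
  if (!is.finite(b) || b <= 0) {
    stop_scs("baseline PWT(0) must be positive", "degenerate_baseline")
  }
  structure(
    list(times = as.numeric(times), f_target = (pwt - b) / b, baseline_pwt = b),
    class = "pwt_normalized"
  )
}

#' @export
print.pwt_normalized <- function(x, digits = 4, ...) {
  cat(sprintf("Normalized PWT time course (baseline %.3g g):\n", x$baseline_pwt))
  print(data.frame(time_min = x$times, f_target = round(x$f_target, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Percent deviation of a fit from its target
#'
#' Fit-quality measure used for exclusion decisions: the residual power
#' relative to the signal power of the normalized target,
#' \deqn{Dev\% = 100 \sum_i (f_{fit,i} - f_{target,i})^2 /
#'                    \sum_i f_{target,i}^2}
#' A perfect fit gives 0; a null (all-zero) fit gives 100.
#'
#' @param fit_values fitted values on the observation grid (unitless).
#' @param target_values normalized target values (unitless).
#' @return Percent deviation (scalar, >= 0).
#' @export
percent_deviation <- function(fit_values, target_values) {
  if (length(fit_values) != length(target_values)) {
    stop_scs("fit and target series must have equal length", "invalid_input")
  }
  ssr <- sum(target_values^2)
  if (ssr == 0) {
    stop_scs("target is identically zero: percent deviation undefined (SSR = 0)",
             "undefined_deviation")
  }
  100 * sum((fit_values - target_values)^2) / ssr
}
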