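#' Double-sigmoid model parameters
#'
#' Constructs and validates the five parameters of the double-sigmoid
#' response model: a scaling factor `I` (unitless, the magnitude of the
#' normalized PWT reversal), the steepness of the ramp-up and wind-down
#' phases `a1` and `a2` (1/min), and the half-rise and half-decay times
#' `t_mid1` and `t_mid2` (min). The canonical forward model has
#' `I > 0`, `a1 > 0`, `a2 < 0`, but any finite signs are accepted: the
#' fit is unconstrained and sign information is used downstream by the
#' quality-control rules.
#'
#' @param I unitless scaling factor.
#' @param a1 ramp-up steepness, 1/min.
#' @param a2 wind-down steepness, 1/min (negative in the canonical model).
#' @param t_mid1 half-rise time, min.
#' @param t_mid2 half-decay time, min.
#'
#' @return An object of class `"sigmoid_params"`: a named list with the
#'   five components above.
#' @examples
#' p <- sigmoid_params(I = 1, a1 = 0.5, a2 = -0.5, t_mid1 = 15, t_mid2 = 75)
#' double_sigmoid(seq(0, 90, by = 15), p)
#' @export
sigmoid_params <- function(I, a1, a2, t_mid1, t_mid2) {
  vals <- c(I = I, a1 = a1, a2 = a2, t_mid1 = t_mid1, t_mid2 = t_mid2)
  if (length(vals) != 5L || !is.numeric(vals) || any(!is.finite(vals))) {
    stop_scs("all five sigmoid parameters must be finite numeric scalars",
             "invalid_input")
  }
  structure(as.list(vals), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, digits = 4, ...) {
  cat("Double-sigmoid parameters:\n")
  print(round(unlist(x), digits))
  invisible(x)
}

#' @export
as.numeric.sigmoid_params <- function(x, ...) unlist(x)

# Coerce a sigmoid_params object, named list or numeric vector of length 5
# (order I, a1, a2, t_mid1, t_mid2) to the internal parameter vector.
par_vec <- function(p) {
  if (inherits(p, "sigmoid_params")) return(unlist(p))
  v <- unlist(p)
  if (length(v) != 5L) {
    stop_scs("expected 5 parameters (I, a1, a2, t_mid1, t_mid2)",
             "invalid_input")
  }
  nm <- c("I", "a1", "a2", "t_mid1", "t_mid2")
  if (!is.null(names(v)) && all(nm %in% names(v))) v <- v[nm]
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop_scs("sigmoid parameters must be finite", "invalid_input")
  }
  names(v) <- nm
  v
}

#' Evaluate the double-sigmoid response model
#'
#' The model is the product of two logistic terms scaled by `I`:
#' \deqn{f(t) = I \frac{1}{1+e^{-a_1(t - t_{mid1})}}
#'              \frac{1}{1+e^{-a_2(t - t_{mid2})}}}
#' With `a1 > 0` and `a2 < 0` this describes a biphasic response that
#' ramps up around `t_mid1` and winds down around `t_mid2`, as a
#' stimulation-induced PWT reversal does after stimulation onset and
#' offset. Evaluation uses the numerically stable logistic
#' ([stats::plogis()]), so extreme steepness never overflows.
#'
#' @param t time(s) in minutes; finite numeric vector.
#' @param params a [sigmoid_params()] object (or coercible 5-vector).
#' @return Numeric vector of unitless responses, bounded between 0 and `I`.
#' @seealso [double_sigmoid_deriv()], [slopes_at_midpoints()]
#' @export
double_sigmoid <- function(t, params) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_scs("`t` must be finite numeric", "invalid_input")
  }
  p <- par_vec(params)
  p[["I"]] * stats::plogis(p[["a1"]] * (t - p[["t_mid1"]])) *
    stats::plogis(p[["a2"]] * (t - p[["t_mid2"]]))
}

#' Analytic first derivative of the double-sigmoid model
#'
#' Closed form of \eqn{f'(t)}: with \eqn{S_k(t) = 1/(1+e^{-a_k(t-t_{midk})})},
#' \deqn{f'(t) = I [a_1 S_1(1-S_1) S_2 + a_2 S_2(1-S_2) S_1]}
#' in units 1/min. The wash-in and wash-out rates reported by the package
#' are this derivative evaluated at `t_mid1` and `t_mid2`.
#'
#' @inheritParams double_sigmoid
#' @return Numeric vector of rates (1/min).
#' @export
double_sigmoid_deriv <- function(t, params) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_scs("`t` must be finite numeric", "invalid_input")
  }
  p <- par_vec(params)
  q1 <- p[["a1"]] * (t - p[["t_mid1"]])
  q2 <- p[["a2"]] * (t - p[["t_mid2"]])
  s1 <- stats::plogis(q1)
  s2 <- stats::plogis(q2)
  # S(1-S) computed as plogis(q) * plogis(-q): stable in both tails
  d1 <- s1 * stats::plogis(-q1)
  d2 <- s2 * stats::plogis(-q2)
  p[["I"]] * (p[["a1"]] * d1 * s2 + p[["a2"]] * d2 * s1)
}

#' Wash-in and wash-out slopes at the curve midpoints
#'
#' Evaluates the analytic derivative of the double-sigmoid at the two
#' midpoint times. `slope1 = f'(t_mid1)` quantifies the wash-in rate of
#' the analgesic effect and `slope2 = f'(t_mid2)` the wash-out rate, both
#' in 1/min on the normalized (unitless) response scale. When the two
#' phases are well separated these approach `I*a1/4` and `I*a2/4`; for
#' overlapping phases the product form makes them shallower, which is why
#' the steepness parameters themselves are not reported as rates.
#'
#' @inheritParams double_sigmoid
#' @return Named numeric vector `c(slope1 = , slope2 = )`, 1/min.
#' @export
slopes_at_midpoints <- function(params) {
  p <- par_vec(params)
  c(slope1 = double_sigmoid_deriv(p[["t_mid1"]], p),
    slope2 = double_sigmoid_deriv(p[["t_mid2"]], p))
}

#' Normalized full-width-half-maximum of the response
#'
#' Operational FWHM of the fitted response: the time between the
#' half-rise and half-decay midpoints, expressed as a fraction of the
#' stimulation-on duration, `(t_mid2 - t_mid1) / T_stim`. A value of 1
#' means the response stayed above half maximum for exactly the length of
#' the stimulation. Note this is the midpoint-spacing definition, not a
#' literal level crossing of `f(t) = I/2`; for well-separated steep
#' phases the two coincide. A negative value indicates an inverted fit
#' (`t_mid2 < t_mid1`) and is flagged upstream rather than rejected here.
#'
#' @inheritParams double_sigmoid
#' @param t_stim stimulation-on duration in minutes (> 0).
#' @return Unitless fraction of the stimulation duration.
#' @export
fwhm_normalized <- function(params, t_stim) {
  if (!is.numeric(t_stim) || length(t_stim) != 1L || !is.finite(t_stim) ||
      t_stim <= 0) {
    stop_scs("`t_stim` must be a single positive duration in minutes",
             "invalid_input")
  }
  p <- par_vec(params)
  (p[["t_mid2"]] - p[["t_mid1"]]) / t_stim
}

# Classed error helper so callers/tests can distinguish failure modes.
stop_scs <- function(message, class) {
  stop(structure(
    class = c(paste0("scskinetics_", class), "scskinetics_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
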