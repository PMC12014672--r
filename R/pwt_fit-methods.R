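#' @export
print.pwt_fit <- function(x, digits = 4, ...) {
  cat("Double-sigmoid PWT fit")
  if (!is.na(x$animal_id %||% NA)) {
    cat(sprintf(" (animal %s, pattern %s)", x$animal_id, x$pattern))
  }
  cat("\n")
  print(round(unlist(x$params), digits))
  cat(sprintf("SSD = %.4g, Dev%% = %.3g, converged: %s\n",
              x$ssd, x$dev_pct, x$converged))
  invisible(x)
}

#' @export
summary.pwt_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pwt_fit")
}

#' @export
print.summary.pwt_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("slope1 = %.4g 1/min, slope2 = %.4g 1/min, FWHM = %.4g\n",
              f$slope1, f$slope2, f$fwhm_norm))
  cat(sprintf("n = %d points, T_stim = %g min, baseline = %.3g g\n",
              f$n_points, f$t_stim, f$baseline_pwt %||% NA_real_))
  if (!is.null(f$qc)) print(f$qc)
  if (f$inverted) cat("warning: inverted midpoints (t_mid2 < t_mid1)\n")
  invisible(x)
}

#' @export
coef.pwt_fit <- function(object, ...) unlist(object$params)

#' @export
deviance.pwt_fit <- function(object, ...) object$ssd

#' @export
fitted.pwt_fit <- function(object, ...) object$fitted

#' @export
residuals.pwt_fit <- function(object, ...) object$f_target - object$fitted

#' Predict the fitted normalized response at new times
#'
#' @param object a `"pwt_fit"`.
#' @param newdata numeric vector of times (min), or a data frame with a
#'   `time_min` column; defaults to the observation grid.
#' @param ... unused.
#' @return Unitless fitted response values.
#' @export
predict.pwt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  t <- if (is.data.frame(newdata)) newdata$time_min else as.numeric(newdata)
  double_sigmoid(t, object$params)
}

#' Simulate new normalized response series from a fitted model
#'
#' Draws replicate unitless target series on the observation grid: the
#' fitted curve plus Gaussian noise with standard deviation equal to the
#' fit's residual standard deviation.
#'
#' @param object a `"pwt_fit"`.
#' @param nsim number of replicate series.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return A data frame with one column per replicate, `seed` attribute set.
#' @export
simulate.pwt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  n <- object$n_points
  sigma <- sqrt(object$ssd / max(1, n - 5))
  out <- as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(n, 0, sigma), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "seed") <- seed
  out
}

#' Plot a fitted PWT time course
#'
#' Observed normalized response (points) with the fitted double-sigmoid
#' curve and the two midpoint times.
#'
#' @param x a `"pwt_fit"`.
#' @param ... additional arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pwt_fit <- function(x, ...) {
  tg <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::plot(x$times, x$f_target, pch = 19,
                 xlab = "time (min)", ylab = "normalized PWT change",
                 ylim = range(c(x$f_target, double_sigmoid(tg, x$params))), ...)
  graphics::lines(tg, double_sigmoid(tg, x$params), col = "steelblue", lwd = 2)
  graphics::abline(v = c(x$params$t_mid1, x$params$t_mid2),
                   lty = 3, col = "grey50")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
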