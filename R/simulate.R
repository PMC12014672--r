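#' Default generative kinetics per stimulation pattern
#'
#' Ground-truth kinetics used by the study simulator, one row per
#' stimulation pattern. Midpoints are expressed as fractions of the
#' stimulation duration so that a 60-min and a 90-min session share the
#' same shape: `t_mid1 = f_mid1 * T_stim` and
#' `t_mid2 = t_mid1 + w_fwhm * T_stim`. The defaults encode the
#' qualitative structure of the study system: tonic stimulation washes
#' in fastest and begins to lose effect while still stimulating
#' (`w_fwhm < 1`, emulating tolerance phenomenologically), whereas the
#' four time-dynamic patterns (TDPs) ramp in more slowly and hold their
#' effect beyond the stimulation window (`w_fwhm > 1`, slow wind-down).
#' Maximum reversals are on the gram scale of the study system (baseline
#' about 6 g rising to 9-12 g during stimulation). Exact values are
#' simulator configuration, not empirical claims.
#'
#' @return A data frame with columns `pattern`, `a1`, `a2` (1/min),
#'   `f_mid1`, `w_fwhm` (fractions of `T_stim`) and `max_reversal_g`.
#' @export
default_pattern_params <- function() {
  data.frame(
    pattern = c("tonic", "amplitude", "pulse_width", "rate", "stochastic"),
    a1 = c(1.20, 0.085, 0.095, 0.110, 0.095),
    a2 = c(-1.00, -0.22, -0.25, -0.24, -0.23),
    f_mid1 = c(0.15, 0.36, 0.35, 0.35, 0.36),
    w_fwhm = c(0.79, 0.90, 0.93, 0.92, 0.91),
    max_reversal_g = c(5.8, 3.6, 4.4, 4.4, 4.0),
    stringsAsFactors = FALSE
  )
}

#' Conventional von Frey filament force set
#'
#' Ascending filament forces in grams with a 15 g ceiling, used when
#' simulated thresholds are quantized to the discrete measurement scale.
#' @return Numeric vector of grams, strictly increasing.
#' @export
default_filament_set <- function() c(0.4, 0.6, 1, 2, 4, 6, 8, 10, 15)

#' Configuration for a simulated crossover study
#'
#' Describes a five-pattern randomized crossover design: each animal
#' receives one session per pattern (tonic plus four TDPs) in a random
#' order, with per-animal baselines drawn from a truncated normal and
#' additive Gaussian behavioural noise on the gram scale. Cohort 1
#' animals are stimulated for 60 min (7 observations), cohort 2 for
#' 90 min (9 observations); the default design has 8 + 15 = 23 animals.
#'
#' @param n_animals number of animals (>= 1).
#' @param cohort cohort label per animal (1 or 2), recycled/truncated to
#'   `n_animals`. Default: 8 animals in cohort 1, the rest in cohort 2.
#' @param baseline_mean,baseline_sd baseline PWT distribution, grams.
#' @param noise_sd additive measurement noise on grams.
#' @param patterns generative kinetics table as in
#'   [default_pattern_params()].
#' @param quantize snap simulated thresholds to `filament_set`?
#' @param filament_set ascending filament forces (g); top value is the
#'   measurement ceiling.
#' @param seed master seed; every random stream of the simulation derives
#'   from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_animals = 23,
                              cohort = NULL,
                              baseline_mean = 6, baseline_sd = 0.8,
                              noise_sd = 1,
                              patterns = default_pattern_params(),
                              quantize = FALSE,
                              filament_set = default_filament_set(),
                              seed = 1L) {
  if (!is.numeric(n_animals) || n_animals < 1) {
    stop_scs("`n_animals` must be >= 1", "invalid_input")
  }
  n_animals <- as.integer(n_animals)
  if (is.null(cohort)) {
    cohort <- c(rep(1L, min(8L, n_animals)),
                rep(2L, max(0L, n_animals - 8L)))
  }
  cohort <- as.integer(rep_len(cohort, n_animals))
  if (!all(cohort %in% c(1L, 2L))) {
    stop_scs("`cohort` entries must be 1 or 2", "invalid_input")
  }
  if (baseline_mean <= 0) stop_scs("`baseline_mean` must be > 0 g", "invalid_input")
  if (noise_sd < 0) stop_scs("`noise_sd` must be >= 0", "invalid_input")
  need <- c("pattern", "a1", "a2", "f_mid1", "w_fwhm", "max_reversal_g")
  if (!is.data.frame(patterns) || !all(need %in% names(patterns))) {
    stop_scs("`patterns` must have columns pattern, a1, a2, f_mid1, w_fwhm, max_reversal_g",
             "invalid_input")
  }
  if (is.unsorted(filament_set, strictly = TRUE)) {
    stop_scs("`filament_set` must be strictly increasing", "invalid_input")
  }
  structure(
    list(n_animals = n_animals, cohort = cohort,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         noise_sd = noise_sd, patterns = patterns,
         quantize = isTRUE(quantize), filament_set = filament_set,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate one PWT time course from known kinetics
#'
#' Forward model inverting the baseline normalization:
#' `PWT(t) = baseline + max_reversal * f_unit(t) + noise`, where
#' `f_unit` is the double sigmoid with unit scaling. Noise is additive
#' Gaussian on the gram scale (measurement noise acts on the behavioural
#' readout, not the normalized response). Optionally each value is
#' snapped to the nearest von Frey filament force and capped at the top
#' filament. Values are floored at 0.1 g so a threshold is always
#' physically positive. Randomness uses the caller's RNG state.
#'
#' @param params unit-scale kinetics: a [sigmoid_params()] with `I = 1`
#'   (any supplied `I` is overridden) giving `a1`, `a2`, `t_mid1`,
#'   `t_mid2` in absolute minutes.
#' @param baseline pre-stimulation PWT, grams (> 0).
#' @param max_reversal maximum PWT reversal, grams (0 for no response).
#' @param t_stim stimulation-on duration, min.
#' @param grid observation times; defaults to `seq(0, t_stim + 30, 15)`.
#' @param noise_sd Gaussian noise SD, grams.
#' @param quantize,filament_set see [simulation_config()].
#' @param animal_id,pattern,cohort metadata carried into the time course.
#' @return A [pwt_timecourse()].
#' @export
simulate_timecourse <- function(params, baseline, max_reversal, t_stim,
                                grid = NULL, noise_sd = 0,
                                quantize = FALSE,
                                filament_set = default_filament_set(),
                                animal_id = NA_character_,
                                pattern = NA_character_,
                                cohort = NA_integer_) {
  if (!is.numeric(baseline) || baseline <= 0) {
    stop_scs("`baseline` must be positive grams", "invalid_input")
  }
  if (is.null(grid)) grid <- seq(0, t_stim + 30, by = 15)
  if (!is.numeric(grid) || any(!is.finite(grid)) || grid[1] != 0) {
    stop_scs("`grid` must be a finite time grid starting at 0", "invalid_input")
  }
  p <- par_vec(params)
  p[["I"]] <- 1
  pwt <- baseline + max_reversal * double_sigmoid(grid, p) +
    stats::rnorm(length(grid), 0, noise_sd)
  if (isTRUE(quantize)) {
    pwt <- pmin(pwt, max(filament_set))
    idx <- vapply(pwt, function(v) which.min(abs(filament_set - v)), 1L)
    pwt <- filament_set[idx]
  }
  pwt <- pmax(pwt, 0.1)
  pwt_timecourse(pwt, t_stim = t_stim, times = grid,
                 animal_id = animal_id, pattern = pattern, cohort = cohort)
}

#' Simulate a complete crossover study
#'
#' Generates one time course per animal x pattern under the design in
#' `cfg`. Per-animal baselines are drawn from
#' `Normal(baseline_mean, baseline_sd^2)` truncated above 1 g, and every
#' animal gets an independent random session order over the five
#' patterns. Each animal has its own random stream derived from the
#' master seed, so enlarging the study never perturbs the data of
#' existing animals, and the whole dataset is reproducible from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `"pwt_study"`: list with
#'   \describe{
#'     \item{data}{long data frame (`animal_id`, `pattern`, `cohort`,
#'       `t_stim_min`, `time_min`, `pwt_g`), one row per observation;}
#'     \item{truth}{per-time-course generative parameters (absolute-time
#'       midpoints, steepnesses, baseline, reversal) for recovery tests;}
#'     \item{session_orders}{per-animal permutation of the patterns;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_study <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) {
    stop_scs("`cfg` must be a simulation_config()", "invalid_input")
  }
  set.seed(cfg$seed)
  animal_seeds <- sample.int(2147483646L, cfg$n_animals)
  pat <- cfg$patterns
  rows <- vector("list", cfg$n_animals)
  truth <- vector("list", cfg$n_animals)
  orders <- vector("list", cfg$n_animals)
  for (i in seq_len(cfg$n_animals)) {
    set.seed(animal_seeds[i])
    id <- sprintf("A%02d", i)
    t_stim <- if (cfg$cohort[i] == 1L) 60 else 90
    # truncated normal baseline, > 1 g
    repeat {
      b <- stats::rnorm(1, cfg$baseline_mean, cfg$baseline_sd)
      if (b > 1) break
    }
    ord <- sample(pat$pattern)
    orders[[i]] <- data.frame(animal_id = id, session = seq_along(ord),
                              pattern = ord, stringsAsFactors = FALSE)
    arows <- vector("list", nrow(pat))
    atruth <- vector("list", nrow(pat))
    for (k in seq_along(ord)) {
      pk <- pat[pat$pattern == ord[k], ]
      t1 <- pk$f_mid1 * t_stim
      t2 <- t1 + pk$w_fwhm * t_stim
      gp <- sigmoid_params(1, pk$a1, pk$a2, t1, t2)
      tc <- simulate_timecourse(gp, baseline = b,
                                max_reversal = pk$max_reversal_g,
                                t_stim = t_stim, noise_sd = cfg$noise_sd,
                                quantize = cfg$quantize,
                                filament_set = cfg$filament_set,
                                animal_id = id, pattern = pk$pattern,
                                cohort = cfg$cohort[i])
      arows[[k]] <- data.frame(
        animal_id = id, pattern = pk$pattern, cohort = cfg$cohort[i],
        t_stim_min = t_stim, time_min = tc$times, pwt_g = tc$pwt,
        stringsAsFactors = FALSE)
      atruth[[k]] <- data.frame(
        animal_id = id, pattern = pk$pattern, cohort = cfg$cohort[i],
        t_stim_min = t_stim, session = k, baseline_g = b,
        max_reversal_g = pk$max_reversal_g, a1 = pk$a1, a2 = pk$a2,
        t_mid1 = t1, t_mid2 = t2, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, arows)
    truth[[i]] <- do.call(rbind, atruth)
  }
  structure(
    list(data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         session_orders = do.call(rbind, c(orders, list(make.row.names = FALSE))),
         config = cfg),
    class = "pwt_study"
  )
}

#' @export
print.pwt_study <- function(x, ...) {
  n_tc <- nrow(unique(x$data[c("animal_id", "pattern")]))
  cat(sprintf("Simulated PWT crossover study: %d animals, %d time courses (%d rows)\n",
              x$config$n_animals, n_tc, nrow(x$data)))
  cat(sprintf("cohorts: %d x 60 min, %d x 90 min; noise_sd = %g g; seed = %d\n",
              sum(x$config$cohort == 1L), sum(x$config$cohort == 2L),
              x$config$noise_sd, x$config$seed))
  invisible(x)
}

#' Coerce a long PWT data frame to a study object
#'
#' Wraps already-collected (or externally loaded) long-format PWT data in
#' the container the analysis functions expect. Ground truth and session
#' orders are unknown for real data and left `NULL`.
#'
#' @param data data frame with columns `animal_id`, `pattern`, `cohort`,
#'   `t_stim_min`, `time_min`, `pwt_g`.
#' @return A `"pwt_study"`.
#' @export
as_pwt_study <- function(data) {
  validate_pwt_data(data)
  structure(list(data = data, truth = NULL, session_orders = NULL,
                 config = NULL),
            class = "pwt_study")
}
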