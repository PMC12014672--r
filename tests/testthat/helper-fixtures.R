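# Shared fixtures and oracles, built in code at test time.

# central-difference derivative oracle (independent of the analytic path)
num_deriv <- function(t, p, h = 1e-4) {
  (double_sigmoid(t + h, p) - double_sigmoid(t - h, p)) / (2 * h)
}

# fixed parameter test set spanning signs, overlap and steepness regimes
oracle_param_grid <- function() {
  list(
    sigmoid_params(1, 0.5, -0.5, 15, 75),
    sigmoid_params(1, 0.5, -0.5, 22.5, 112.5),
    sigmoid_params(1.2, 0.4, -0.3, 20, 80),
    sigmoid_params(0.8, 0.1, -0.1, 30, 90),
    sigmoid_params(2, 1.5, -1.2, 10, 50),
    sigmoid_params(0.5, 0.05, -0.2, 40, 70),
    sigmoid_params(-0.5, 0.5, -0.5, 15, 75),
    sigmoid_params(1, 0.3, -0.6, 25, 60),
    sigmoid_params(1, 0.9, -0.05, 12, 100),
    sigmoid_params(1.5, 0.25, -0.25, 50, 55),
    sigmoid_params(1, 0.5, -0.5, 60, 40),
    sigmoid_params(0.3, 2, -2, 18, 95),
    sigmoid_params(1, 0.15, -0.35, 5, 110),
    sigmoid_params(1, 0.7, -0.7, 33, 66),
    sigmoid_params(-1.2, 0.2, -0.4, 28, 82),
    sigmoid_params(1, 0.45, -0.15, 45, 45),
    sigmoid_params(0.9, 1.1, -0.9, 8, 115),
    sigmoid_params(1.1, 0.35, -0.55, 37, 73),
    sigmoid_params(0.6, 0.6, -0.1, 21, 88),
    sigmoid_params(1.3, 0.12, -0.8, 55, 100)
  )
}

# noiseless normalized time course from known parameters
make_ntc <- function(params, times) {
  structure(list(times = times, f_target = double_sigmoid(times, params),
                 baseline_pwt = 6),
            class = "pwt_normalized")
}

grid9 <- seq(0, 120, by = 15)
grid7 <- seq(0, 90, by = 15)

# small long-format study data frame built by hand (2 animals, 2 patterns)
tiny_study_df <- function() {
  expand_one <- function(animal, pattern, pwt) {
    data.frame(animal_id = animal, pattern = pattern, cohort = 1L,
               t_stim_min = 60, time_min = grid7, pwt_g = pwt,
               stringsAsFactors = FALSE)
  }
  rbind(expand_one("r1", "tonic", c(6, 7, 11, 11.5, 11, 8, 6.5)),
        expand_one("r1", "amplitude", c(6, 6.5, 9, 10, 10, 8.5, 7)),
        expand_one("r2", "tonic", c(5.5, 7, 10.5, 11, 10.5, 7.5, 6)),
        expand_one("r2", "amplitude", c(6.5, 7, 9.5, 10.5, 10, 9, 7.5)))
}
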