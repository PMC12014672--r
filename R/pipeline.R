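#' Run the full analysis pipeline
#'
#' End-to-end chain: load (or simulate) a crossover PWT dataset, fit the
#' double-sigmoid to every time course, apply the exclusion rules,
#' summarize per pattern, and run the comparison structure
#' (timepoint-vs-baseline per pattern, TDP-vs-tonic per timepoint,
#' extended-period degradation on the 90-min cohort, slope contrasts and
#' the omnibus tests). All artifacts are written to `out_dir` as CSV plus
#' a JSON run manifest; the run is deterministic for a fixed input (or
#' simulation seed).
#'
#' @param input a `"pwt_study"`, a long-format data frame, a CSV path
#'   (see [read_pwt_csv()]), or `NULL` to simulate from `sim_config`.
#' @param sim_config [simulation_config()] used when `input` is `NULL`.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param alpha significance level for every comparison.
#' @param dev_max,i_min QC thresholds (percent deviation; minimum scale).
#' @param control optimizer settings ([fit_control()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `study`, `fits`, `summary`
#'   ([summarize_patterns()]), `comparisons` (one tidy data frame),
#'   `omnibus`, and `paths` of the written artifacts. Artifacts:
#'   `pwt_data.csv` (input data), `fits.csv` (per-time-course fit + QC
#'   table), `pattern_summary.csv`, `pwt_summary.csv`,
#'   `comparisons.csv`, `manifest.json` (config, seed, thresholds,
#'   package version), `optimizer_settings.json`.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config = simulation_config(n_animals = 6, seed = 7),
#'                     out_dir = tempfile("pwt_run_"))
#' res$summary$metrics
#' }
#' @export
run_pipeline <- function(input = NULL, sim_config = simulation_config(),
                         out_dir = NULL, alpha = 0.05,
                         dev_max = 50, i_min = 0.1,
                         control = fit_control(), quiet = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop_scs("`alpha` must be in (0, 1)", "invalid_input")
  if (dev_max <= 0 || i_min <= 0) {
    stop_scs("QC thresholds must be positive", "invalid_input")
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  study <- if (is.null(input)) {
    say("simulating study (n = %d animals, seed = %d)",
        sim_config$n_animals, sim_config$seed)
    simulate_study(sim_config)
  } else if (inherits(input, "pwt_study")) {
    input
  } else if (is.character(input)) {
    say("reading %s", input)
    read_pwt_csv(input)
  } else {
    as_pwt_study(input)
  }

  say("fitting %d time courses",
      nrow(unique(study$data[c("animal_id", "pattern")])))
  fits <- fit_study(study, control = control, dev_max = dev_max, i_min = i_min)
  summ <- summarize_patterns(fits, study)

  pats <- unique(study$data$pattern)
  comp <- list()
  for (p in pats) {
    comp[[length(comp) + 1L]] <- timepoint_vs_baseline(study, p, alpha = alpha)
  }
  if ("tonic" %in% pats) {
    for (t in c(15, 30, 45, 60)) {
      comp[[length(comp) + 1L]] <- pattern_vs_tonic(study, t, alpha = alpha)
    }
  }
  if (any(study$data$cohort == 2)) {
    for (p in pats) {
      comp[[length(comp) + 1L]] <- extended_period_test(study, p, alpha = alpha)
    }
  }
  comparisons <- do.call(rbind, c(comp, list(make.row.names = FALSE)))
  slopes <- if ("tonic" %in% pats) {
    slope_contrasts(fits, metrics = c("slope1", "slope2", "fwhm_norm"),
                    alpha = alpha)
  } else NULL
  if (!is.null(slopes)) {
    sl <- data.frame(contrast = slopes$contrast,
                     pattern = paste(slopes$pattern, slopes$metric, sep = ":"),
                     time_min = NA_real_, n = slopes$n,
                     estimate = slopes$estimate, statistic = slopes$statistic,
                     p_value = slopes$p_value, significant = slopes$significant,
                     degenerate = FALSE, stringsAsFactors = FALSE)
    comparisons <- rbind(comparisons, sl)
  }
  omni <- omnibus_tests(study, fits)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      data = file.path(out_dir, "pwt_data.csv"),
      truth = file.path(out_dir, "truth.csv"),
      fits = file.path(out_dir, "fits.csv"),
      pattern_summary = file.path(out_dir, "pattern_summary.csv"),
      pwt_summary = file.path(out_dir, "pwt_summary.csv"),
      comparisons = file.path(out_dir, "comparisons.csv"),
      manifest = file.path(out_dir, "manifest.json"),
      optimizer = file.path(out_dir, "optimizer_settings.json"))
    utils::write.csv(study$data, paths$data, row.names = FALSE)
    if (!is.null(study$truth)) {
      utils::write.csv(study$truth, paths$truth, row.names = FALSE)
    } else {
      paths$truth <- NULL
    }
    utils::write.csv(fits, paths$fits, row.names = FALSE)
    utils::write.csv(summ$metrics, paths$pattern_summary, row.names = FALSE)
    if (!is.null(summ$pwt)) {
      utils::write.csv(summ$pwt, paths$pwt_summary, row.names = FALSE)
    }
    utils::write.csv(comparisons, paths$comparisons, row.names = FALSE)
    manifest <- list(
      package = "scskinetics",
      version = as.character(utils::packageVersion("scskinetics")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      input = if (is.character(input)) input else
        if (is.null(input)) "simulated" else "in-memory",
      seed = if (is.null(input)) sim_config$seed else NA,
      n_timecourses = nrow(fits), n_excluded = sum(fits$excluded),
      alpha = alpha, dev_max = dev_max, i_min = i_min,
      sim_config = if (is.null(input)) {
        sc <- sim_config
        sc$patterns <- as.list(sc$patterns)
        unclass(sc)
      } else NULL)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    jsonlite::write_json(unclass(control), paths$optimizer, auto_unbox = TRUE,
                         pretty = TRUE)
    say("artifacts written to %s", out_dir)
  }
  invisible(list(study = study, fits = fits, summary = summ,
                 comparisons = comparisons, slope_contrasts = slopes,
                 omnibus = omni, paths = paths))
}
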