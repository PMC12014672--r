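pwt_csv_columns <- c("animal_id", "pattern", "cohort", "t_stim_min",
                     "time_min", "pwt_g")

# Schema validation with errors that name the offending column/row.
validate_pwt_data <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    stop_scs("PWT dataset is empty", "schema")
  }
  miss <- setdiff(pwt_csv_columns, names(df))
  if (length(miss)) {
    stop_scs(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
             "schema")
  }
  for (col in c("cohort", "t_stim_min", "time_min", "pwt_g")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop_scs(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]),
               "schema")
    }
  }
  bad <- which(df$pwt_g <= 0)
  if (length(bad)) {
    stop_scs(sprintf("non-positive pwt_g at row %d", bad[1]), "schema")
  }
  invisible(df)
}

#' Read a long-format PWT dataset from CSV
#'
#' Expects a header with columns `animal_id`, `pattern`, `cohort`,
#' `t_stim_min`, `time_min`, `pwt_g` (UTF-8, `.` decimal): one row per
#' animal x session x timepoint with the threshold in grams. Malformed
#' files raise a schema error naming the offending column or row.
#'
#' @param path CSV file path.
#' @return A `"pwt_study"` (see [as_pwt_study()]).
#' @export
read_pwt_csv <- function(path) {
  if (!file.exists(path)) stop_scs(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_pwt_study(df)
}

#' Write a study's long-format data to CSV
#'
#' @param study a `"pwt_study"`.
#' @param path output CSV path.
#' @param truth_path optional path for the generative truth table (if the
#'   study was simulated).
#' @return `path`, invisibly.
#' @export
write_pwt_csv <- function(study, path, truth_path = NULL) {
  utils::write.csv(study$data, path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(study$truth)) {
    utils::write.csv(study$truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Fit every time course of a study
#'
#' Runs the normalize-fit-QC chain of [fit_pwt()] on each animal x
#' pattern series and assembles one row per time course.
#'
#' @param x a `"pwt_study"` or a long-format data frame with the columns
#'   of [read_pwt_csv()].
#' @param control optimizer settings ([fit_control()]).
#' @param dev_max,i_min QC thresholds passed to [apply_exclusion()].
#' @return A data frame (one row per time course) with design metadata,
#'   the five fitted parameters, `ssd`, `ssr`, `dev_pct`, `slope1`,
#'   `slope2`, `fwhm_norm`, `converged`, `inverted`, `n_points`,
#'   `excluded` and the three QC flags.
#' @export
fit_study <- function(x, control = fit_control(), dev_max = 50, i_min = 0.1) {
  df <- if (inherits(x, "pwt_study")) x$data else x
  validate_pwt_data(df)
  keys <- unique(df[c("animal_id", "pattern")])
  out <- vector("list", nrow(keys))
  for (j in seq_len(nrow(keys))) {
    sub <- df[df$animal_id == keys$animal_id[j] & df$pattern == keys$pattern[j], ]
    sub <- sub[order(sub$time_min), ]
    tc <- pwt_timecourse(sub$pwt_g, t_stim = sub$t_stim_min[1],
                         times = sub$time_min,
                         animal_id = as.character(sub$animal_id[1]),
                         pattern = as.character(sub$pattern[1]),
                         cohort = as.integer(sub$cohort[1]))
    fit <- fit_pwt(tc, control = control)
    qc <- apply_exclusion(fit, dev_max = dev_max, i_min = i_min)
    pr <- unlist(fit$params)
    out[[j]] <- data.frame(
      animal_id = tc$animal_id, pattern = tc$pattern, cohort = tc$cohort,
      t_stim_min = tc$t_stim,
      I = pr[["I"]], a1 = pr[["a1"]], a2 = pr[["a2"]],
      t_mid1 = pr[["t_mid1"]], t_mid2 = pr[["t_mid2"]],
      ssd = fit$ssd, ssr = fit$ssr, dev_pct = fit$dev_pct,
      slope1 = fit$slope1, slope2 = fit$slope2, fwhm_norm = fit$fwhm_norm,
      converged = fit$converged, inverted = fit$inverted,
      n_points = fit$n_points,
      excluded = qc$excluded, high_deviation = qc$high_deviation,
      small_scale = qc$small_scale, negative_scale = qc$negative_scale,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "control") <- control
  attr(res, "qc_thresholds") <- c(dev_max = dev_max, i_min = i_min)
  res
}
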