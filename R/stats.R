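sem <- function(x) stats::sd(x) / sqrt(length(x))

# Paired two-sided comparison of aligned vectors (within-animal pairs).
# Zero-variance differences are reported as a degenerate result, not an error.
paired_cell <- function(x, y, alpha) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_scs(sprintf("insufficient paired data (n = %d < 3)", n),
             "insufficient_data")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(n = n, estimate = mean(d), statistic = NA_real_,
                p_value = NA_real_, significant = NA, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(n = n, estimate = unname(tt$estimate), statistic = unname(tt$statistic),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE)
}

# animal -> PWT at a single time for one pattern (named vector)
pwt_at <- function(df, pattern, t) {
  sub <- df[df$pattern == pattern & df$time_min == t, ]
  stats::setNames(sub$pwt_g, sub$animal_id)
}

comparison_row <- function(contrast, pattern, time_min, cell) {
  data.frame(contrast = contrast, pattern = pattern, time_min = time_min,
             n = cell$n, estimate = cell$estimate, statistic = cell$statistic,
             p_value = cell$p_value, significant = cell$significant,
             degenerate = cell$degenerate, stringsAsFactors = FALSE)
}

#' Compare PWT at each on-stimulation timepoint to baseline
#'
#' For one pattern, paired within-animal two-sided t-tests of `PWT(t)`
#' against the pre-stimulation baseline `PWT(0)` at each timepoint in the
#' wash-in window, aggregating both cohorts. Comparisons are deliberately
#' uncorrected (multiple comparisons without post hoc correction), with
#' significance declared at `alpha`.
#'
#' @param study a `"pwt_study"` (or long data frame).
#' @param pattern stimulation pattern to test.
#' @param timepoints times (min) to compare to baseline; default the
#'   first-hour grid `c(15, 30, 45, 60)`.
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per timepoint: `contrast`, `pattern`,
#'   `time_min`, `n`, `estimate` (mean paired difference, g),
#'   `statistic`, `p_value`, `significant`, `degenerate`.
#' @export
timepoint_vs_baseline <- function(study, pattern, timepoints = c(15, 30, 45, 60),
                                  alpha = 0.05) {
  df <- if (inherits(study, "pwt_study")) study$data else study
  if (!pattern %in% df$pattern) {
    stop_scs(paste0("pattern not present: ", pattern), "invalid_input")
  }
  base <- pwt_at(df, pattern, 0)
  rows <- lapply(timepoints, function(t) {
    v <- pwt_at(df, pattern, t)
    common <- intersect(names(v), names(base))
    cell <- paired_cell(v[common], base[common], alpha)
    comparison_row("timepoint_vs_baseline", pattern, t, cell)
  })
  do.call(rbind, rows)
}

#' Compare each TDP pattern to tonic stimulation at one timepoint
#'
#' Paired within-animal two-sided t-tests of PWT under each time-dynamic
#' pattern against PWT under tonic stimulation at the same timepoint.
#' Animals missing one of the two sessions are dropped pairwise and the
#' attained `n` is reported.
#'
#' @inheritParams timepoint_vs_baseline
#' @param t timepoint (min) at which to compare.
#' @param tonic label of the reference pattern (default `"tonic"`).
#' @return Data frame with one row per non-tonic pattern (columns as in
#'   [timepoint_vs_baseline()]; `estimate` is mean TDP - tonic, g).
#' @export
pattern_vs_tonic <- function(study, t, alpha = 0.05, tonic = "tonic") {
  df <- if (inherits(study, "pwt_study")) study$data else study
  if (!tonic %in% df$pattern) {
    stop_scs(paste0("reference pattern not present: ", tonic), "invalid_input")
  }
  ref <- pwt_at(df, tonic, t)
  tdps <- setdiff(unique(df$pattern), tonic)
  rows <- lapply(tdps, function(p) {
    v <- pwt_at(df, p, t)
    common <- intersect(names(v), names(ref))
    cell <- paired_cell(v[common], ref[common], alpha)
    comparison_row("pattern_vs_tonic", p, t, cell)
  })
  do.call(rbind, rows)
}

#' Test degradation of the effect over an extended stimulation period
#'
#' Restricted to the 90-min cohort: paired comparisons of `PWT(75)` and
#' `PWT(90)` against `PWT(60)` for one pattern, probing whether the
#' analgesic effect is maintained when stimulation is extended past an
#' hour (loss under constant stimulation is the signature of tolerance).
#'
#' @inheritParams timepoint_vs_baseline
#' @param later_times times compared against the 60-min reference.
#' @return Data frame, one row per later time; `estimate` is the mean
#'   within-animal `PWT(t) - PWT(60)` in grams, so a significant negative
#'   estimate indicates a decline.
#' @export
extended_period_test <- function(study, pattern, later_times = c(75, 90),
                                 alpha = 0.05) {
  df <- if (inherits(study, "pwt_study")) study$data else study
  df <- df[df$cohort == 2, ]
  if (nrow(df) == 0) {
    stop_scs("no cohort-2 (90-min) data available", "insufficient_data")
  }
  if (!pattern %in% df$pattern) {
    stop_scs(paste0("pattern not present in cohort 2: ", pattern),
             "invalid_input")
  }
  ref <- pwt_at(df, pattern, 60)
  rows <- lapply(later_times, function(t) {
    v <- pwt_at(df, pattern, t)
    common <- intersect(names(v), names(ref))
    cell <- paired_cell(v[common], ref[common], alpha)
    comparison_row("extended_vs_60", pattern, t, cell)
  })
  do.call(rbind, rows)
}

#' Contrast wash-in/wash-out metrics of each TDP against tonic
#'
#' Paired within-animal two-sided t-tests of the fitted temporal metrics
#' (`slope1`, `slope2`, optionally `fwhm_norm`) for each time-dynamic
#' pattern against tonic stimulation. Only QC-retained fits enter;
#' animals whose tonic or TDP fit was excluded contribute nothing to that
#' pair. A contrast with fewer than 3 complete pairs (e.g. a pattern
#' wiped out by QC) is reported as unavailable (`NA` row), never as an
#' error.
#'
#' @param fits a fit table from [fit_study()].
#' @param metrics metric columns to contrast.
#' @param alpha significance level.
#' @param tonic reference pattern label.
#' @return Data frame with one row per pattern x metric: `contrast`
#'   (`"slope_vs_tonic"`), `pattern`, `metric`, `n`, `estimate` (mean
#'   TDP - tonic), `statistic`, `p_value`, `significant`, `available`.
#' @export
slope_contrasts <- function(fits, metrics = c("slope1", "slope2"),
                            alpha = 0.05, tonic = "tonic") {
  ret <- fits[!fits$excluded, ]
  tdps <- setdiff(unique(fits$pattern), tonic)
  rows <- list()
  for (p in tdps) {
    for (m in metrics) {
      a <- ret[ret$pattern == p, ]
      b <- ret[ret$pattern == tonic, ]
      common <- intersect(a$animal_id, b$animal_id)
      x <- stats::setNames(a[[m]], a$animal_id)[common]
      y <- stats::setNames(b[[m]], b$animal_id)[common]
      row <- if (length(common) < 3) {
        data.frame(contrast = "slope_vs_tonic", pattern = p, metric = m,
                   n = length(common), estimate = NA_real_,
                   statistic = NA_real_, p_value = NA_real_,
                   significant = NA, available = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        cell <- paired_cell(x, y, alpha)
        data.frame(contrast = "slope_vs_tonic", pattern = p, metric = m,
                   n = cell$n, estimate = cell$estimate,
                   statistic = cell$statistic, p_value = cell$p_value,
                   significant = cell$significant,
                   available = TRUE, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Per-pattern summaries of fits and raw thresholds
#'
#' Mean +/- SEM of the fitted temporal metrics per pattern over
#' QC-retained fits, with fit quality (Dev\%) summarized both over all
#' fits and over retained fits, plus mean +/- SEM raw PWT per timepoint
#' per pattern.
#'
#' @param fits fit table from [fit_study()].
#' @param study optional `"pwt_study"` (or long data frame) for the raw
#'   PWT summaries.
#' @return List with two data frames: `metrics` (per pattern:
#'   `n_fitted`, `n_retained`, mean/SEM of `slope1`, `slope2`,
#'   `fwhm_norm`, `dev_pct` over retained fits, and `dev_pct_all` over
#'   all fits) and `pwt` (pattern x timepoint mean/SEM in grams; `NULL`
#'   without `study`).
#' @export
summarize_patterns <- function(fits, study = NULL) {
  if (nrow(fits) == 0) stop_scs("empty fit table", "invalid_input")
  pats <- unique(fits$pattern)
  mrows <- lapply(pats, function(p) {
    all_p <- fits[fits$pattern == p, ]
    ret <- all_p[!all_p$excluded, ]
    ms <- function(v) if (length(v)) c(mean(v), sem(v)) else c(NA_real_, NA_real_)
    s1 <- ms(ret$slope1); s2 <- ms(ret$slope2)
    fw <- ms(ret$fwhm_norm); dv <- ms(ret$dev_pct)
    dva <- ms(all_p$dev_pct)
    data.frame(pattern = p, n_fitted = nrow(all_p), n_retained = nrow(ret),
               slope1_mean = s1[1], slope1_sem = s1[2],
               slope2_mean = s2[1], slope2_sem = s2[2],
               fwhm_mean = fw[1], fwhm_sem = fw[2],
               dev_pct_mean = dv[1], dev_pct_sem = dv[2],
               dev_pct_all_mean = dva[1], dev_pct_all_sem = dva[2],
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, mrows)
  pwt <- NULL
  if (!is.null(study)) {
    df <- if (inherits(study, "pwt_study")) study$data else study
    agg_m <- stats::aggregate(pwt_g ~ pattern + time_min, df, mean)
    agg_s <- stats::aggregate(pwt_g ~ pattern + time_min, df, sem)
    agg_n <- stats::aggregate(pwt_g ~ pattern + time_min, df, length)
    pwt <- data.frame(pattern = agg_m$pattern, time_min = agg_m$time_min,
                      n = agg_n$pwt_g, pwt_mean = agg_m$pwt_g,
                      pwt_sem = agg_s$pwt_g, stringsAsFactors = FALSE)
    pwt <- pwt[order(pwt$pattern, pwt$time_min), ]
    rownames(pwt) <- NULL
  }
  list(metrics = metrics, pwt = pwt)
}

#' Omnibus tests across patterns
#'
#' The omnibus layer over the cell-level comparisons: a two-way
#' repeated-measures ANOVA of PWT on pattern and timepoint (animal as the
#' error stratum) over the first-hour window, and mixed-effects models
#' (random animal intercept, [lmerTest::lmer()]) for the fitted slope
#' metrics across patterns. These are reported for context; the
#' cell-level paired comparisons are not gated on them.
#'
#' @param study a `"pwt_study"` (or long data frame).
#' @param fits optional fit table for the slope mixed models.
#' @param window times (min) included in the PWT ANOVA.
#' @return List with `pwt_anova` (data frame of effects, F, p) and
#'   `slope_models` (data frame of pattern fixed-effect F tests per
#'   metric, `NULL` without `fits`).
#' @export
omnibus_tests <- function(study, fits = NULL, window = c(0, 15, 30, 45, 60)) {
  df <- if (inherits(study, "pwt_study")) study$data else study
  sub <- df[df$time_min %in% window, ]
  sub$animal_id <- factor(sub$animal_id)
  sub$pattern <- factor(sub$pattern)
  sub$time_f <- factor(sub$time_min)
  fit <- stats::aov(pwt_g ~ pattern * time_f + Error(animal_id), data = sub)
  tab <- summary(fit)[["Error: Within"]][[1]]
  eff <- trimws(rownames(tab))
  keep <- eff != "Residuals"
  pwt_anova <- data.frame(effect = eff[keep], df = tab$Df[keep],
                          statistic = tab$`F value`[keep],
                          p_value = tab$`Pr(>F)`[keep],
                          stringsAsFactors = FALSE)
  slope_models <- NULL
  if (!is.null(fits)) {
    ret <- fits[!fits$excluded, ]
    rows <- lapply(c("slope1", "slope2"), function(m) {
      ret$y <- ret[[m]]
      mod <- suppressMessages(lmerTest::lmer(y ~ pattern + (1 | animal_id),
                                             data = ret))
      an <- stats::anova(mod)
      data.frame(metric = m, statistic = an$`F value`[1],
                 df_num = an$NumDF[1], df_den = an$DenDF[1],
                 p_value = an$`Pr(>F)`[1], stringsAsFactors = FALSE)
    })
    slope_models <- do.call(rbind, rows)
  }
  list(pwt_anova = pwt_anova, slope_models = slope_models)
}
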