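---
title: "Double-sigmoid modelling of PWT time courses during spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-sigmoid modelling of PWT time courses during spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scskinetics)
```

## The scientific problem

Spinal cord stimulation (SCS) reverses mechanical hypersensitivity in
neuropathic-pain models, and the *kinetics* of that reversal — how fast
analgesia washes in after the stimulator turns on and washes out after it
turns off — differ between conventional tonic pulses and time-dynamic
pulse patterns (TDPs) that continuously modulate amplitude, pulse width
or rate. The behavioural readout is the paw withdrawal threshold (PWT)
to von Frey filaments, in grams, measured at 15-min intervals before,
during (60 or 90 min) and for 30 min after stimulation.

Raw PWT series are sparse (7 or 9 points), noisy, and bounded by the
filament set, so turning-point analysis of the raw curves is fragile.
This package instead fits each series with a smooth biphasic model and
derives the kinetic quantities from the fit.

## The model

Each series is first baseline-normalized,

$$f_{target}(t) = \frac{PWT(t) - PWT(0)}{PWT(0)},$$

which removes between-animal baseline differences (the result is
invariant to rescaling the raw series) and anchors the curve at 0 for
$t = 0$. The unitless target is fitted with a product of two logistic
terms,

$$f_{fit}(t) = I\;\frac{1}{1+e^{-a_1(t - t_{mid1})}}\;
               \frac{1}{1+e^{-a_2(t - t_{mid2})}},$$

where $I$ scales the magnitude of the reversal, $t_{mid1}$ and
$t_{mid2}$ are the half-rise and half-decay times (min), and $a_1 > 0$,
$a_2 < 0$ set the steepness of the two phases (1/min). The reported
kinetic metrics are

* `slope1` $= f'(t_{mid1})$ and `slope2` $= f'(t_{mid2})$, from the
  closed-form derivative
  $f'(t) = I\,[a_1 S_1 (1-S_1) S_2 + a_2 S_2 (1-S_2) S_1]$ — the wash-in
  and wash-out rates in 1/min. For well-separated phases these approach
  $I a_1/4$ and $I a_2/4$; the steepness parameters themselves are *not*
  rates, which is why only the slopes are reported.
* `fwhm_norm` $= (t_{mid2} - t_{mid1})/T_{stim}$, the fraction of the
  stimulation duration for which the response stays above half maximum.
  This midpoint-spacing definition is an operational convention: it
  coincides with the literal half-maximum crossing width only when both
  phases are steep and well separated. We implement the operational
  definition and note the discrepancy here rather than "correcting" it.

Slopes are computed analytically, not numerically; the analytic
derivative is itself tested against a central-difference oracle.

## Fitting

The cost is the summed squared deviation (SSD) between $f_{fit}$ and
$f_{target}$ on the observation grid, minimized by Levenberg–Marquardt
least squares with an analytic Jacobian from one fixed initialization:
$I = 1$, $a_1 = 0.5$, $a_2 = -0.5$, $t_{mid1} = T_{stim}/4$,
$t_{mid2} = t_{mid1} + T_{stim}$. Convergence tolerance is $10^{-8}$ on
the cost with at most 10,000 evaluations; the fit is deterministic.

Two numerical safeguards matter with 5 parameters and 7–9 points:

* **Midpoints-first schedule.** The full problem has near-flat
  directions, and a direct five-parameter descent frequently ends in a
  *degenerate* basin: one logistic term collapses to an effectively
  constant multiplier over the window and $I$ inflates to compensate,
  leaving a curve that tracks the data while the parameters (and hence
  slopes and FWHM) are meaningless. The default schedule therefore first
  fits $(I, t_{mid1}, t_{mid2})$ with the steepnesses held at their
  initial values, then polishes all five parameters; a polish that
  degenerates a term is rejected in favour of the blockwise solution.
* **Plausibility bounds.** $|I| \le 2.5$ (observed normalized responses
  lie in $(0, 2)$), $|a| \le 2$ min$^{-1}$ (a transition faster than
  ~2 min cannot be distinguished from a step at 15-min sampling), and
  midpoints within $[-T_{stim}, 3T_{stim}]$. Negative $I$ and inverted
  midpoints remain reachable because the exclusion rules depend on them.

Both safeguards can be disabled (`fit_control(bounded = FALSE,
staged = FALSE)`) to obtain a direct unconstrained fit. Because the
model is symmetric under exchanging its two terms, a solution with
$a_1 < 0 < a_2$ is relabelled to canonical roles before metrics are
derived. An inverted fit ($t_{mid2} < t_{mid1}$) is flagged and yields a
negative FWHM; it is reported, not rejected.

Sigmoid evaluation uses `stats::plogis`, so extreme steepness cannot
overflow. Fits on fewer than six points are refused (five free
parameters); optimizer failure is reported through the `converged` flag,
never as an error.

## Fit quality and exclusion

Quality is the percent deviation
$\mathrm{Dev\%} = 100\,\mathrm{SSD}/\mathrm{SSR}$ with
$\mathrm{SSR} = \sum_i f_{target}(t_i)^2$: the residual power relative
to the signal power (0 for a perfect fit, 100 for a null fit). A fitted
series is excluded from kinetic summaries when any of three rules fires:

1. $\mathrm{Dev\%} > 50$ — the model does not describe the series;
2. $0 \le I < 0.1$ — fitted response below 10% of baseline, no
   meaningful reversal (an identically-zero target, whose Dev\% is
   undefined, is excluded through this path as well);
3. $I < 0$ — the fitted response runs opposite to the expected
   direction.

The flags are kept separately so any tally of combined criteria can be
formed. Excluded fits drop out of slope/FWHM summaries and contrasts,
but their raw PWT values still contribute to the threshold-level
comparisons, and Dev\% is summarized both with and without exclusions.

## The synthetic crossover study

Because per-animal raw data for this kind of experiment are not
publicly deposited, the package ships a generator that emulates the
design: `n_animals` rats (default 23: 8 stimulated for 60 min, 15 for
90 min), five sessions per animal — tonic, amplitude, pulse width, rate
and stochastic modulation — in a per-animal random order, PWT measured
on the `0, 15, ..., T_stim + 30` grid. The forward model inverts the
normalization: $PWT(t) = b + R\,f_{unit}(t) + \varepsilon$, with
per-animal baseline $b \sim N(6, 0.8^2)$ g truncated above 1 g,
pattern-specific maximum reversal $R$, and Gaussian measurement noise
($\sigma = 1$ g) acting on the gram scale, where the behavioural
measurement happens. Optionally each value is snapped to a conventional
von Frey filament series with a 15 g ceiling; quantization is off by
default since the filament set used in any given laboratory varies.
Every animal draws from its own random stream derived from the master
seed, so enlarging a study never perturbs existing animals.

Default kinetics (see `default_pattern_params()`) encode the
qualitative biology with magnitudes chosen once and documented here:

* tonic: fastest wash-in ($a_1 = 1.2$ min$^{-1}$, on the scale implied
  by published tonic wash-in slopes of ~0.3 min$^{-1}$), largest
  reversal (5.8 g), and a half-decay *before* the end of a 90-min
  stimulation ($t_{mid2} - t_{mid1} = 0.79\,T_{stim}$) — a
  phenomenological stand-in for tolerance to sustained constant
  stimulation, with no adaptation mechanism modelled;
* TDPs: slower wash-in ($a_1 \approx 0.1$ min$^{-1}$, still rising
  gently between 60 and 90 min), reversals of 3.6–4.4 g, and decay
  centred after stimulation ends (midpoint spans $0.90$–$0.93\,T_{stim}$)
  but early enough that the wind-down is expressed inside the recorded
  window — without that, the decay parameters of a fitted series are
  unidentifiable and fits drift into the degenerate configurations
  described above.

The generator reproduces the *structure* of real data (baseline scale,
reversal scale, crossover design, sampling grid, additive noise). It
does not reproduce serially correlated behaviour, staircase psychophysics
of the von Frey procedure, carry-over between sessions, or mechanistic
tolerance; passing tests on synthetic data therefore validate the
analysis machinery, not any biological claim.

## Cohort statistics

The comparison structure mirrors a crossover behavioural study, with
$\alpha = 0.05$, two-sided, and deliberately *no* multiplicity
correction:

* `timepoint_vs_baseline()` — paired within-animal t-tests of $PWT(t)$
  against $PWT(0)$ at $t = 15, 30, 45, 60$ min, cohorts aggregated;
* `pattern_vs_tonic()` — paired t-tests of each TDP against tonic at a
  given timepoint, animals missing a session dropped pairwise;
* `extended_period_test()` — 90-min cohort only: $PWT(75)$ and
  $PWT(90)$ against $PWT(60)$, probing loss of effect under extended
  stimulation;
* `slope_contrasts()` — paired t-tests of `slope1`, `slope2` (and
  optionally FWHM) for each TDP against tonic over QC-retained fits; a
  contrast with fewer than three complete pairs is reported as
  unavailable rather than raising an error;
* `omnibus_tests()` — a two-way repeated-measures ANOVA for PWT and
  mixed-effects models (random animal intercept) for the slopes are
  computed and reported for context, but the cell-level comparisons are
  not gated on them, mirroring how such studies report cell results
  directly. Animal is the only grouping factor; cohort does not enter
  the slope models, matching summaries that pool both cohorts.

Zero-variance paired differences yield a flagged degenerate result
(`p = NA`), not an exception; fewer than three pairs is an error the
pipeline surfaces per contrast.

## Numerical conventions and edge cases

* Times are minutes with $t = 0$ at stimulation onset; observation $i$
  (1-based) sits at $15(i-1)$ min. The $t = 0$ point is part of the
  fitted grid and anchors the left tail.
* Scale invariance of the analysis holds exactly in exact arithmetic;
  in floating point it is bit-exact when the scale factor is a power of
  two and agrees to ~$10^{-12}$ (target) / ~$10^{-6}$ (fitted
  parameters) otherwise, which the tests assert explicitly.
* Simulated thresholds are floored at 0.1 g so a threshold is always
  positive; with the default noise this path is essentially never taken.
* All seeds are 32-bit integers; every stochastic test and script fixes
  them.

## Problem sizes used by the checks

The test-suite calibration checks use 500 replicate null studies of 12
animals (pooling the four baseline cells per replicate), 100 replicate
power studies of 20 animals at a 5 g reversal with 0.5 g noise, 200
noisy recovery replicates at $\sigma = 0.1$ on the normalized scale, and
50 replicate full studies of 23 animals for the directional
reproduction check. These sizes give Monte-Carlo standard errors
comfortably below the tolerances asserted while keeping the default
suite in the minutes range.

## Known limitations

* With 7–9 observations per series, per-fit steepness (and hence the
  slopes) is heavy-tailed: a ramp that completes between two grid
  points is indistinguishable from a step, so individual slope values
  can saturate at the plausibility bound. Pattern-level means over ~20
  animals are the intended unit of interpretation.
* FWHM is the midpoint spacing, not a literal level-crossing width, and
  can be negative for inverted fits; such fits are flagged but retained.
* The generator's noise is white; real behavioural series are likely
  serially correlated, which would widen the true sampling variability
  of all statistics relative to the simulated one.
* No standard errors are attached to individual fitted parameters, and
  no random-effects curve fitting across animals is attempted.

## A worked example

```{r, eval = FALSE}
library(scskinetics)

# one animal, one session
tc <- pwt_timecourse(c(6, 6.8, 10.9, 11.5, 11.2, 8.1, 6.4), t_stim = 60)
fit <- fit_pwt(tc)
summary(fit)
plot(fit)

# a full synthetic study through the pipeline
res <- run_pipeline(sim_config = simulation_config(seed = 1),
                    out_dir = "pwt_results")
res$summary$metrics
subset(res$comparisons, contrast == "extended_vs_60" & pattern == "tonic")
```
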