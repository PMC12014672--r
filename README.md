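# scskinetics

Double-sigmoid modelling of paw-withdrawal-threshold (PWT) time courses
during spinal cord stimulation (SCS).

## What it is for

In rodent neuropathic-pain studies, SCS reverses mechanical
hypersensitivity, and the *kinetics* of that reversal — how quickly
analgesia washes in after the stimulator turns on and washes out after
it turns off — distinguish conventional tonic stimulation from
time-dynamic pulse patterns (TDPs) that modulate amplitude, pulse width
or rate. The behavioural readout, PWT to von Frey filaments (grams), is
measured on a sparse 15-min grid before, during (60 or 90 min) and for
30 min after stimulation. This package is for analysts of such
crossover experiments: it turns each noisy 7–9-point series into a
small set of interpretable kinetic quantities and runs the cohort-level
comparisons between stimulation patterns.

## The model

Each series is baseline-normalized,
`f_target(t) = (PWT(t) − PWT(0)) / PWT(0)`, and fitted with a
five-parameter double sigmoid

    f_fit(t) = I · 1/(1 + exp(−a1 (t − t_mid1))) · 1/(1 + exp(−a2 (t − t_mid2)))

by minimizing the summed squared deviation (SSD) on the observation
grid from a fixed initialization (`I = 1`, `a1 = 0.5`, `a2 = −0.5`,
`t_mid1 = T_stim/4`, `t_mid2 = t_mid1 + T_stim`). From the fitted
parameters it derives

* `slope1 = f′(t_mid1)`, `slope2 = f′(t_mid2)` — wash-in and wash-out
  rates (1/min, analytic derivative);
* `fwhm_norm = (t_mid2 − t_mid1)/T_stim` — the fraction of the
  stimulation duration with the response above half maximum;
* `Dev% = 100·SSD/SSR` — fit quality, with exclusion rules
  (`Dev% > 50`, `0 ≤ I < 0.1`, `I < 0`) for misfit, non-responding or
  inverted series.

A synthetic-data module simulates the full randomized five-pattern
crossover design (two cohorts, 60- and 90-min stimulation) with known
ground truth, and the statistics module reproduces the study-style
comparison structure: paired timepoint-vs-baseline tests, TDP-vs-tonic
contrasts per timepoint, extended-period (60→90 min) degradation tests,
slope/FWHM contrasts, and non-gating omnibus tests — all uncorrected,
two-sided, α = 0.05.

## Worked example

```r
library(scskinetics)

tc  <- pwt_timecourse(c(6, 6.8, 10.9, 11.5, 11.2, 8.1, 6.4), t_stim = 60)
fit <- fit_pwt(tc)
summary(fit)
#> Double-sigmoid PWT fit
#>       I      a1      a2  t_mid1  t_mid2
#>  0.9380  0.2467 -0.1840 22.2822 72.4245
#> SSD = 0.001457, Dev% = 0.0606, converged: TRUE
#> slope1 = 0.05785 1/min, slope2 = -0.04314 1/min, FWHM = 0.8357
#> n = 7 points, T_stim = 60 min, baseline = 6 g
#> QC: retained (high_deviation=FALSE, small_scale=FALSE, negative_scale=FALSE)
```

The fitted threshold reversal peaks at 0.94× baseline (`I`), rises to
half maximum 22 min after stimulation onset and decays through half
maximum at 72 min, staying above half maximum for 84% of the 60-min
stimulation (`FWHM = 0.84`); wash-in is faster than wash-out
(0.058 vs −0.043 min⁻¹).

A full synthetic study through the pipeline:

```r
res <- run_pipeline(sim_config = simulation_config(seed = 1),
                    out_dir = "pwt_results")
res$summary$metrics[, c("pattern", "n_retained", "slope1_mean",
                        "slope2_mean", "fwhm_mean")]
#>       pattern n_retained slope1_mean slope2_mean fwhm_mean
#> 1  stochastic         23      0.0640      -0.156     0.753
#> 2        rate         23      0.1238      -0.213     0.966
#> 3       tonic         22      0.1997      -0.260     0.344
#> 4   amplitude         21      0.0866      -0.136     0.795
#> 5 pulse_width         22      0.0621      -0.157     0.855

subset(res$comparisons, contrast == "extended_vs_60" & pattern == "tonic")
#>          contrast pattern time_min  n estimate statistic  p_value significant
#> 41 extended_vs_60   tonic       75 15  0.00984    0.0259 9.80e-01       FALSE
#> 42 extended_vs_60   tonic       90 15 -5.82880  -14.9305 5.41e-10        TRUE
```

Tonic stimulation shows the fastest wash-in (largest `slope1_mean`),
the fastest wash-out (most negative `slope2_mean`), the shortest
normalized response duration, and a significant ~5.8 g loss of effect
at 90 vs 60 min of stimulation, while the four TDP patterns hold their
effect — the qualitative signature the simulator's defaults encode.
`run_pipeline()` writes the per-series fit/QC table, pattern summaries,
all comparisons and a JSON run manifest to the output directory. A thin
command-line wrapper lives in `inst/scripts/run_pwt_pipeline.R`.

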