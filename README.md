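# rerpsim

Simulation and regression-based overlap correction for event-related
potentials (ERPs), built to answer one methodological question: when does
deconvolution-based overlap correction remove *spurious* reaction-time (RT)
effects from response-locked waveforms, and when does it remove *real*
ones?

Trial-averaged EEG mixes overlapping event-locked components. If a
stimulus-locked component S and a response-locked component R overlap by an
amount that varies with RT, response-locked averages show RT effects even
when neither component depends on RT. Overlap correction models the
continuous recording `y(t)` as a sum of time-expanded finite impulse
response (FIR) kernels,

    y(t) = sum_l beta_S(l) * 1[stimulus at t - l]
         + sum_l beta_R(l) * 1[response at t - l] + e(t),

with all kernels estimated jointly by least squares (optionally split into
fast/slow RT categories). That model assumes every signal is precisely
stimulus- or response-locked. An evidence-accumulation (EA) signal — a ramp
that starts after the stimulus and terminates at the response, as in
sequential sampling models with a decision bound `b(t)` — is neither, and
this package demonstrates what the correction does to it.

The package provides:

* **Simulators** (`scenario_config()`, `assemble_recording()`) for three
  ground-truth worlds: timescale-invariant S + R kernels; a
  stimulus-to-response ramp terminating on a constant or collapsing bound;
  and a diffusion process (Euler–Maruyama, single absorbing bound) with
  jittered pre- and post-accumulation non-decision delays.
* **The estimator** (`deconv_fit()`) — sparse FIR deconvolution over the
  whole recording, returning an `rerp_fit` object with `coef()`,
  `predict()` (per-component reconstruction), `residuals()`, `plot()`,
  `summary()` and `simulate()` methods — plus `subtract_component()` and
  `residual_fraction()`.
* **ERP analysis** (`epoch()`, `assign_rt_categories()`,
  `average_by_category()`, `preresponse_amplitude()`, `buildup_slope()`,
  `baseline_difference()`), all effects signed fast − slow.
* **Orchestrated experiments** (`run_panel_ab/cd/ef()`,
  `run_jitter_experiment()`, `run_all()`) reproducing the full analysis
  ladder on synthetic data.

## Worked example

Simulate 500 trials of a pure accumulation-to-bound ramp (collapsing
bound, no S or R components, no sensor noise), fit the usual
pooled-S + by-category-R deconvolution model, and "correct" the data by
subtracting the estimated S component:

```r
library(rerpsim)

cfg <- scenario_config("RAMP", n_trials = 500, seed = 1)
sim <- assemble_recording(cfg)
sim
#> <sim_result> RAMP scenario: 500 trials, 1413.3 s of signal @ 100 Hz

events <- assign_rt_categories(sim$events)
fit <- deconv_fit(sim$recording, events,
                  design_spec(fs = cfg$fs, s_scheme = "pooled",
                              r_scheme = "by_rt_category"))
fit
#> Overlap-corrected deconvolution fit (FIR least squares)
#>   141327 samples @ 100 Hz; 500 trials; 3 predictors (S, R_fast, R_slow); 323 betas
#>   variance explained: 0.9850; residual variance: 0.000494

corrected <- subtract_component(sim$recording, predict(fit, "S"))
avg_un <- average_by_category(epoch(sim$recording, events, "response", c(-1, 0.3)))
avg_co <- average_by_category(epoch(corrected, events, "response", c(-1, 0.3)))
round(c(uncorrected = rt_effect(preresponse_amplitude(avg_un)),
        corrected   = rt_effect(preresponse_amplitude(avg_co))), 4)
#> uncorrected   corrected
#>      0.0742      0.0159
```

The ground truth here has a *real* RT effect: with a collapsing bound, fast
trials terminate at higher amplitudes (fast − slow = +0.074 amplitude
units in the uncorrected response-locked averages). Two model mis-steps
happen at once: the fit explains 98.5% of the variance (so low residuals
are no evidence that the model is right), and subtracting the estimated S
component shrinks the real effect by ~80% (to +0.016) — the same
"correction" that exactly removes the spurious effect in the S + R world
(run the identical code with `scenario_config("SR", ...)` to see the
corrected effect drop to ~1e-15). `run_all(seed = 1)` executes the whole
ladder, including the pre-stimulus baseline-shift artifact and the
non-decision-jitter attribution experiment, and prints a summary table.

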