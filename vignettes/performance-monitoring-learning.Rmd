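---
title: "Performance monitoring and learning from feedback: model and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance monitoring and learning from feedback: model and pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmlearn)
```

## The scientific problem

When people learn a motor task from feedback, the error shown to them
confounds two causes: wrong beliefs about what the correct action is, and
execution noise that made the action deviate from what was intended.  An
agent that can monitor its own responses — predict the outcome of the action
it just executed, and know how much to trust that prediction — can discount
execution noise and extract more information from each feedback sample.
`pmlearn` implements this idea as a Bayesian observer for a time-estimation
task, together with the trial-level behavioral and EEG analysis pipeline
used to test its predictions, and synthetic-data generators that make the
whole pipeline testable end to end without any external data.

## The model

The environment presents feedback `f = (r - t) * s`, where `r` is the
executed response, `t` the unknown target interval and `s` the unknown
feedback scale.  In the simulation's abstract units the truth is `t = 19`,
`s = 90`, with response noise `sigma_r = 10` and trial-wise efference-copy
noise drawn uniformly from `{5, 10, 20}`.

The agent holds a joint belief over `(t, s)` on a fixed 100 x 50 lattice
(`t` on [0, 100], `s` on [0.1, 100], evenly spaced, endpoints included) and
starts from a uniform prior.  Each trial it:

1. intends `i = E[t]` and executes `r ~ N(i, sigma_r^2)`;
2. receives an efference copy `c ~ N(r, sigma_c^2)` with a trial-wise
   noise level;
3. reports its predicted outcome `po = (c - i) * E[s]` and a confidence
   `co` that is the rank of the *assumed* precision of the copy
   (`5 -> 3`, `10 -> 2`, `20 -> 1`);
4. fuses copy and intention by precision weighting,
   `v = 1 / (1/sigma_c^2 + 1/sigma_r^2)`,
   `m = v * (c/sigma_c^2 + i/sigma_r^2)`;
5. evaluates, for every grid cell, the Gaussian likelihood of the observed
   feedback with mean `(m - t) * s` and variance `v * s^2`, multiplies it
   into the prior and renormalizes.  The posterior is the next trial's
   prior.

The cell variance `v * s^2` follows from `f = (r - t) * s`: uncertainty
about the feedback-generating response scales quadratically onto the
feedback axis.  This is the only reading of the likelihood that is
consistent with the feedback rule and the fusion equations.

**Confidence calibration.** The parameter `cc` is the probability that the
agent assumes the *true* efference-copy noise level on a trial; otherwise
it assumes one of the other levels, uniformly.  The uniform-over-incorrect
choice is the minimal assumption; nothing in the mechanism depends on it
beyond symmetry.  The confidence report is always derived from the
*assumed* level, so a miscalibrated agent misreports confidence coherently
with its mis-weighted belief update.

**Reduced variants.** `average_confidence` knows the copy but not its
trial-wise precision and uses a fixed subjective noise level; the default
is the exact level mean `35/3`.  A rounded value of `12` is sometimes
quoted for this quantity and can be supplied via `avg_sigma_c = 12`; the
difference is behaviorally negligible, and the exact mean is the default
because it is the only value derivable from the stated level set.
`feedback_only` ignores the copy entirely (`m = i`, `v = sigma_r^2`).

## Numerical choices

* Likelihoods are computed as log densities, shifted by the cellwise
  maximum before exponentiation.  If an update still underflows entirely,
  the prior is retained for that trial and the trial is flagged
  (`degenerate`); with the default parameters this never happens.
* Posterior normalization is enforced to 1e-12 after every update and is a
  tested invariant.
* Responses, copies and predicted outcomes are unbounded reals: no
  truncation to the visible scale is applied anywhere, since the
  likelihood is well defined for any real feedback.
* Each agent pre-draws four named noise streams (response, noise level,
  copy, calibration) from one seed in a fixed order, so the three variants
  and all calibration levels see *common random numbers* — variant
  comparisons are paired.

## Simulation experiments

`run_model_comparison()` (200 agents x 250 trials per variant by default)
reproduces the information ordering: final target error of
full < average-confidence < feedback-only.  `run_cc_sweep()` shows that
the mean absolute response error over the final 50 trials decreases as
`cc` rises from 0 through 0.75 to 1.  `prediction_feedback_coupling()`
regresses feedback on the predicted outcome within each confidence level;
the slope grows with confidence.  The defaults (200 agents, 250 trials,
mirroring 5 blocks x 50 trials) are package choices — only the qualitative
orderings are treated as reproducible, and those are what the acceptance
tests assert.

`shannon_surprise_grid()` computes `-log N(spe; 0, sigma^2)`: surprise
grows with the prediction error and, at any fixed error, with the
precision of the prediction — the mechanism by which high confidence
amplifies the information carried by a given mismatch.

## The behavioral pipeline

The empirical task produces one row per trial: produced interval (target
1504 ms), a signed outcome prediction and the signed feedback on a common
ms axis, a confidence rating in [0, 1], and the production latency.  The
pipeline applies, in order:

* `filter_outliers()` — drop participants with mean RT above 10 s, then
  single trials above 6 s;
* `compute_error_signals()` — error magnitude `|produced - target|`,
  sensory prediction error `|prediction - feedback|`, reward prediction
  error `|prediction| - |feedback|`, and the trial-to-trial improvement
  `em[n-1] - em[n]` within blocks.  The improvement sign convention is
  chosen so that "larger previous errors are followed by larger
  improvements" is a positive slope;
* `confidence_calibration()` — per participant, the sign-reversed partial
  correlation of confidence and SPE, controlling for block-wise mean error
  magnitude by double residualization (the estimator is a package choice;
  only the control variable is prescribed);
* `scale_predictors()` — ms to seconds for the error signals, confidence
  and block affinely to [-1, 1], median-centering of everything except
  RPE, whose zero (outcome exactly as predicted) is meaningful;
* `fit_trial_model()` — a fixed-effects least-squares contract with an
  optional per-participant intercept.  Full random-slope mixed models are
  deliberately out of scope; the contract exposes estimates, standard
  errors and t statistics for any stated formula.
* `log_error_magnitude()` replaces exact zeros by half the smallest
  positive value before taking logs; the zero rule is a package choice.

## ERP features

Epochs are 500 samples at 500 Hz spanning -200..800 ms around feedback
onset (left-closed 2 ms bins).  `baseline_correct()` subtracts the
[-200, 0) ms mean per epoch and channel.  `reject_artifacts()` flags
epochs with any |voltage| above 150 uV or any adjacent-sample jump above
50 uV, on all channels present.  `frn_peak_to_peak()` finds the minimum
in 200..300 ms at FCz and the maximum in the 100 ms window ending at that
trough, and reports `V_min - V_max` (negative-going; the operand order
makes typical FRN amplitudes negative, matching the component's
polarity).  The "preceding maximum" carries no positivity constraint —
none is computable from its definition.  `window_mean()` averages a
region of interest over a window: P3a on the fronto-central ROI at
330-430 ms, P3b on the parietal ROI at 416-516 ms.  `subject_window()`
can re-derive 100 ms windows centered on a subject's average positive
peak (FCz/Pz); the common printed windows remain the default, ties take
the earliest latency.

## The synthetic-data generators

`generate_behavior()` simulates each participant as a *full* agent with an
individual calibration probability drawn from Beta(2, 1) (broad spread,
most participants reasonably calibrated — mirroring the empirical
predominance of positive calibration).  Model units are mapped to the ms
axes with 25 ms per unit, giving a 250 ms response SD around the 1504 ms
target — a realistic coefficient of variation for supra-second interval
production.  The ternary confidence report is mapped to
{0.17, 0.5, 0.83} plus Gaussian jitter (SD 0.05) to emulate a continuous
scale.  Response times are the produced interval plus a lognormal latency
with rare (0.4%) slow contaminants, so the outlier rules are exercised.
Feedback is not clamped to the +/-1 s display range; clamping would break
the algebraic identities between prediction, feedback and the error
signals that the tests rely on.

`generate_epochs()` builds one epoch per trial as band-limited (0.5-40 Hz)
AR(1) noise (marginal SD 8 uV, rho 0.95, independent across channels)
plus three Gaussian-shaped components whose amplitudes are linear in the
scaled trial variables: an FRN-like negativity at FCz (250 ms, base
-12 uV, +8 uV per second of RPE — better-than-predicted outcomes shrink
it), a fronto-central P3a (380 ms, +4 uV/s of SPE, +1.5 uV per unit
confidence) and a parietal P3b (466 ms, +3 uV/s SPE, -4 uV/s error
magnitude, -2 uV/s RPE).  Effect *signs* follow the component physiology;
the magnitudes are package choices set so that 2000 epochs give
comfortable power at single-trial noise levels.  A configurable fraction
of epochs (default 2%) receives an injected amplitude spike or gradient
step so the rejection rules always have work to do.

The generator attaches an `expected_effects` attribute: the exact linear
mapping from trial variables to the window-mean features (component
topography averaged over the ROI times the temporal kernel averaged over
the window).  For the window means this theory is exact and the tests
check recovered coefficients against it.  For the FRN peak-to-peak
feature the min/max extremum picking under noise *compresses* the slope
toward zero (a soft-min effect), so its entry is a noise-free upper
bound and the tests assert sign recovery with 2-SE confidence instead.

What a green test does establish: the pipeline's algebra, orderings and
sign recovery at realistic single-trial signal-to-noise.  What it does
not: coefficient-level replication of empirical mixed-model tables, which
would require the deposited participant data and a random-effects fitter;
volume-conducted 64-channel topographies; ocular or non-stationary
artifacts beyond the two injected kinds.

## Serialization

Epochs are stored as a wide CSV (epoch, channel, one column per sample)
with a JSON sidecar holding channel names, sampling rate, epoch onset and
trial keys.  An HDF5 container would be the natural choice, but no R HDF5
binding is available in the supported environment; the CSV/JSON pair is
deterministic, diff-able and round-trips exactly through
`write_epochs()`/`read_epochs()`.

## Known limitations

* The grid bounds ([0, 100] for `t`, [0.1, 100] for `s`) are part of the
  stated model; targets outside them are not representable.
* `sigma_r` and the noise-level set are known to the agent, not learned;
  calibration is static within an agent (no metacognitive learning).
* The regression contract is fixed-effects only; with strongly
  heterogeneous participants its standard errors are anti-conservative
  relative to a mixed model.
* The behavioral generator's learning dynamics come entirely from the
  Bayesian agent; it does not emulate strategic behaviors such as
  center-of-scale prediction biases early in learning.

## A worked run

```{r, eval = FALSE}
task <- task_config(n_trials = 250)
mc <- run_model_comparison(n_agents = 200, task = task, seed = 1)
mc
#> <sim_summary> 200 agents x 250 trials
#>   average_confidence   final target error   0.38  scale error   2.73
#>   feedback_only        final target error   0.45  scale error   2.74
#>   full                 final target error   0.26  scale error   2.40

prediction_feedback_coupling(subset(mc$trajectories, variant == "full"))
#>   co     slope          se     n
#> 1  1 0.1941174 0.003240716 16634
#> 2  2 0.4988523 0.004139212 16580
#> 3  3 0.8022482 0.003468593 16786
```
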