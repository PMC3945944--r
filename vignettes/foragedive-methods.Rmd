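---
title: "Predicting foraging success from dive patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting foraging success from dive patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`foragedive` implements an end-to-end workflow for asking whether the
foraging success of a diving marine predator — operationalised as the number
of prey capture attempts (PCAs), i.e. mouth-opening events detected on a
jaw-mounted accelerometer or Hall sensor — can be predicted from the dive
profile alone, and at which temporal scale. The archetypal study system is a
lactating Antarctic fur seal foraging at night on vertically migrating
myctophids, carrying a 1-Hz time-depth recorder and a 16-Hz jaw sensor, but
nothing in the pipeline is species-specific.

This vignette explains each stage's model, its assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not establish.

## Signal processing

### Surface-offset correction

Pressure transducers drift, so raw depth at the surface wanders away from
zero over a trip. A *surface record* is the minimum depth between two dives;
the correction fits a smooth trend through these minima and subtracts it. Two
numerical choices matter. First, the minimum is taken on a 5-s running mean
of the inter-dive segment: the raw minimum of a noisy segment is biased low
by roughly two noise standard deviations, and the light smoothing removes
most of that bias without letting the shallow tails of adjacent dives leak
in. Second, the trend is a robust (Huber-reweighted) straight line when fewer
than ten surface records exist and a smoothing spline (6 effective degrees of
freedom) otherwise. Negative corrected depths are preserved rather than
clipped so miscorrections remain visible.

### Dive detection and phase segmentation

A dive is a maximal run of samples deeper than 3 m, extended one sample to
each side to the surface crossings; the post-dive surface interval is the gap
to the next dive's start. Only dives deeper than 15 m carry phase metrics:
shallower dives are too brief for 1-Hz rate thresholds to be meaningful, and
they are treated as a distinct (non-modeled) behaviour throughout.

Vertical rate is the first difference of the 1-Hz depth — deliberately
unsmoothed, since any pre-smoothing would interact with the step definitions
below; the choice is exposed in the configuration. Scanning forward, the
descent continues while the rate stays at or above 0.4 m/s. A slowdown run is
tolerated (it is a *descent step*) when it lasts less than 8 s **and** its
mean depth lies before 60 % of the maximum dive depth; the first slowdown
failing either condition ends the descent. The rule for long shallow
plateaus (>= 8 s at any depth ends the descent) closes a gap the step
definition leaves open, and errs on the side of starting the bottom phase
early, which is the conservative direction for bottom-phase statistics. The
ascent is segmented by the identical scan run backwards from the dive end.
Descent rate is depth at the bottom start divided by descent duration;
ascent rate mirrors it.

### Steps, wiggles, and bottom depth variation

Within the bottom phase, *descending* (deepening) and *ascending*
(shallowing) steps are maximal runs of rate magnitude above 0.4 m/s lasting
less than 8 s; with depth positive downward, "descending" means moving away
from the surface (dive profiles are drawn depth-down, so descending steps
appear as downward staircases). A *wiggle* is an ascending step followed by
a descending step with less than 3 s between the end of the first and the
start of the second; pairs are formed greedily in time order and each step
joins at most one wiggle. The opposite ordering is available behind a
configuration switch but off by default. Runs are strictly maximal with no
gap tolerance: a single discordant sample splits a run, which is the
documented (and tested) reading of "instantaneous rate". The bottom
depth-variation index is the maximum dive depth minus the depth at the
bottom start; it is negative only if the maximum occurs during the descent,
and such dives are flagged rather than dropped.

## Dive bouts

Post-dive intervals mix a fast within-bout recovery process and a slow
between-bout process. The bout-ending criterion (BEC) is estimated by
maximum likelihood on a two-component exponential mixture
$p\,\lambda_f e^{-\lambda_f x} + (1-p)\,\lambda_s e^{-\lambda_s x}$, fitted
by Nelder–Mead from three moment-based starts (splitting the sample at three
different quantiles); ties are broken by log-likelihood. The BEC is the
closed-form intersection of the weighted component densities,
$x^* = \log\!\big(\tfrac{p\lambda_f}{(1-p)\lambda_s}\big) / (\lambda_f - \lambda_s)$.
The criterion variable is, by default, the absolute successive difference of
post-dive intervals; the literature contains several variants, so raw
intervals are available behind a switch. Because a difference threshold
cannot itself delimit bouts, the fitted BEC is applied to the raw post-dive
intervals: a new bout starts whenever an interval exceeds it. Bouts of fewer
than three dives are excluded, as is the terminal dive of every bout (its
interval reflects something other than post-dive recovery). Degenerate
inputs — fewer than 20 intervals, all-identical intervals, or a fit that
fails to separate two processes — raise informative errors rather than
returning a criterion.

## Prey-capture-attempt detection

Jaw acceleration is high-passed at 3 Hz with a zero-phase (forward–backward)
4th-order Butterworth filter to remove swimming and head motion — the filter
family is our choice; only the cutoff is prescribed by the method. A
centered moving variance with a 1.5-s window (24 samples at 16 Hz) converts
transients into peaks; Hall-sensor records use a 5-s window and skip the
high-pass, since that signal is a slow baseline with event deflections.
Events are maximal super-threshold runs of the variance series, with runs
closer than 0.5 s merged (two bursts inside one variance window are not
separable — closely spaced attempts are undercounted by construction, a
limitation shared by any windowed-variance detector). Each event is timed at
the peak of the absolute filtered signal inside its run, which localises the
transient to well under the ±0.5 s matching tolerance used in validation;
the variance peak itself can sit half a window away. The threshold is
per-individual and robust — median + 6 MAD of the variance series — because
"extreme" is not quantified in the source method and individuals differ in
baseline noise; an absolute threshold is available. Events are assigned to
the dive whose span contains them; events outside any dive are counted
separately and never modeled.

## Aggregation scales

Responses (summed PCA counts) and predictors are assembled at six scales:
dive, bout, 30-min, 1-h and 2-h windows inside bouts, and whole nights. The
eleven dive-scale predictors are maximum depth, post-dive surface duration,
descent and ascent rates, bottom duration, bottom depth variation, the four
step counts, and wiggles; super-dive scales use their means and add the
number of dives and `pct_time_deep`, the fraction of the unit's span covered
by deep-dive cycles (dive plus following surface interval). Bouts, windows
and nights are kept only when that coverage exceeds 85 %, so the modeled
units genuinely describe deep-diving behaviour. Windows are anchored at each
bout's start and tiled without overlap; partial trailing windows are
dropped — the simplest fully reproducible choice, since the source method
does not state anchoring. Coverage uses exact interval intersections of each
dive cycle with the window. Dives are assigned to windows by their start
time, which makes response totals exactly conserved between nested scales.
Night boundaries come from configuration (or simulation truth); computing
them from solar geometry is out of scope. All predictors are standardized
(centered, scaled) before modeling; the statistics are stored so that
held-out data can be standardized with training-set statistics, and a
zero-variance column is a named error rather than a silent NaN.

## Models, selection, averaging

PCA counts are Poisson with a log link on the standardized predictors, with
a per-individual Gaussian random intercept capturing inter-individual
differences. The marginal likelihood integrates the intercept by *adaptive*
Gauss–Hermite quadrature (15 nodes by default; the integrand is re-centered
at its per-cluster mode, so 15 nodes are effectively exact for these
cluster sizes). The implementation reduces each cluster's integrand to three
sufficient statistics, making one likelihood evaluation O(n · p); the
quasi-Newton optimisation (L-BFGS-B, sd constrained non-negative, analytic
gradient via Fisher's identity) therefore fits a model in milliseconds,
which is what makes all-subsets enumeration feasible. The test suite
cross-checks coefficients, standard errors, the random-intercept sd and the
log-likelihood against `lme4::glmer` at the same node count. The night scale
uses a plain Poisson GLM: with one row per night there are too few rows to
support a random effect.

Every predictor subset up to a per-scale cap (11 at the dive scale, 7 for
bouts, 13 for 30-min and 1-h windows, 4 for 2-h windows, 2 for nights —
caps that keep at least ten rows per estimated predictor) is fitted and
ranked by AICc, $-2\ell + 2k + 2k(k+1)/(n-k-1)$, with the random-intercept
sd counted in $k$. Akaike weights are
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. The candidate set is the
smallest weight-ordered prefix whose cumulative weight strictly exceeds
0.95, re-normalized before averaging (whether to re-normalize is not
specified in the source method; re-normalizing makes the averaged
coefficients a proper convex combination). Averaging substitutes zero for a
predictor absent from a model (so weakly supported predictors shrink toward
zero and a never-selected predictor reports exactly 0), importance is the
summed weight of candidate models containing the predictor, and standard
errors are unconditional in the Burnham–Anderson sense, combining
within-model variance with between-model spread. Non-converged fits are
dropped from the ranking with a warning; a derivative-free fallback catches
most awkward small-sample surfaces first.

Predictions are population-level, $\mu = \exp(x'\bar\beta)$ with the random
intercept at zero — the only defensible choice for an unseen individual.
For fitted values on training individuals the posterior-mode intercepts can
be added (`population_level = FALSE`); the full-data concordance below uses
these conditional fitted values, matching how mixed-model fitted values are
conventionally displayed.

## Validation

The concordance index over all pairs with unequal observed counts (tied
predictions score 0.5) measures how well predicted expected counts order the
observed counts; bands are: > 0.9 excellent, 0.8–0.9 good, 0.7–0.8
reasonable, 0.6–0.7 poor, 0.5–0.6 unsuccessful, with boundary values
assigned to the lower band (a C-index of exactly 0.70 is "poor") and values
below 0.5 flagged anti-concordant. Cross-validation leaves each *individual*
out in turn — the relevant generalisation for biologging is to new animals —
re-running the entire selection-and-averaging procedure on the training
individuals (including standardization) and predicting the held-out animal
at population level. "All combinations of individuals" is read as each
individual once: n folds.

Two summaries are reported, and they genuinely differ. The *pooled* C-index
concatenates all held-out predictions; the *mean-fold* C-index averages
per-individual C-indices. With a strong random intercept the pooled version
is biased **below** 0.5 under a within-individual permutation null: each
fold's intercept estimates the training individuals' mean, which
anti-correlates with the held-out individual's own intercept, and since
permuted-data predictions are nearly constant within a fold, these
anti-concordant cross-fold pairs dominate. The mean-fold C-index sits at
chance under the same null, so calibration claims in the tests are made on
the mean-fold statistic, while both are printed for transparency.

## The synthetic-data generator

No public dataset accompanies the method, so the generator is a first-class,
tested module that emulates exactly the structure the analysis assumes:
night-restricted bouts of dives (a bout every hour or so, ~20 dives per
bout, ~45-s within-bout surface intervals — about fifty deep dives per
6-h night, the scale reported for the study system); trapezoidal dives with
bottom-arrival depths around 45 ± 12 m and an 8 % admixture of shallow
(< 15 m) V-dives so the deep filters are exercised; transit-step plateaus,
bottom steps, wiggle excursions (≥ 2 m) and terminal descending staircases
injected at configurable Poisson rates; linear (or half-sine) surface-offset
drift; Gaussian depth noise defaulting to 0.1 m, the depth sensor's stated
resolution; and a 16-Hz acceleration channel of baseline noise plus a 0.4-Hz
body-motion component, with one 0.3-s in-band (6-Hz, random-phase)
oscillatory transient of amplitude 10× the baseline sd per true event. Per-dive counts are drawn from the Poisson log-link model on the
(within-trip standardized) true dive covariates with a random intercept of
sd 0.5; the default coefficient vector is the averaged dive-scale model
reported for the fur-seal system, so simulated count structure matches the
magnitudes a practitioner would see. The transient waveform (a fixed-
amplitude in-band oscillation) and the 0.3-s duration are stand-ins: the
source method does not characterise event waveforms, and the detector's
measured recall/precision (≥ 0.9 under the mean + 6 sd threshold rule)
should be read as validation of the pipeline's logic, not of any particular
sensor's physics.

All dive-profile breakpoints fall on integer seconds, so on noise-free data
the 1-Hz samples reproduce the piecewise-linear profile exactly and phase
boundaries and feature counts are recoverable *exactly* — which is what
turns the generator into an oracle for the segmentation and feature
detectors. Every random quantity derives from one seed (per-individual
streams are derived deterministically), and the whole pipeline is
byte-identical across runs with the same configuration.

What passing tests do **not** show: real jaw-acceleration events are not
i.i.d. bursts, real dive profiles bend smoothly rather than piecewise
linearly, real predictors are mutually correlated (simulated ones are
independent, which flatters subset selection), and real surface-offset
drift can be non-monotone in ways a 6-df spline may underfit. Results on
real data should be benchmarked against the per-stage diagnostics the
pipeline writes, not assumed from the synthetic performance.

## Problem sizes and runtime

The test suite and the acceptance script run the generator at reduced but
honest sizes chosen as the package's own defaults for routine verification:
one-to-six individuals with one-to-two 2–6-h nights for pipeline-level
checks (a few hundred dives, a few million 16-Hz samples), 100 replicates at
n = 2000 with 10 individuals for mixed-model recovery, 50 replicates of the
1024-model enumeration for selection behaviour, and 100 replicates of
n = 1000 interval mixtures for the bout criterion. A full enumeration of
2048 dive-scale models fits in a few seconds on one core thanks to the
compiled likelihood.

## Known limitations

Closely spaced prey-capture attempts merge into one detected event (variance
window width); the BEC likelihood is the two-process exponential variant,
not the three-process or Poisson-process alternatives; window tiling is
anchored, not sliding; the night-scale GLM ignores individual identity
entirely; and model-averaged standard errors inherit the usual caveats of
unconditional averaging when candidate models disagree strongly.
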