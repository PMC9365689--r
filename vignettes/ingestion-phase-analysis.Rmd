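---
title: "Stage-resolved analysis of ingestion responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved analysis of ingestion responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ingestphase)
```

## The problem

When a thirsty mouse drinks, its brain is informed about the water three
times: immediately, through taste and licking (the **oral** stage, seconds);
over the next minutes, as fluid fills the gut (the **gastrointestinal**
stage, roughly the 12 minutes of a standard intragastric infusion); and tens
of minutes later, as absorbed water dilutes the blood (the **systemic**,
post-absorptive stage). Dopaminergic neurons respond at each of these stages,
but different neurons respond at different stages, so population analyses
must classify each cell by *when* it responds, not just whether it responds.

`ingestphase` implements that analysis chain for single-cell calcium imaging
(extracted fluorescence traces) and fibre photometry (dual-channel dopamine
sensor recordings), together with the behavioural quantities (lick bouts,
fluid preference, movement) and the statistics (permutation tests,
intra-class correlation) that support it. Because the in-vivo recordings the
method was developed on are not publicly deposited, the package also ships a
seeded synthetic-session generator whose ground truth lets every stage of
the pipeline be validated end to end.

## Normalization

**Calcium traces.** Every trace is normalized as \(z = (C - \mu)/\sigma\),
where \(\mu\) and \(\sigma\) are the mean and standard deviation over the
baseline window — by default the first 10 minutes of the recording, before
any manipulation. We use the population (divide-by-\(n\)) standard
deviation; the choice is immaterial at baseline lengths of thousands of
samples but is fixed for reproducibility. A neuron whose baseline is exactly
constant is normalized to \(z \equiv 0\); a zero-variance baseline followed
by signal is flagged degenerate and excluded with a logged reason, since its
z-scale would be meaningless.

**Bleach screening.** Neurons whose baseline is dominated by a decaying
exponential (a photobleaching artifact, not activity) are removed before
analysis. We fit \(A e^{-t/\tau} + c\) to the baseline and exclude when the
fit explains at least `r2_min = 0.8` of the baseline variance and
\(A \ge 2\) baseline standard deviations. The thresholds are configurable
and every decision is logged with its fit diagnostics. The baseline is
block-averaged to 1 Hz before fitting: bleaching has time constants of
minutes, so nothing is lost, and the exponential fits stay cheap even for
hundreds of neurons.

**Slow baseline fluorescence.** The sub-1/60 Hz component of a trace (used
to distinguish tonic from phasic changes) is extracted with a zero-phase
forward–backward Butterworth lowpass (order 2 per pass), with reflection
padding at the edges. The cutoff is the defining parameter; the filter
family and order are fixed in the implementation and verified in tests
against the analytic transfer function.

**Photometry dF/F0.** The 405-nm isosbestic channel is insensitive to the
sensor's ligand, so fluctuations it shares with the 470-nm signal channel
are artifacts (motion, bleaching). We regress the signal on the reference by
ordinary least squares *over the baseline window only*, predict
\(F_0(t) = a F_{405}(t) + b\) for the whole session, and report
\(\Delta F/F_0 = (F - F_0)/F_0\). Fitting on the baseline only avoids
absorbing real late-session responses into the artifact model. Samples where
the predicted \(F_0\) is non-positive are masked rather than silently
producing sign-flipped values. The 1 Hz downsampling used for plotting
compactness is never used for statistics.

**Downsampling** is an exact windowed (block) average — an anti-aliased
reduction whose output length is \(\lfloor n \cdot
f_\mathrm{target}/f_\mathrm{native} \rfloor\) — so downsampled epoch means
stay interpretable as means of the raw samples.

## Epochs and classification

Epoch windows are anchored to behavioural events (`define_epochs`):

| epoch | anchor | window |
|---|---|---|
| oral | first lick-bout start | 0–30 s |
| gastrointestinal | infusion start | 0–12 min |
| systemic (imaging) | infusion start / first bout | 12–32 min |
| systemic (photometry) | infusion start / first bout | 12–50 min |
| ip_systemic | intraperitoneal injection | 0–30 min |
| baseline | anchor | −10–0 min |

An alternative preset, `legacy_end_anchored`, defines a single
post-ingestion window 0–20 min after the *end* of consumption or infusion —
the convention that start-anchored windows superseded once rise-time
analysis showed systemic responses begin 10–14 min after onset. Both presets
are named explicitly in every report; they are not reconciled silently.

A neuron's response to an epoch is the arithmetic mean of its normalized
trace over the window. Since baseline z-scores average to zero by
construction, this mean *is* the mean change of activity; an optional
re-baselining against a pre-anchor window is available for recordings whose
baseline drifts. Classification is strict: activated if the mean exceeds
+1z, inhibited if below −1z, otherwise unresponsive (a mean of exactly 1.0
is *not* activated). The `exclusive` mode additionally requires an epoch to
strictly dominate all other epochs for the activated label, attributing
multi-epoch responders to their strongest stage; it can only ever shrink the
activated set.

The population summary per epoch reports the activated and inhibited
fractions and the **population-weighted z-score** — fraction times the
group's mean z change — which collapses prevalence and magnitude into one
comparable number (zero when the group is empty).

## Onset latency and persistence

The rise time t50 of a systemic responder is the midpoint of a 4-parameter
logistic \(b + A\,\mathrm{logis}((t - m)/k)\) fitted by least squares
(Levenberg–Marquardt, multi-start over midpoint quartiles and slopes 0.5, 2
and 5 min) to the z-trace after the anchor. The logistic models the *rise*,
so the fit window ends at the smoothed peak of the response; including the
later return to baseline would bias the midpoint earlier. Fits whose
midpoint escapes the window are flagged non-convergent and excluded from
latency statistics with a logged reason.

Persistence has no standard estimator, so the package defines one (a
declared reconstruction): on the 30-s running-mean trace, the contiguous
time spent at or above 50% of the peak change, from the upward half-peak
crossing to the downward one. On the generator's waveform this equals the
injected persistence parameter exactly, which is what makes the recovery
test meaningful. Fits are performed at 0.5 Hz by default: systemic dynamics
have time constants of minutes, and the coarser grid makes hundreds of
multi-start fits cheap without measurable bias at that timescale.

Inhibited responses are fitted on the sign-flipped trace, making latency
estimates symmetric between mirrored activated/inhibited pairs.

## Behaviour

A **lick bout** is a maximal run of licks in which no inter-lick interval
exceeds 2 s and whose span (first to last lick) is at least 10 s. "No
interval greater than 2 s" is read inclusively: a gap of exactly 2 s stays
inside the bout. "Lasting ten or more seconds" is read as span, not lick
count. The start of the first bout anchors the oral and (for drinking
sessions) systemic epochs.

The **preference index** is the lick fraction for a target solution,
`target/(target+other)`; two-day two-bottle tests (bottle side randomized
day 1, reversed day 2) are pooled lick-weighted, with per-day indices also
available, since the pooling rule is not standardized.

**Movement segmentation** rectifies and sums the three accelerometer axes,
lowpasses at 5 Hz with a third-order zero-phase Butterworth filter, and
thresholds with Otsu's method (256 equal-width bins over the signal range).
A constant signal has no histogram structure; that degenerate case labels
everything rest with a warning rather than inventing a threshold.

## Statistics

**Permutation tests** use the difference in means (unpaired) or the mean
paired difference as statistic. The null set is enumerated exactly — all
\(2^n\) sign flips or all \(\binom{n+m}{n}\) relabellings — whenever the
count is at most \(2^{20}\); otherwise 10,000 Monte-Carlo draws with the
add-one convention \((1 + k)/(B + 1)\), so p is never zero and the test is
valid at any iteration count. One-sided variants are available for
directional hypotheses established earlier in an experiment.

**Intra-class correlation** uses the one-way random-effects ANOVA method of
moments: ICC = between-mouse variance / total variance, with negative
between-mouse estimates clipped to zero (reported pre-clip in diagnostics).
It guards population claims against single-animal outliers. Linear
mixed-model effect estimation is deliberately out of scope; the response
tables export cleanly to any LMM package.

**Cross-condition correlation** of matched neuron responses reports the OLS
slope, Pearson r, a 95% confidence band for the fitted line, and a
permutation p obtained by permuting the pairing (exact to n = 9).

**Cross-session matching** of neurons minimizes total centroid distance by
the Hungarian algorithm, restricted to pairs within one soma diameter
(15 um default). Spatial footprints are not used, and all matches are
exported for the manual verification such alignments require.

## The synthetic-session generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions the analysis targets:

* imaging at 8 Hz, photometry at ~1017 Hz (downsampled to 4 Hz for
  analysis), 10-min baseline before any manipulation;
* intragastric infusion of 0.6 or 1.2 ml at 100 or 200 ul/min;
* systemic onset 14 ± 1 min after infusion start (10.1 ± 0.6 min after
  drinking onset), persistence 30 ± 0.7 min, drawn per neuron from
  truncated normals (±3 sd);
* archetype mixtures assigned by largest-remainder rounding (ties broken in
  the order oral, GI, systemic-activated, systemic-inhibited), so injected
  counts are exact, not merely expected;
* closed-loop training: every lick of a flavoured solution triggers a 1-ul
  infusion of its mapped solution; four counterbalanced groups crossing
  flavour order with the water/hypertonic-saline mapping; two-day
  two-bottle tests before and after six training days.

Waveforms: oral responders emit per-lick calcium transients (exponential
rise 0.1 s, decay 1 s — resolvable at 8 Hz; the sensor's kinetics are a free
parameter, not a measured constant); GI responders are elevated while the
infusion runs (soft-edged window); systemic responders follow a logistic
rise with midpoint at their onset and a logistic decay with midpoint at
onset + persistence, i.e. the waveform's time-above-half-peak equals the
persistence parameter by construction. Amplitudes are expressed in z-units
relative to the injected noise floor, so "high SNR" has a precise meaning
(peak 4z over unit noise by default, with ±15% per-neuron jitter).
A session-level latent osmolality record (piecewise-linear fall for water,
rise for hypertonic saline, scaled by delivered volume) is attached to each
simulated session; the systemic logistic is the modelled neural read-out of
that latent.

Photometry sessions share a low-frequency random-walk artifact between the
two channels with channel-specific gain — a deliberately simple common-mode
model that isosbestic regression should (and, in tests, does) remove almost
entirely. Every generator draws from per-entity substreams keyed by a hash
of (master seed, entity id), so regenerating with more neurons never
perturbs the noise of existing ones, and identical configurations are
bit-identical.

**What the generator does not emulate** — and therefore what passing
recovery tests do and do not show: it produces no pixel-level movies, no
source-extraction crosstalk or over-segmentation, no correlated
network-level noise across neurons, no hemodynamic contamination, no
licking biomechanics, and its artifact and drift models are stylized. Tests
against it validate the *analysis* (formulas, windows, estimators,
inference) under the statistical structure the analysis assumes; they are
not evidence about extraction quality on real movies.

## Numerical choices and degenerate inputs

* Half-open windows `[start, end)` on the sample grid, with a sample's time
  taken at its left edge; epoch boundaries are therefore unambiguous at any
  sample rate.
* Otsu ties take the lowest maximizing bin edge; thresholds are bin edges,
  values strictly above fall in the upper class.
* The permutation p's add-one convention applies to Monte-Carlo runs only;
  exact runs report the true ratio of integers.
* All-equal data give p = 1 with a warning (not an error) in permutation
  tests; zero-variance vectors are an error in correlation, where no
  meaningful statistic exists.
* Sigmoid fits use bounded parameters (amplitude ≥ 0, slope ≥ 1e-3 min) and
  nine starting points; non-convergence after all starts excludes the
  neuron from latency statistics, never silently imputes.
* Seeds derived by string-key hashing are kept below \(2^{31}\) (R's
  integer range).

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at desk scale, chosen
so the full chain runs in minutes on one core while keeping Monte-Carlo
error well inside the tolerances tested: 200-neuron populations across 20
seeds for fraction recovery, 100 neurons for latency recovery, 1,000 random
lick trains and 1,000 null replicates for the oracle-equivalence and
calibration checks, 20 seeded photometry sessions for artifact removal.

## Known limitations

* The systemic waveform is a stylized logistic; real post-absorptive
  dynamics may be asymmetric, and t50 on real data inherits whatever bias
  the sigmoid family imposes there.
* Persistence is estimator-defined (time above half-peak on a smoothed
  trace); other reasonable definitions would differ on asymmetric
  responses.
* When a session contains both drinking and infusion, the systemic anchor
  is whichever event the configuration declares primary — it is stated in
  the report, never inferred.
* Whether the acclimatization segment belongs to the baseline is a
  configuration decision (`baseline_window`), not a guess the package
  makes.
* Speed-dependence of the systemic onset on infusion rate is exposed as a
  per-neuron onset parameter, with no functional form shipped: none is
  established.
* Trace I/O is CSV/JSON only; sessions too large for that are expected to
  arrive as in-memory matrices from the user's extraction pipeline.
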