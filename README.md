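# ingestphase

Stage-resolved analysis of neural responses to ingestion, for calcium
imaging and fibre photometry.

Ingestion reaches the brain in three waves: an **oral** stage locked to
licking (seconds), a **gastrointestinal** stage while fluid or nutrients sit
in the gut (~0–12 min from infusion start), and a **systemic**,
post-absorptive stage that begins tens of minutes after consumption as blood
osmolality and nutrient levels change. Neurons that respond at one stage are
largely silent at others, so population analyses of, say, dopaminergic
recordings during drinking must classify each cell by *when* it responds.
This package implements that analysis chain for neuroscientists working with
extracted calcium traces (e.g. CNMF-E output) or dual-channel photometry
signals, and for anyone who needs its behavioural and statistical building
blocks (lick microstructure, fluid preference, permutation inference).

## What it computes

* **Normalization** — baseline z-scoring `z = (C − μ)/σ` (μ, σ from the
  first 10 min), isosbestic ΔF/F₀ = (F − F₀)/F₀ with F₀ regressed from the
  405-nm channel on the baseline, 1/60 Hz zero-phase lowpass for slow
  baseline fluorescence, exponential bleach-artifact screening, block-average
  downsampling.
* **Epoch classification** — oral (30 s from the first lick bout), GI
  (0–12 min from infusion start), systemic (12–32 min imaging / 12–50 min
  photometry), IP (0–30 min post injection); activated if the epoch mean
  exceeds +1z, inhibited below −1z, with an exclusive-epoch variant; the
  population-weighted z-score (fraction × group mean z) per epoch.
* **Latency** — onset t50 as the midpoint of a multi-start 4-parameter
  logistic fit, and persistence as time above half-peak on the smoothed
  trace.
* **Behaviour** — lick bouts (≥10 s span, no inter-lick interval >2 s),
  preference index (target licks / total licks), closed-loop consumption
  summaries, Otsu-thresholded accelerometer movement segmentation.
* **Statistics** — exact/Monte-Carlo permutation tests (difference in
  means; 10,000 iterations or full enumeration), intra-class correlation
  across mice, cross-condition correlation with permutation p, Hungarian
  cross-session neuron matching.
* **Synthetic sessions** — seeded generators for all of the above with
  ground truth (archetype fractions, onsets at 14 ± 1 min post infusion /
  10.1 ± 0.6 min post drinking, persistence 30 ± 0.7 min, four-group
  closed-loop flavour-training cohorts), so the whole pipeline is testable
  without any recording.

## Worked example

Simulate an intragastric water-infusion session (1.2 ml over 12 min), run
the full chain, and look at what comes back:

```r
library(ingestphase)

design <- session_design("imaging", duration_min = 65,
                         manipulation = "ig_infusion",
                         infusion_rate_ul_min = 100,
                         infusion_volume_ul = 1200, seed = 11)
report <- run_session(list(
  design = design, n_neurons = 100,
  fractions = c(gi = 0.10, systemic_activated = 0.39,
                systemic_inhibited = 0.10),
  fit_rise = TRUE, seed = 11))
report
#> <session_report> imaging/ig_infusion, 100 neurons (0 bleach-excluded)
#>              epoch   n fraction_activated fraction_inhibited
#> 1 gastrointestinal 100               0.10                0.0
#> 2         systemic 100               0.39                0.1
#>   weighted_z_activated weighted_z_inhibited
#> 1            0.2782981            0.0000000
#> 2            1.3512605           -0.3599798
```

The classifier recovers the injected mixture exactly: 39% of neurons
activated in the systemic epoch, 10% inhibited, 10% activated during the
infusion itself. The population-weighted z-score (1.35 for systemic
activation) is the fraction multiplied by the group's mean z change — the
one-number summary used to compare stimuli. Rise fits on the systemic
responders give their onset latency and persistence:

```r
head(report$rise[report$rise$direction == "activated", ], 3)
#>     neuron_id direction  t50_min persistence_min r_squared converged
#> n11       n11 activated 15.17933        29.83333 0.9834389      TRUE
#> n12       n12 activated 15.75415        30.93333 0.9856751      TRUE
#> n13       n13 activated 13.93651        29.00000 0.9813727      TRUE
```

with a cohort mean t50 of 14.09 min — the delayed, post-absorptive wave.
A closed-loop flavour-training experiment (every lick triggers a 1-µl
infusion; one flavour maps to water, the other to hypertonic saline):

```r
run_training_experiment(list(n_per_group = 3, seed = 11))
#> <training_report> 12 mice: mean preference change +0.393 (paired p = 0.0004883)
```

Mice drift toward the rehydrating flavour; the paired permutation test on
pre- vs post-training preference is exact (2¹² sign flips).

## Scope

Source extraction (CNMF-E), motion correction, and linear-mixed-model effect
estimation are out of scope: the package starts from extracted traces and
exports tidy tables any LMM package can consume. Trace I/O is plain-text
(long CSV + JSON sidecars).
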