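# dexstates

Analysis of cortical local field potential (LFP) dynamics and behavior
during unconsciousness induced by the alpha-2-adrenergic agonist
dexmedetomidine, and during recovery — either gradual, or instantaneous
after an alpha-2 antagonist (atipamezole) bolus.

The package is aimed at systems-neuroscience and anesthesia researchers
working with multi-channel intracortical recordings (e.g. somatosensory S1,
S2 and ventral premotor PMv arrays in non-human primates) together with a
behavioral trial log. It implements the full analysis chain as reusable,
tested R functions, and ships a seeded synthetic-session generator with
ground-truth state timelines so that every stage can be validated without
animal data.

## What it computes

**Behavioral endpoints.** From trial outcomes (`correct`, `failed_attempt`,
`no_response`) it estimates task *engagement* P(any response) and
*performance* P(correct) on a 1-s grid and detects:

- **LOC** (loss of consciousness): first time engagement drops below 0.3,
- **ROC** (return of consciousness): first time after LOC engagement rises
  above 0.3,
- **ROPAP** (return of pre-anesthetic performance): first time after LOC
  that performance exceeds 0.9 and stays there for at least 3 min.

**Spectral analysis.** Zero-phase 60 Hz notch; multitaper spectrograms
(30-s non-overlapping windows, 3 Slepian tapers); 1-min condition epochs by
Welch's method with percentile 95% CIs across channels; magnitude coherence
per 2-s window for all within/between-region channel pairs with
bias-corrected bootstrap CIs; band-power z-scoring against the
pre-anesthetic baseline.

**Spindle events.** 9–17 Hz bursts found on the band-limited analytic
envelope z-scored against the awake baseline: onset/offset at 4 z, peak at
≥ 6 z, duration 500–2500 ms inclusive, artifacts above 15 z rejected.
Events are characterized by density (events/min), duration and peak
frequency (Hilbert–Huang marginal spectrum, with a multitaper-PSD argmax
cross-check), and compared across behavioral periods with two-sided
unpaired t-tests at p < 0.01.

**State space.** Three per-second band-power ratios per channel,

```
Ratio1 = P(17–35 Hz) / P(0.5–60 Hz)
Ratio2 = P(1–8 Hz)   / P(1–16 Hz)
Ratio3 = P(9–15 Hz)  / P(1–16 Hz)
```

each reduced to the first principal component of its time-by-channel
matrix, smoothed with a 20-s Hanning window. The 3-D trajectory (one point
per second, LOC to session end) is summarized by kernel density (occupied
brain states) and Euclidean speed (state transitions), with the behavioral
probabilities as overlay.

**Statistics.** Frequency-wise repeated-measures ANOVA with
Greenhouse–Geisser correction or Friedman tests, pairwise post hoc
comparisons at Bonferroni-corrected thresholds (0.05/6 ≈ 0.0083 for four
conditions, 0.05/3 ≈ 0.017 for three), Kolmogorov–Smirnov normality
screening, percentile and bias-corrected bootstrap CIs.

## Worked example

```r
library(dexstates)

tl <- state_timeline(c("awake", "induction", "unconscious", "recovered"),
                     c(0, 120, 240, 600), c(120, 240, 600, 1000))
s   <- generate_session(timeline = tl, n_channels = c(S1 = 3), seed = 53)
res <- run_pipeline(s, verbose = FALSE)

res$endpoints
#> Behavioral endpoints:
#>   LOC:   254.0 s
#>   ROC:   571.0 s
#>   ROPAP: 671.0 s

round(res$embedding$variance_explained, 3)
#> [1] 0.997 0.988 0.938

res$spindle_summary$stats[, c("label", "density_per_min")]
#>         label density_per_min
#> 1       awake        0.000000
#> 2   induction        6.666667
#> 3 unconscious        4.166667
#> 4   recovered        0.450000
```

The detected LOC (254 s) trails the latent awake→unconscious switch
(240 s) by less than half the probability-estimator window, ROC/ROPAP
bracket the recovery, the first principal component of every spectral
ratio dominates its time-by-channel matrix (shared state dynamics), and
spindle density peaks while the anesthetic state is active and collapses
after recovery — the qualitative signature of this anesthetic.

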