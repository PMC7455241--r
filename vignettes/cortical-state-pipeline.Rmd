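---
title: "Methods: cortical state dynamics under an alpha-2 agonist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical state dynamics under an alpha-2 agonist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dexstates)
```

This vignette documents the models, estimators and numerical choices behind
`dexstates`, in the spirit of a methods section: what each stage assumes,
which knobs matter, and what the synthetic validation does and does not
establish about real recordings.

## The problem

Dexmedetomidine, a selective alpha-2-adrenergic agonist, produces
unconsciousness with a distinctive electrophysiological fingerprint:
awake-state beta oscillations (18–25 Hz over somatosensory cortex, 26–34 Hz
over ventral premotor cortex) give way to slow-delta (0.5–4 Hz) activity,
with transient alpha (8–12 Hz) and prominent 9–17 Hz spindle bursts around
the transitions and during early recovery. Because a specific antagonist
(atipamezole) exists, recovery can be studied in two regimes: gradual
emergence through an intermediate, spindle-rich state, and an instantaneous
pharmacological reversal. The pipeline quantifies both regimes from two
data streams: multi-channel LFP sampled at 1 kHz and a trial-by-trial
behavioral log.

## Behavioral endpoints

Each trial outcome is one of `correct`, `failed_attempt`, `no_response`.
Engagement is the probability of any response; performance the probability
of a correct response, so performance ≤ engagement pointwise by
construction.

The estimator is deliberately simple and fully exposed: a **centered
sliding window of 20 trials** evaluated on a 1-s grid, with Wilson 95%
confidence bounds (`estimate_probabilities()`, `n_trials`). No published
window length exists for this task, so the default is a package design
choice; with typical 6–10 s trial periods it spans roughly 150 s, and the
endpoint-recovery guarantee below is expressed relative to this window. A
causal exponentially-weighted variant (`method = "ewma"`) is available for
sensitivity analysis.

Endpoint semantics (`detect_endpoints()`):

* LOC fires at the first grid time with engagement **below 0.3** coming
  from at or above it; ROC symmetrically **above 0.3** after LOC. Values
  exactly at threshold never trigger.
* ROPAP is the start of the first run after LOC with performance **above
  0.9** sustained for **≥ 180 s**; a single sub-threshold grid point resets
  the hold. With a 1-s grid the run must span 181 grid points.
* Missing endpoints are reported as `NA`, never imputed.

These semantics make two properties provable rather than empirical:
raising the LOC threshold can only move LOC earlier, and whenever all
three endpoints exist, LOC < ROC ≤ ROPAP (performance above 0.9 implies
engagement above 0.3 at the same time).

On synthetic sessions with hard latent switches, the median absolute
endpoint error over 50 seeds is well under half the estimator window
(about 37/29/70 s for LOC/ROC/ROPAP against a 76 s half-window in the test
configuration). ROPAP carries the largest intrinsic delay: crossing a 0.9
threshold with a 20-trial window requires ≥ 19 post-switch correct trials
inside the window, i.e. nearly the full half-window must have elapsed.

## Spectral estimation

* **Line noise**: 2nd-order Butterworth band-stop (59–61 Hz default width,
  configurable) applied forward and backward (`signal::filtfilt`), giving
  zero phase distortion. The stop-band width is a design choice; only the
  filter order and bidirectional application are fixed by convention.
* **Spectrograms**: 30-s non-overlapping windows, 3 Slepian tapers. The
  time-bandwidth product is not part of the printed convention; we use
  NW = 2 (K = 2·NW − 1 = 3 tapers), the standard pairing for three tapers.
  Tapers are computed from the symmetric tridiagonal formulation of the
  Slepian problem (Sturm bisection plus inverse iteration) and memoized per
  window length; their frequency concentrations match published values
  (0.99994/0.9977/0.9605 at NW = 2).
* **Condition epochs**: 1-min epochs, Welch PSD with 2-s Hann segments at
  50% overlap (matching the 2-s coherence resolution), channel-mean with
  percentile 95% CI across channels.
* **Coherence**: magnitude coherence from taper-averaged cross-spectra in
  2-s non-overlapping windows. Epoch summaries average auto- and
  cross-spectra over all windows *before* normalizing (consistent
  estimator); region averages pool all within-region pairs (n(n−1)/2) or
  between-region pairs (n1·n2) with a bias-corrected bootstrap CI
  (1000 resamples) across pairs. With 9/11/10 channels this yields the
  familiar 36/55/45 within- and 99/90/110 between-region pair counts.
* **Normalization**: band power and firing rates are z-scored per channel
  against the pre-anesthetic baseline mean and SD; a zero-variance
  baseline is a hard error, not a silent NaN.

## Spindle detection

The detector operates on the 9–17 Hz band of the line-noise-free trace
(4th-order zero-phase Butterworth) and z-scores the analytic-signal
envelope against the **awake baseline interval** of the same channel. The
baseline definition is not uniquely pinned by convention (raw filtered
amplitude vs envelope; which interval); we use the envelope over the awake
period — the natural reference, since spindles are essentially absent
awake — and expose both the interval and thresholds in
`spindle_params()`.

Gates, applied exactly: envelope z ≥ 4 from start to end, peak z ≥ 6,
duration 500–2500 ms inclusive, peak z ≤ 15 (artifact rejection —
replacing manual visual confirmation with a deterministic rule).
Sub-threshold gaps shorter than 100 ms are merged before the duration gate
to avoid double-counting envelope ripple.

Peak frequency uses the Hilbert–Huang transform: empirical mode
decomposition (cubic-spline envelope sifting, Cauchy-type stopping
criterion 0.3, ≤ 8 modes) followed by the amplitude²-weighted marginal
distribution of instantaneous frequency in 0.5 Hz bins, restricted to the
analysis band. Because EMD stopping rules vary between implementations, a
plain multitaper-PSD argmax fallback (`method = "psd"`) is provided and the
two are cross-checked in the tests (they agree within ~3 Hz on noisy
events, and recover noiseless carriers to within the bin width).

One geometric fact matters when validating against injected ground truth:
a Hann-enveloped burst whose peak reaches 8 z stays above the 4 z onset
threshold for only ~44% of its support, so the *detected* duration is
roughly 0.44 of the injected one. Validation bursts of 1.2–2.4 s therefore
produce gate-compliant detected events; this follows from the threshold
geometry, not from tuning. Injected burst amplitudes are calibrated so the
band-limited envelope truly attains the requested z value — the
generator compensates the band filter's gain at each carrier frequency,
which matters near the 9 and 17 Hz corners where a zero-phase 4th-order
filter passes only half the power.

## Spectral-ratio state space

Per channel and 1-s bin, three band-power ratios are computed from a 1-s
multitaper estimate (NW = 2, 3 tapers): Ratio1 = P(17–35)/P(0.5–60)
(beta fraction), Ratio2 = P(1–8)/P(1–16) (slow fraction), Ratio3 =
P(9–15)/P(1–16) (alpha/spindle fraction). A 30-s spectrogram window cannot
produce per-second points, so the 1-s estimator is the necessary choice
here. The ratios are bounded in [0, 1]; the numerators of Ratio2 and
Ratio3 are disjoint subsets of their common denominator, so their sum
cannot exceed 1 (up to floating error) — both facts are enforced as
invariants. Bins with zero denominator power are flagged invalid rather
than zeroed.

For each ratio, PCA runs on the time-by-channel matrix of the analysis
span (LOC to session end), channel means removed, no variance scaling
(the ratios are already commensurate). The PC1 score series is kept with
its explained-variance fraction and smoothed with a normalized 20-s
Hanning window (variance-reducing by construction; constants are
preserved). The PC1 sign is fixed so the loading vector has positive mean
— channels load positively on the shared trajectory — making embeddings
comparable across seeds; an explicit baseline interval can override this.
PCA is computed per session; nothing in the method requires concatenating
sessions, and per-session PCA keeps the embedding self-contained.

Trajectory metrics: Gaussian product-kernel density with per-dimension
Silverman bandwidths (no kernel or bandwidth is pinned by convention;
Silverman is the neutral default), Euclidean speed between consecutive
1-s points of the *smoothed* coordinates (PC-score units per second), and
both engagement and performance overlays — either can be the behavioral
covariate of interest, so both are emitted.

On synthetic sessions the embedding reproduces the qualitative recovery
geometry: gradual emergence populates the region between the unconscious
and recovered cluster cores (intermediate state plus repeated
back-and-forth transitions), with elevated speed on the transit segments,
while an antagonist-mode session leaves that region essentially empty and
shows a single abrupt high-speed jump at the bolus.

## Statistics

Frequency-wise condition comparisons use a complete within-subject layout
(units × conditions × frequencies). The parametric branch is a one-way
repeated-measures ANOVA with Greenhouse–Geisser-corrected p-values (the
specific epsilon estimator is a package choice; sphericity is not
separately tested, and the correction is conservative for F ≥ 1); the
nonparametric branch is Friedman's test. Post hoc pairwise contrasts are
paired by default (within-channel differences; a flag switches to
unpaired) and flagged at the Bonferroni threshold 0.05/C(k, 2). `auto`
mode selects the branch by a Kolmogorov–Smirnov normality screen.

`ks_normality()` implements the limiting-form KS test against a normal
with the sample's mean and SD. Estimating parameters from the same sample
makes this p conservative; the Lilliefors variant (via the nortest
package) is available behind a flag and is documented as the statistically
stricter choice.

Bootstrap CIs: percentile and bias-corrected percentile, 1000 resamples by
default (the resample count is a package choice), with simulated coverage
within 95% ± 3%.

## The synthetic generator

`generate_session()` is first-class, tested code, not a fixture. Each
state segment emits its configured band components as **narrow-band
filtered Gaussian noise** (order-2 Butterworth magnitude response applied
spectrally), not pure sinusoids — pure tones would make coherence
degenerate and spectra unrealistically sharp. A configurable
`shared_fraction` of each component's power (default 0.8, i.e. a 4:1
shared-to-independent variance ratio) is common to all channels of a
region, driving both inter-channel coherence and the dominance of PC1 in
the ratio matrices; the remainder is channel-specific, on top of
independent white noise. Spindle bursts are Hann-enveloped sinusoids with
carriers uniform in 9–17 Hz, injected by a duration-corrected renewal
process (non-overlapping, realized rate equal to the nominal rate) and
logged exactly.

Default study conditions: 1 kHz sampling; 9/11/10 channels for S1/S2/PMv;
a 60-min infusion at 18 µg/kg/h for 10 min then 4 µg/kg/h for 50 min; a
10-min awake baseline and 60 min of recovery in the default timeline;
state transitions instantaneous at segment boundaries (a linear
cross-fade is available but defaults to 0 s so ground truth stays sharp).
Absolute band amplitudes are free parameters — no published calibration
of awake vs anesthetized absolute power exists for these recordings — and
the defaults simply place state components well above the 10 µV noise
floor. Behavioral response probabilities per state put awake/recovered
performance near ceiling (engagement 0.99–0.995, correct-given-engaged
0.99–0.995, consistent with animals trained to a > 90% correct criterion),
unconscious engagement at 0.02, and intermediate engagement at 0.5 to
reproduce the fluctuating early-recovery behavior.

What the generator does **not** emulate: biophysical (thalamocortical)
dynamics, pharmacokinetics, spike trains, cross-frequency coupling,
non-stationary drift, electrode artifacts, or realistic 1/f backgrounds.
Passing tests therefore certify the *estimators* — detection geometry,
recovery of known ground truth, invariants — not the biological claims;
applying the pipeline to real recordings remains subject to the usual
caveats (artifact screening, baseline stationarity).

## Numerical choices and degenerate inputs

* All intervals are half-open `[start, end)`; timestamps are seconds from
  recording start.
* Multitaper PSDs are one-sided in µV²/Hz and integrate to the signal
  variance (Parseval, verified to ±10% on white noise); coherence is
  clipped into [0, 1] against floating error.
* Degenerate inputs fail loudly: empty trial logs, zero-variance
  baselines, constant ratio matrices, epochs outside the recording,
  truncated session containers (size-checked against the JSON sidecar
  before any data are returned).
* Problem sizes in the test suite are chosen to exercise every code path
  at desk scale: 2–9 channels, sessions of 2.5–60 min, 20–50 seeded
  replicates per stochastic guarantee; the full suite runs in under two
  minutes on one core.

## Known limitations

* The 1-s ratio estimator has 2 Hz analysis bandwidth at NW = 2; Ratio2's
  1–8 Hz numerator therefore blurs slightly at its lower edge. This is
  intrinsic to per-second dots.
* EMD-based peak frequency cannot separate components closer than roughly
  a factor of 1.5 in frequency; the PSD fallback resolves such cases and
  is the recommended estimator for crowded bands.
* The spindle detector's duration gate measures super-threshold time, so
  reported durations understate the full envelope support of weak events;
  comparisons between periods remain valid because the bias is shared.
* Firing-rate z-normalization accepts spike-count series as given; spike
  sorting is out of scope.
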