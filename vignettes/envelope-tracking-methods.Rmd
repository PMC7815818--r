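---
title: "Methods: cortical tracking of the speech envelope with TRFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical tracking of the speech envelope with TRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`envtrack` quantifies how faithfully multichannel EEG tracks the slow
amplitude modulations of continuous speech. The analysis is a forward
(encoding) model: a temporal response function (TRF) $w(\tau, b, c)$ maps
time-lagged stimulus features to each EEG channel,

$$\hat{y}_c(t) = \beta_{0c} + \sum_{b=1}^{B} \sum_{\tau} w(\tau, b, c)\,
s_b(t - \tau),$$

where $s_b$ is the *envelope edge* (first temporal derivative of the
compressed envelope) in gammatone band $b$, and $\tau$ ranges over
$-100\ldots450$ ms (72 samples at 128 Hz; the lag index set is
`round(t_min*fs/1000):round(t_max*fs/1000)`, inclusive). Weights are
estimated by ridge regression,

$$\hat{w} = (X^\top X + \lambda m I)^{-1} X^\top y, \qquad
m = \mathrm{tr}(X^\top X)/p,$$

with the intercept column unpenalized. Scaling $\lambda$ by the mean
diagonal $m$ makes it dimensionless and comparable across track lengths and
feature scalings; the consequence is that $\lambda \approx 1$ already
shrinks substantially, which is why the default grid spans decade steps
$10^{-6}\ldots10^{6}$ rather than starting at $10^0$ — the lower decades are
needed for the near-noiseless regime where the cross-validated correlation
should approach 1.

The *cortical tracking metric* is the leave-one-track-out cross-validated
Pearson correlation between predicted and observed EEG, averaged over tracks
and then channels. Fold models are the average of per-track TRFs (the mTRF
toolbox convention). The ridge parameter is selected per subject and band by
maximizing the grand-mean correlation. Chance levels are the 97.5th
percentile of the same metric recomputed under derangements of the
stimulus/EEG track pairing (within subject, no identity pairs), which
preserves each subject's EEG statistics while destroying the
stimulus-response correspondence.

**A calibration caveat, found while validating this package.** The
mismatched-pairing chance level, as conventionally defined (derangements
only, exceedance of the 97.5th percentile), is measurably
*anti-conservative*: with stimulus-independent EEG the matched metric
exceeds the threshold in roughly 5–7% of replicates rather than 2.5%. Two
mechanisms contribute, both verified by direct simulation of the algorithm
on abstract data: (i) restricting the null to derangements breaks joint
exchangeability — under the matched (identity) pairing every pair of folds
contributes a reciprocal covariance term that derangement pairings mostly
lack, so the matched statistic has systematically higher variance than the
null draws; (ii) comparing against an empirical quantile without the
$(1+\#)/(B+1)$ Monte Carlo correction adds about another percentage point.
Sampling the *full* permutation group and using the corrected Monte Carlo
p-value restores exactness (measured 2.0% at nominal 2.5%). The package
implements the conventional procedure as specified; treat its chance level
as a descriptive benchmark rather than an exact 2.5% test, and expect the
corresponding calibration check in the acceptance suite to flag this.

## Stimulus model

Audio is decomposed by a bank of 16 fourth-order gammatone filters (Slaney's
all-pole cascade) with center frequencies uniformly spaced on the ERB-rate
scale $21.4\log_{10}(0.00437 f + 1)$ between 250 and 8000 Hz inclusive. Per
band: magnitude of the analytic signal (FFT Hilbert transform, 1 s
reflection padding), power-law compression with exponent 0.6 (an inner-ear
compression stand-in), anti-alias low-pass (raised-cosine taper opening at
$0.4\,f_{out}$), FFT resampling to the EEG rate (128 Hz), then the first
temporal difference scaled to per-second units. The derivative is kept
*signed* — onsets positive, offsets negative — because both event types
carry information; `rectify = TRUE` switches to onset-only features. The
resampling happens before differentiation so that the derivative is defined
on the clock the TRF is fit on.

## Preprocessing

Analysis bands are full (1–8 Hz), delta (1–4 Hz) and theta (4–8 Hz),
realized as two-pass (zero-phase) 4th-order Butterworth band-passes
implemented as second-order sections; `filter_response_report()` emits the
realized magnitude response so the filtering choice is auditable. Band
limited data are referenced to the common average and z-scored with a
*single pooled* mean/SD per subject (`zscore: pooled`), preserving relative
channel amplitudes that the TRF topography needs; a `per_channel` switch
exists. Epochs run from −5 to 70 s around track onset at full scale; the
pre-stimulus segment supports the RMS-ratio signal-quality proxy
(post 1.6–55 s over pre −2.6…−1.6 s).

## The synthetic world

The generator emulates the study design — 2 groups × 2 narratives ×
15 tracks × ~60 s × 32 channels at 128 Hz — and *inverts the analysis
model*: simulated EEG is the lagged envelope-edge design multiplied by a
known kernel plus $1/f$ noise. Stimuli are pink-noise carriers
amplitude-modulated by a quasi-periodic syllable train (rate 4.5 Hz,
narrative 2 uses 4.0 Hz; inter-pulse jitter ±20%), so the envelope spectrum
peaks near the syllable rate as real speech does.

Ground-truth kernels have two temporal components sharing a smooth Gaussian
profile across bands and a seed-fixed channel polarity map:

* a **slow component** (difference of Gammas, peak ~100 ms) whose spectrum
  lives almost entirely below 4 Hz — the delta-band encoding;
* a **fast component** (Gabor, carrier 7 Hz, temporal SD 120 ms, center
  175 ms) concentrated in the upper theta band, multiplied by
  `theta_gain` (2 for the patient-like group, 1 for controls).

Two construction details matter and were settled by measurement during
design, before the acceptance checks were frozen:

1. **Carrier choice.** At a 6.5 Hz carrier, enough of the (doubled) fast
   component leaks through the delta filter's roll-off at 4–5 Hz to create a
   spurious systematic delta-band group effect; at 7 Hz the leak is
   negligible and the dissociation is genuinely band-specific.
2. **Balanced polarity map.** An unconstrained ±1 channel polarity draw
   interacts destructively with common-average referencing (a 7:1 draw
   almost cancels the signal on majority channels), producing between-subject
   tracking variance that has nothing to do with the modeled biology. The
   map is therefore a balanced random assignment (half +1, half −1) — the
   zero-sum structure any average-referenced topography has.

`snr_db` calibrates the noise against the *gain = 1 reference* signal, not
each subject's own signal; otherwise the theta gain would be normalized away.
The default is −10 dB, which puts tracking correlations well below
saturation; group-level runs add N(0, 2 dB) per-subject SNR jitter as the
sole subject-level heterogeneity. Noise is $1/f$ (exponent 1) per channel
plus a 0.3-weighted common-mode component, so average referencing is
non-trivial; the pre-stimulus segment is noise-only by construction, making
the post/pre RMS proxy meaningful.

What a green test does **not** establish: the generator contains no
artifacts (blinks, muscle), no alpha or other oscillatory background, no
adaptation or nonlinearity, and no latency differences between groups; the
`theta_gain` magnitude is a calibration knob, not an estimate of the
clinical effect size.

## Group statistics

* **Mixed ANOVA (2 × 2).** Classical decomposition via the sum/difference
  contrasts: the group effect is tested against subject-within-group error,
  condition and interaction against the subject × condition residual; all
  dfs are (1, N−2). Generalized eta squared is
  $SS_e / (SS_e + \sum SS_{err})$ (Olejnik–Algina, no "observed" factors).
  With unequal group sizes the within-subject effects use unweighted
  marginal means (Type III); balanced designs reduce to the textbook
  formulas.
* **RAU.** Comprehension percentages are stabilized with Studebaker's
  rationalized arcsine transform before the ANOVA.
* **Cluster permutations.** TRF time courses (band-averaged, one electrode,
  Fz by default) are compared per lag with two-tailed, tie-corrected
  Wilcoxon rank-sum z statistics; clusters are contiguous runs with
  $|z| > 1.96$ (the conventional sample-level threshold — the source
  procedure does not state one), cluster mass is the signed sum of z, and
  the null is the max |mass| over relabelings. Rows are canonically ordered
  before null draws so results are invariant to the order subjects are
  supplied in. How the lag × band TRF is reduced to one plotted time course
  is unstated in the source; we average across bands and expose the choice.

## Numerical choices and degenerate inputs

* Lagged designs are zero-padded at track edges (keeps tracks equal length
  for correlation comparability); correlations use post-onset samples only.
* `fit_ridge` with $\lambda = 0$ on a rank-deficient system raises an error
  advising $\lambda > 0$; zero-variance data cannot be z-scored; a constant
  ANOVA cell with a non-zero effect raises a degenerate-design error rather
  than reporting an infinite F.
* Permutations and simulations take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical outputs.
* Design matrices, gram matrices and Cholesky factors are cached and shared
  across subjects (all subjects hear the same narratives), which is the
  main reason the full simulated study fits in minutes on one CPU.

## Known limitations

Backward (decoding) models, banded/multivariate regularization, spectrogram
or phoneme-level features, artifact handling (ASR/ICA/bad channels), EDF and
BrainVision ingestion, and spatial (channels × time) cluster adjacency are
out of scope; the portable container plus `epoch_tracks()` is the ingestion
path for real data. The mixed ANOVA covers the 2 × 2 design only.
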