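---
title: "Methods: IAF-anchored alpha PSD case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IAF-anchored alpha PSD case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restalpha)
```

## The analysis model

The package implements a complete case-control pipeline for the
resting-state alpha rhythm. The primary outcome per subject and electrode
is the *alpha PSD*: the mean one-sided power spectral density over the
closed window $[\mathrm{IAF} - 1, \mathrm{IAF} + 1]$ Hz, where the
individual alpha peak frequency (IAF) is the subject's main spectral peak
within 8–13 Hz. Anchoring the band at the individual peak rather than a
fixed 8–13 Hz window makes the outcome robust to between-subject
variation in alpha frequency, which is substantial (roughly 8.5–12.5 Hz
in healthy adults) and shifts with age and migraine.

Group comparison is deliberately nonparametric: alpha power is strongly
right-skewed across subjects (a Lilliefors-corrected Kolmogorov–Smirnov
screen, `ks_normality()`, is provided to verify this on real tables), so
the pipeline reports medians and interquartile ranges, uses the
Wilcoxon–Mann–Whitney test per electrode, and controls multiplicity with
the Benjamini–Hochberg step-up over exactly the 11-electrode posterior
region of interest. A Kruskal–Wallis omnibus on each subject's ROI-mean
alpha PSD acts as gatekeeper; post-hoc results are always reported but
carry a `nonconfirmatory` flag when the omnibus is not significant, so
exploratory use remains possible without silently dropping the gate.

## Preprocessing choices

**Filter.** The band-pass is a 4th-order Butterworth design (1–45 Hz)
applied with zero phase. Because no IIR-filtering infrastructure is
available in the dependency set, the squared digital Butterworth
magnitude — the exact steady-state transfer of forward–backward
filtering — is applied in the frequency domain on an odd-reflection
padded copy of each channel. This is numerically equivalent to
`filtfilt` away from the recording boundaries and strictly better at
them (no startup transients); residual edge effects are confined to
about $1/f_{\mathrm{low}}$ s. The tests verify passband gain at 10 Hz
within $\pm 1\%$, DC rejection, and 60 Hz attenuation below 0.05.

**Reference.** The retroauricular scheme subtracts the sample-wise mean
of T9 and T10 from every channel. The pair-mean reading was chosen over a
single linked electrode because it is symmetric; a single-electrode
scheme remains available via `reference.scheme`. Re-referencing is
idempotent and exactly common-mode-removing.

**Epoch selection.** Visual epoch selection is replaced by a
deterministic surrogate: the recording is tiled into non-overlapping
20-s candidates from $t = 0$, each candidate scored by the maximum
peak-to-peak amplitude over scalp channels, candidates above 400 µV
excluded outright, and the 8 lowest-scoring survivors kept (ties broken
toward earlier onset). The grid origin and tie-break are the simplest
deterministic choices; onset positions of manually selected epochs are
not reproducible anyway. An optional ICA stage (compact symmetric
fixed-point ICA with tanh contrast, deterministic identity
initialization) removes components correlating $> 0.8$ with the
Fp1/Fp2 blink template; it is off by default because the epoch screen
already rejects high-amplitude artifacts and a generic ICA is only a
rough surrogate for curated component selection.

## Spectral estimation

Welch's method with 4-s Hann segments at 50 % overlap gives
$\Delta f = 0.25$ Hz — five or more bins inside every $\pm 1$ Hz window —
and enough segment averaging (72 segments from eight 20-s epochs) for
stable peak detection. A single-FFT-per-epoch variant
($\Delta f = 0.05$ Hz) is available via `spectrum.seg_len_s`. The
normalization is the one-sided density convention
($\int S(f)\,df = \mathrm{Var}\,x$), verified against Parseval on white
noise and against an independent periodogram oracle.

**IAF detection.** The IAF is the largest PSD value in the closed 8–13 Hz
band that is a *strict, prominent* local maximum. Prominence — the peak
must be at least twice the aperiodic background predicted by a log-log
linear fit over 2–40 Hz (7–14 Hz excluded) — is part of the *quality
grading only*: an estimated spectrum has noise wiggles that are strict
local maxima at any SNR, so without a prominence requirement a channel
with no alpha rhythm would still be graded as peaked. On idealized
spectra where the background fit is undefined (exact spectral lines) the
check is skipped. When no prominent interior peak exists the band
maximum is reported with quality `boundary_peak` (a monotone 1/f
spectrum yields the lower edge); a constant band yields the lower edge
with `flat`. Ties break toward the lower frequency.

**The ±1 Hz window is not clipped** to 8–13 Hz: an IAF of 12.8 Hz
averages up to 13.8 Hz. The window is defined around the individual
peak, not intersected with the search band; this dialect choice is
explicit and tested.

**IAF mode.** Default is per-electrode IAF (each channel evaluated at its
own peak). `occipital_mean` mode applies the mean of the O1/O2 peaks to
every channel instead — both readings of "the" IAF are legitimate and the
choice is logged.

## The synthetic cohort: what it emulates, what it does not

Each channel is the sum of

* an aperiodic background, Gaussian noise shaped to
  $S(f) = s \cdot f^{-\beta}$ (plateaued below 0.5 Hz), default
  $\beta = 1.5$ and $s = 1\ \mu V^2/\mathrm{Hz}$ at 1 Hz;
* a narrowband alpha component: Gaussian noise with a Gaussian spectral
  envelope of 1 Hz FWHM centred at the subject's true IAF — band-limited
  noise, not a sinusoid, so spectra have realistic peak width and the
  ±1 Hz averaging is meaningful — scaled per channel to the topography
  weights occipital 1.0, parietal 0.7, P9/P10 0.5, temporal 0.35,
  central 0.3, T9/T10 0.2, frontal 0.1 (the inferior and central weights
  are this package's choice; only the occipital/parietal/temporal/frontal
  tiers were externally anchored);
* white sensor noise (SD 2 µV);
* Poisson blink transients (2/min, biphasic 0.5 s, 150 µV at Fp1/Fp2,
  half at F7/F8).

With the default base alpha amplitude of 1 µV RMS at the occipital
reference, group-median alpha PSD values land in the
$10^{-2}$–$10^{0}$ µV²/Hz range typical of published resting-state
tables; absolute magnitudes are an order-of-magnitude target only, since
they depend on spectral-estimation conventions that differ between labs.
Between-subject amplitude variability is a lognormal factor
(`amp_sdlog = 0.35`, chosen as a realistic ~35 % coefficient of
variation) shared across channels within a subject.

Cohorts are matched exactly by construction: age and sex are drawn once
per pair and copied; migraine flags are assigned to a fixed fraction
(default 14/21 ≈ two thirds, the comorbidity rate typical of the target
population) identically in both groups. IAF cell means default to
10.1 Hz (controls) vs 10.6 Hz (cases) without migraine and 10.3 Hz for
both groups with migraine, with doubled spread under migraine — this
reproduces the qualitative pattern the stratified IAF analysis is meant
to display (wider IAF distributions with migraine, higher IAF in
migraine-free cases) without asserting those numbers as measured
constants. The group effect is a multiplicative alpha-amplitude factor
$\delta$ applied to cases at the effect electrodes
{P3, P4, Pz, P10, T3, T4}; power therefore scales as $\delta^2$.

Not emulated: volume conduction and source mixing (channels are
independent up to the common reference), ocular/cardiac source
topographies beyond the frontal blink template, alpha reactivity
(eyes-open blocks), and non-stationarity over the recording. A green
pipeline test on this generator therefore establishes *statistical*
correctness of the analysis chain (calibration, recovery, determinism),
not robustness to every physiological artifact of real EEG.

## Statistical details and numerical choices

* **Mann–Whitney**: $U = \#\{x > y\} + \tfrac12\#\{x = y\}$. Exact
  two-sided p (doubled smaller tail of the full permutation distribution
  of $U$, computed by the standard counting recurrence) for tie-free
  samples with $n_x + n_y \le 12$; otherwise normal approximation with
  tie correction and continuity correction. The exact branch is verified
  against exhaustive enumeration; at 21 vs 21 the approximation's type-I
  error is calibrated to [0.035, 0.065] in the acceptance suite.
* **Kruskal–Wallis**: mid-rank H with tie correction, chi-squared
  reference. For two tie-free groups it matches the MWU normal
  approximation without continuity correction to $10^{-6}$ — this known
  equivalence is a cross-check in the tests. The $n \ge 5$ guidance for
  the chi-squared approximation is documented but not enforced, so
  degenerate-but-valid small inputs remain computable.
* **BH-FDR**: step-up with cumulative-minimum monotonization, capped at
  1, family = exactly the 11 ROI electrodes. Verified against a
  brute-force implementation of the definition to $10^{-12}$.
* **Normality**: Lilliefors-corrected KS with the Dallal–Wilkinson p
  approximation — accurate in the decision region ($p \lesssim 0.1$),
  conservative (capped at 1) above it; the screen's purpose is the
  at-level decision, not fine p-values.
* **Quantiles**: IQR = Q3 − Q1 with linear-interpolation quantiles
  (type 7). Table output rounds to 3 decimals half-up, matching clinical
  table conventions; all test comparisons use unrounded values.
* **EDF**: 16-bit plain EDF, one-second records, default physical range
  ±3276.8 µV (0.1 µV/bit, lossless for EEG-scale signals at the stated
  precision). Out-of-range signals raise an error instead of clipping.
  Headers carry a fixed epoch date so identical cohorts produce
  byte-identical files.
* **Topographic maps**: exact thin-plate-spline interpolation over the
  azimuthally projected unit-disc montage, masked to the head circle;
  grid cells whose nearest electrode carries no value are blanked, which
  renders untested regions white. Node-exactness is tested to $10^{-9}$.

## Known limitations

* Absolute PSD levels depend on unreported acquisition/estimation
  conventions in any published table; only rank-based statistics and the
  FDR arithmetic are exactly reproducible, and the acceptance targets are
  restricted accordingly.
* The omnibus reading (Kruskal–Wallis on the subject-level ROI mean) is
  one defensible interpretation of a "test across electrodes"; a min-p
  permutation alternative would be equally defensible and is noted as
  future work.
* The Dallal–Wilkinson approximation degrades for very small n (< 5,
  rejected) and large p (capped).
* The effect-recovery acceptance simulation is scaled to 20 cohorts of
  180-s, 4-epoch recordings for runtime; the nominal design point for
  that check is the same generator at 100 cohorts, and the observed
  margins (recovery 100 %, false alarms 0 % in the scaled run) leave
  ample slack.
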