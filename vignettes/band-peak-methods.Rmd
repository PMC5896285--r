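---
title: "Band-peak spectral features for single-channel EEG classification: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-peak spectral features: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbandpeak)
```

## The model

Eyes-closed EEG has a stereotyped spectral shape: 1/f background activity
carrying a dominant alpha-band (8–13 Hz) peak and weaker beta-band
(13–30 Hz) peaks. Mental and motor imagery tasks modulate the amplitudes
of these rhythms — attention-demanding tasks attenuate alpha, motor
imagery desynchronizes beta over the contralateral sensorimotor cortex —
while leaving the overall shape intact. The package's core assumption is
that these peak *amplitudes*, read off a single channel's power spectral
density (PSD), carry enough information to discriminate mental tasks.

The feature vector of one epoch is `(f1, f2, f3)`: the largest local PSD
peak value in the alpha band and the two largest local peak values in the
beta band. Everything else in the package exists to produce these three
numbers reproducibly (preprocessing, Welch estimation) or to measure what
they can do (classification protocol, voting, metrics).

## Pipeline stages and their parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| filter | cutoff, order | 50 Hz, 10 | removes line noise and high-frequency EMG while leaving alpha/beta untouched |
| segmentation | preparation cut, parts | 2 s, 2 | discards the cue/preparation period; two 4 s epochs per 10 s trial double the sample count at a spectral resolution still fine enough for band peaks |
| Welch | window, overlap | 400-point Hamming, 50 % | 9 averaged segments per 2048-sample epoch at 512 Hz; 1.28 Hz resolution places 4 bins in alpha and 13 in beta |
| bands | alpha, beta | [8, 13), [13, 30] Hz | standard clinical band edges; the half-open/closed split resolves the shared 13 Hz edge (below) |
| protocol | train/test/repetitions | 50 per class / 50 draws / 100 | repeated random subsampling; balanced test draws keep sensitivity and specificity well defined every repetition |
| SVM | C, sigma | 1, median heuristic | no tuning; the median pairwise training distance adapts the kernel width to the feature scale |

## Conventions fixed where the method leaves them open

Several details are under-determined by the method's description; the
package fixes each one explicitly. The band-peak features are invariant
to some of these (anything monotone per-spectrum, such as global PSD
scaling), but reproducibility requires a single convention.

**Filtering.** The Butterworth low-pass is designed by bilinear transform
with pre-warped cutoff and applied as a *causal* forward pass — not
zero-phase `filtfilt` — because the epochs should remain usable in online
settings where future samples are unavailable. A 10th-order direct-form
recursion is numerically fragile, so the design is factored into five
biquad sections (second-order sections), each with unit DC gain; the
cascade's measured response is −3.01 dB at the 50 Hz cutoff and −69.4 dB
at 100 Hz. Trials are filtered whole, before segmentation, so the filter
transient affects only the discarded preparation period.

**Welch estimation.** One-sided density scaling with window-power
normalization (`1/(fs * sum(w^2))`, interior bins doubled), symmetric
Hamming taper, per-segment mean removal as the only detrending, and
segments that would overrun the epoch end are dropped. With these
conventions the integral of the PSD approximates the signal variance,
which the tests verify both against an independently coded brute-force
periodogram average (agreement to 1e−10 relative error) and via
Parseval-style checks.

**Peak detection.** A peak is a bin strictly greater than both neighbors;
plateau bins never count. Candidates are ranked by descending PSD value
with ties broken toward the lower frequency. If a band holds fewer peaks
than needed, the largest remaining band bins (edges included) pad the
list, so the feature vector always has exactly three entries — the
classifiers need fixed dimensionality even on pathological spectra.
The alpha band is right-open and beta right-closed so the 13 Hz bin is
counted exactly once, in beta. Band *power* baselines integrate by
trapezoid over in-band bins only; with the half-open alpha band this
clips the edge half-bins, which is accepted as part of the band
convention rather than special-cased.

**Feature scale.** PSD values enter the classifiers on a linear scale,
not in dB. A log transform would change the classifier geometry and is
not silently applied; features are z-scored per evaluation repetition
using training-split statistics only, which removes scale sensitivity
without information leakage.

**Classifiers.** LDA uses the pooled within-class covariance with a ridge
of `1e-6 * trace/dim`, guaranteeing invertibility on degenerate training
draws (e.g. constant features) at negligible bias; its continuous
discriminant score feeds the ROC. The SVM's hyperparameters are not part
of the method, so the defaults are deliberately tuning-free: `C = 1` and
the median-distance sigma. A decision score of exactly zero classifies to
the first class of the pair. In `(f2, f3)` the two beta peaks are ordered
by descending amplitude, not by frequency.

**Protocol.** Training epochs are redrawn *every* repetition (not one
fixed split reused 100 times) — the more literal reading of repeated
random subsampling — and test draws are without replacement within a
repetition, balanced across classes. The positive class of a pair, for
sensitivity/specificity, is the first task in the fixed enumeration
RS < MA < RH < LH < LA; the same order breaks all voting ties.

**Multiclass voting.** Level 1: within each channel, the 10 pairwise
classifiers vote and the max-win task becomes the channel's label.
Level 2: channels vote, each weighted by its classification accuracy
(CA); the CA is estimated on the channel's own training epochs
(resubstitution), since no held-out data exists inside a repetition. An
unweighted (plurality) mode is also provided, and test draws are
balanced over the five tasks so chance level is exactly 20 %.

**Seeding.** A single global seed fans out to per-stage child seeds
through a fixed string hash of the stage name, so the generator, the
pairwise evaluations and the multiclass evaluation are independently
reproducible and adding draws to one stage does not perturb another.

## The synthetic generator

Each trial is `gain_ch * (alpha + beta1 + beta2 sinusoids) + 1/f noise`,
with per-trial uniform amplitude jitter (±20 %) and uniform phase shared
across channels, and pink noise drawn independently per channel (white
Gaussian noise shaped by `1/sqrt(f)` above 1 Hz, flat below). The default
five-task profiles encode the qualitative physiology: resting state has
the largest alpha peak, letter imagery a slightly smaller one, mental
arithmetic an attenuated alpha, and the motor imagery tasks have both
reduced alpha and reduced beta, with a 0.7 gain on the contralateral
central channel (C3 for right hand, C4 for left). Oscillation amplitudes
of order 1–4 against unit-scale pink noise give band peaks that stand
clearly above the background without making classification trivial. No
quantitative amplitude calibration to real recordings is claimed; the
defaults are free parameters chosen once.

The generator emulates exactly the structure the features exploit —
stable band peaks with class-dependent amplitudes — and nothing else. It
does not simulate eye blinks, EMG, electrode drift, non-stationarity
within a trial, inter-subject variability, or volume conduction. Passing
the pipeline's tests on this benchmark therefore demonstrates the
*mechanics* of the method (bookkeeping, estimator correctness, protocol
calibration, recovery of planted spectral contrasts), not its accuracy on
real EEG, which depends on how strongly real tasks modulate the rhythms.

## Degenerate inputs and numerical edges

* Epochs shorter than the Welch window are rejected with a suggestion to
  shrink it; bands containing fewer than three bins at the current
  resolution raise a resolution error.
* All-zero epochs produce all-zero spectra and the feature vector
  `(0, 0, 0)` via the padding fallback.
* Conflicting duplicate training labels, zero-variance features and
  singular scatter matrices are all handled without failure (ridge,
  sd-of-zero guard, SVM soft margin).
* Non-divisible segmentations truncate trailing samples with a warning.

## Known limitations

The two epochs cut from one trial share that trial's jittered oscillation
amplitudes, so they are correlated. Because the subsampling protocol
draws *epochs*, a test epoch's sibling can sit in the training set, which
inflates accuracy slightly above chance even for identically distributed
classes: the five-class null runs at roughly 24–25 % rather than 20 %
(the binary null stays within a point or two of 50 %). This is a property
of epoch-level subsampling itself, which the package reproduces
deliberately; trial-level splitting would remove it but would no longer
match the protocol under study. The chance-level tests account for the
effect's direction by bracketing rather than pinning the null accuracy.

Problem sizes in the test suite are scaled to what the checks need
statistically: full 512 Hz / 100-trial bookkeeping where counts are the
point, 256 Hz / 30–50 trials with 20–100 repetitions for the Monte-Carlo
recovery and calibration checks, chosen so each check's sampling error is
small against the margin it asserts.
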