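---
title: "Cardiac timing and blood pressure from Doppler radar: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac timing and blood pressure from Doppler radar: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models inside `radarbp`, the assumptions they
make, and the choices taken where the design was genuinely open. It states
no empirical numbers beyond what the test suite and `scripts/acceptance.R`
compute.

## 1. Signal model

A continuous-wave quadrature Doppler radar observing chest displacement
$x(t)$ at carrier wavelength $\lambda$ delivers the baseband pair
$$I(t) = \cos\!\big(\theta + 4\pi x(t)/\lambda + \Delta\Phi(t)\big), \qquad
  Q(t) = \sin\!\big(\theta + 4\pi x(t)/\lambda + \Delta\Phi(t)\big),$$
with $\theta$ a fixed demodulation phase and $\Delta\Phi$ residual noise.
Two consequences the package tests directly: the complex signal
$S = I + jQ$ of a target moving at constant velocity $v$ has its spectral
peak at $f = 2v/\lambda$, and the unwrapped angle of $S$, scaled by
$\lambda/4\pi$, returns $x(t)$ up to an additive constant. Note the
quadrature convention: the in-phase/quadrature pair differs by a
$\pi/2$ phase shift, i.e. $Q$ is the sine of the *same* phase argument
(writing $Q$ as a cosine of a sign-flipped phase, as sometimes printed,
would break $I^2+Q^2=1$ and the demodulation identity).

## 2. The synthetic cohort

The reference data for this class of method (supine resting adults, 24.25
GHz radar, synchronized ECG and continuous blood pressure, 1 kHz sampling)
are not publicly distributable, so the package generates its own cohorts
with known ground truth. Chest displacement is the sum of

* a respiration sinusoid (0.2–0.3 Hz, 1–3 mm),
* a raised-cosine cardiac pulse per beat (~0.1 mm, energy below 2 Hz),
* a Hann-enveloped vibration burst at each systole onset (S1-like: 12–24 Hz
  centre, ~80 ms, 70–120 µm) and a weaker, shorter, higher-pitched burst at
  each diastole onset (S2-like: amplitude ×0.75, duration ×0.75, frequency
  ×1.2, capped at 30 Hz).

Distinct S1/S2-like bursts mirror real heart-sound morphology (valve
closure is sharper and weaker than the ventricular contraction complex) and
give segmenters a legitimate cue besides inter-burst spacing. Beat-to-beat
intervals jitter multiplicatively (CV 2–8%), and the systolic fraction of
each beat (0.30–0.40 across subjects) drifts slowly within a subject
(amplitude 0.02, period 60 s), emulating autonomic modulation.

Noise enters as white Gaussian phase noise (default 0.03 rad) plus small
additive amplitude noise. The phase-noise default is calibrated so that the
integrated-spectrum burst peaks clear the noise floor by at least ~6 dB for
every subject the cohort sampler can draw: in-band phase noise adds
*coherently* to the burst phasor, so an under-margined burst is randomly
nulled in some beats, which no segmenter can recover from. The ECG channel
is an analytic P-QRS-T template of compact-support raised cosines, built so
the R-peak sample is the local argmax and the T wave returns to baseline
exactly at the labelled T-end — detectors on the clean ECG recover the
ground truth exactly, which is what makes it usable as the label source.

Per-segment blood pressure follows a linear coupling
$\mathrm{SBP} = a_0 + a_s\,\overline{\mathrm{sys}} +
a_d\,\overline{\mathrm{dia}} + a_i\,\overline{\mathrm{IBI}} +
\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 2$ mmHg and
one draw per segment (defaults $a_s=-60$, $a_d=-20$ mmHg/s for SBP:
shorter durations, higher pressure). The recording's continuous `sbp`/`dbp`
channels are a step-function rendering of these per-segment values; the
per-segment table is the authoritative target (re-averaging the rendered
channel would double-count the noise).

What the simulator does **not** model: body-motion artifacts, multi-target
scenes, antenna patterns, sensor nonlinearity, and the person-to-person
variability of the duration–pressure relation beyond the linear coupling.
Passing tests on this cohort therefore demonstrate correctness of the
pipeline's mechanics and its behaviour under the stated noise — not
clinical performance on real radar data.

## 3. Integrated spectrum

The 8–30 Hz band isolates the vibration bursts from respiration and pulse
wave. Filters are 4th-order Butterworth applied forward–backward: zero
phase, so no group delay biases the timing estimates. (The band-pass is
realized as a high-pass/low-pass cascade; a direct narrow band-pass at
0.5–2 Hz/1 kHz normalized frequency is numerically unstable in double
precision.) The STFT uses a 256 ms Hann window — shorter than any plausible
IBI, so a frame sees at most one burst — zero-padded to 1024 points, and the
power is folded one-sided and scaled so that a rectangular-window full-band
sum reproduces the frame energy exactly (Parseval; this scaling is what the
acceptance script checks). Frame timestamps are window *centres*: with
start-stamps every spectral peak would lag its burst by half a window
(128 ms), breaking the peak-to-burst alignment property.

The STFT input is the band-passed **complex** signal $S(t)$, not its
magnitude: for a phase-modulated carrier the band-passed complex signal is
approximately $je^{j\phi_{\mathrm{slow}}}\,\beta(t)$ with $\beta$ the
band-limited phase signal, so its energy sits at the burst frequency inside
the integration band, whereas the magnitude is a rectified signal whose
energy moves to DC and twice the burst frequency — largely *outside* 5–30
Hz. Integration sums bins in 5–30 Hz inclusive (the sub-8 Hz bins carry
essentially nothing after the 8–30 Hz filter, so the literal band pair is
harmless). The pipeline computes frames directly at an 8 ms step — identical
to computing at 1 ms and keeping every 8th frame — giving a 125 Hz frame
rate aligned with the down-sampled label grid.

## 4. The hidden semi-Markov model

Four states in a fixed cycle: systole-onset vibration → systolic interval →
diastole-onset vibration → diastolic interval. The topology is nonergodic
(each state reachable only from its predecessor), so the transition matrix
is implicit and all modelling lives in the dwell distributions $p_j(d)$ and
the emissions $b_j(O_t)$.

* **Emissions**: multinomial logistic regression on three per-frame
  features — min–max-normalised energy, its first difference, and a 100 ms
  moving-average envelope. Posteriors (uniform class priors are not imposed;
  the cyclic decoder supplies the structure) are floored at $10^{-12}$
  before logs.
* **Dwell distributions**: discretized Gaussians on $[d_{\min}, d_{\max}]$,
  fitted per state from uncensored run lengths (first/last runs of each
  sequence are excluded), standard deviation floored at 2 frames. Bounds at
  125 Hz: vibration states 3–25 frames (24–200 ms); systolic interval 5–70
  frames (≤ 0.56 s); diastolic interval 5–130 frames (≤ 1.04 s). The
  quiescent caps matter: a loose cap (say 1.6 s) lets the decoder absorb an
  entire skipped beat into one run at high heart rates, silently deleting
  beats.
* **Decoding**: dwell-extended Viterbi in the log domain with prefix-summed
  log-emissions, $O(T \cdot N \cdot d_{\max})$. The analysis window cuts the
  cycle at an arbitrary phase, so the first and last runs are scored with
  the dwell *survival* function instead of the pmf, and the initial
  distribution is uniform. Ties break toward the smallest dwell — decoding
  is deterministic. An exhaustive reference decoder (`brute_force_decode`,
  guarded to $T \le 30$) scores every duration-segmented cyclic path with
  the same boundary-censored product; the test suite and acceptance script
  require exact path agreement on random instances.

Training labels come from ground truth: state 1 spans the burst window at
each R peak, state 3 the (shorter) burst window at each T-end, states 2/4
the remainders.

## 5. The 1D U-net

The reference architecture: 1024-point single-channel input; three encoder
blocks of twice {Conv1D(k=3, same) + batch norm + ReLU} with filters
(32, 64, 128) and 2× max pooling; a 256-filter bottom block; a mirrored
decoder (nearest-neighbour ×2 upsampling, concatenation with the matching
encoder block's pre-pool activations, two convolutions); final Conv1D(k=1)
with a sigmoid (keeps outputs in [0, 1] for the MAE loss against 0/1
labels; no output activation is prescribed, so the saturating choice is
ours). Training: Adam, MAE loss with MSE monitored, batch 256 for 100
epochs at learning rate 0.001 in the full regimen.

No deep-learning framework ships with this package's dependency set, so the
network runs on a compact conv-engine written here: activations are
$(N\!\cdot\!L)\times C$ matrices, convolutions are im2col + BLAS matrix
products, and backpropagation is hand-derived (and verified against
numerical gradients in the test suite). One engine subtlety worth recording:
the optimiser walks the parameter and gradient trees positionally, so batch
norm's running statistics carry explicit zero gradients — otherwise they
would be silently "updated" with the gamma/beta gradients.

**Scaled-down regimen.** Cohort-sized experiments (tens of subjects ×
minutes, CPU-only) use `unet_config_scaled()`: quarter-width filters
(8, 16, 32; bottom 64), 15 epochs, batch 8, learning rate 0.003. Width was
fixed up front on compute grounds; batch 8 (not 256) and lr 0.003 (not
0.001) because ~200 windows × 15 epochs at batch 256 would give Adam a few
dozen steps — far too few to converge. The acceptance experiments state
their problem sizes (10–11 subjects × 120 s) as the package's scaled study
conditions.

**Input/label grid.** Each 10 s window's integrated spectrum (1219 frames at
125 Hz after windowing) is min–max normalised per window and linearly
resampled to the fixed 1024-point grid; labels are evaluated at the same
resampled timestamps (systole 0, diastole 1, pre-first-R frames inherit the
in-progress diastole). Training windows are *time-scale augmented*: their
spans are drawn uniformly in 8–12.5 s before resampling, exposing the
network to ±25% apparent heart rate. Without augmentation the network
extrapolates badly to held-out subjects whose heart rates fall outside the
training subjects' range — dwell priors give the HSMM this robustness for
free; the network has to be taught it.

**Mask to beats.** Predictions are binarised at 0.5; interior runs shorter
than resting-physiology floors — 0.12 s for systole, 0.2 s for diastole —
are merged into their neighbours (the mask-domain analogue of the HSMM's
minimum dwells; a uniform 40 ms floor leaves confident 0.2–0.3 s
hallucinated systoles inside the long diastoles of slow subjects, and a
single such insertion corrupts a whole segment's mean IBI), and each
interior 0-run/1-run pair becomes one beat. At the
subject level the overlapping windows' soft predictions are first stitched
onto the 125 Hz frame grid (averaging where two windows overlap) and beats
are extracted once from the stitched mask — per-window extraction followed
by duplicate-merging loses edge-censored beats and creates boundary
artifacts.

## 6. Features and blood-pressure regression

Per beat: IBI, systolic and diastolic durations (systolic + diastolic = IBI
by construction for every source) and the pulse-wave width at 25% of the
beat's peak above its window minimum (per-beat baseline; robust to slow
drift; linear interpolation at the level crossings). Per 10 s segment
(5 s overlap): arithmetic means over beats fully inside the window. Beats
straddling boundaries count for neither side. The conventional baseline
derives beats from the 0.5–2 Hz pulse wave (falling interval = systole),
with peak picking at minimum separation 0.3 s and prominence 0.2× the
signal IQR — the conventional filter-based approach this method is designed to improve on;
its systematic lag relative to the R peak can exceed the ±0.4 s beat-matching
tolerance for slow pulses, in which case those beats simply go unmatched.

The regressor is a random forest per target (SBP, DBP), hyperparameters
grid-searched over trees {100, 300, 500} × depth {∞, 5, 10} × minimum node
size {1, 5} by subject-grouped inner 3-fold CV on the training segments
only, then refitted. Evaluation is subject-grouped 5-fold CV — no subject's
segments ever span a train/test boundary, asserted per fold. "STD" is
reported as the standard deviation of the *absolute* errors, matching the
mean-absolute-difference ± SD convention; readers comparing against
sources that report the SD of signed errors should note the difference.

Two estimator-training protocols are provided. `per_fold` retrains HSMM and
U-net inside every CV fold on that fold's training subjects — the full
protocol, used in the smoke tests. `holdout` trains them once on a dedicated
majority partition of subjects (6 of 11 in the acceptance experiment) that
is then excluded from the BP evaluation; it is equally leakage-free,
mirrors the direction of an 80/20 subject split, and makes multi-seed
replication tractable on one CPU. Under `holdout` the estimator subjects'
(in-sample-decoded) features join the regressor's training pool — they never
enter a test fold — because a forest trained on four subjects' feature range
extrapolates poorly to a fifth.

## 7. Numerical and degenerate-input conventions

* Min–max normalisation maps constant inputs to all-zeros.
* Emission features are invariant to positive rescaling of the energy.
* The Viterbi recursion floors emissions at $10^{-12}$ and dwell masses at
  $10^{-300}$ before logs; infeasible decodes (window shorter than any
  admissible dwell structure) raise an error rather than returning a path.
* Segmentation drops a trailing remainder shorter than one window; a
  recording shorter than one window yields an empty list with a warning.
* The 16-bit integer recording codec stores per-channel offset/scale in the
  header; decode∘encode is the identity on the quantized grid.
* All randomness — cohort sampling, noise, network initialisation and batch
  order, forest fitting, CV assignment — flows from explicit integer seeds;
  repeated runs are bit-reproducible.

## 8. Known limitations

* The simulator's bursts are stationary within a subject; real
  seismocardiographic morphology varies beat to beat.
* The duration–pressure coupling is linear with homoscedastic noise; the
  regression task is therefore easier than on real subjects, and the gap
  between feature sources compresses toward the noise floor.
* The scaled U-net regimen trades accuracy for CPU time; the full Table-style
  regimen is available through `unet_config()` but is not exercised by the
  test suite.
* The HSMM's dwell caps encode resting physiology; exercise or arrhythmia
  would violate them.
* Under the linear duration–pressure coupling, segment-mean IBI carries
  nearly all of the predictable BP signal, so once every feature source
  estimates IBI well, their BP errors converge to the noise floor and
  separate by less than the per-replicate estimation noise. The relative
  quality of the feature sources is therefore visible in duration space but
  compresses, on this synthetic task, in blood-pressure space — a property
  of the simulated coupling, not of the estimators.
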