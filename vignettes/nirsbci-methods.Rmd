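---
title: "Methods: simulation and classification of short-channel-corrected prefrontal fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and classification of short-channel-corrected prefrontal fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirsbci` implements an end-to-end passive BCI analysis for prefrontal
fNIRS: a generative model of multichannel sessions, the standard conversion
and denoising chain (Modified Beer-Lambert Law, bandpass, short-channel
recursive least squares), windowed feature extraction, a suite of six
classifier families, and participant-level evaluation with online replay.
This vignette records the model, its assumptions, the tunable parameters,
and the design decisions taken where the design was genuinely open.

## The measurement model

A single-detector probe over left prefrontal cortex carries six long source
positions — three over a relatively lateral aspect (dorsolateral prefrontal
territory) and three over a relatively medial aspect (anterior
medial/default-mode territory) — at 3.0 or 3.61 cm from the detector, and
one short position per side at 1.5 cm. Short separations sample only
extracerebral (scalp/skull) haemodynamics, which makes them pure regressors
for the systemic physiology that contaminates the long channels. Each
position emits at 690 and 830 nm; intensity changes convert to chromophore
concentration changes via the Modified Beer-Lambert Law,

$$[\Delta HbO, \Delta HbR]^T = E^{-1}\,\Delta OD / (d \cdot DPF),$$

with $\Delta OD(\lambda, t) = -\log_{10} I(\lambda,t)/I_0(\lambda)$, $E$ the
2×2 extinction matrix, $d$ the source-detector distance and $DPF$ the
differential pathlength factor.

**Numerical choices.** $E$ uses the Gratzer/Prahl compilation at 690/830 nm
(0.276/2.052 and 0.974/0.693 cm⁻¹mM⁻¹); $DPF = 6.0$ at both wavelengths, a
common adult-forehead value; both are configurable. The baseline reference
$I_0$ is the *geometric* mean of intensities over the baseline window
(default: the first 10 s of the session). The geometric mean is the mean in
optical-density domain, which keeps baseline referencing exactly linear:
the recovered concentration series equals the generating series referenced
to the same window, to machine precision. An arithmetic-mean reference
would introduce a small nonlinear offset with no physical content.

## The generative model

Each synthetic session follows a three-group block protocol: per group, one
visualization block, 120 s rest, one workload block, 120 s rest. Groups 1–2
are training data, group 3 is the real-time test group. For long channel
$c$ on side $s$:

$$y_c(t) = \beta_{s,\text{task}} \cdot (h * b_{\text{task}})(t) + g\,u_s(t) + \varepsilon_c(t),$$

where $h$ is a canonical double-gamma HRF (gamma-density difference with
response peak at 6 s, undershoot peak at 16 s, ratio 1/6, normalised to
unit plateau), $b_\text{task}$ the task boxcar, $u_s$ a superficial process
shared by all channels of side $s$ (one per chromophore), $g$ the
superficial coupling gain, and $\varepsilon$ white noise. Short channels
observe $u_s$ with gain 1 and *no* task-locked term — the idealisation that
makes short-channel regression exactly testable: with zero white noise and
$g = 1$, long minus short leaves the pure task response, and the recovered
RLS slope equals $g$.

$u_s$ is a sum of cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave
(0.10 Hz) sinusoids with participant-random phases, plus a slow random-walk
drift. The 1.1 Hz cardiac component is deliberately generated at the
sampled rate (band-limited synthesis): at 5.8 Hz sampling it is directly
representable, and the analysis bandpass removes it in any case. HbR task
responses are $-0.3\times$ the HbO response (typical inverted, smaller HbR
response); HbR systemic oscillations are scaled to 0.3 of the HbO
amplitudes with independent phases.

**Default amplitudes** (µM): engaged-side task response 0.4, non-engaged
side 0.1 — a double dissociation in which visualization drives the medial
channels and workload the lateral ones; Mayer 0.15, respiration 0.10,
cardiac 0.08, drift 0.10, white noise 0.02 per sample; $g = 0.8$.
Participant variability multiplies effect and noise amplitudes by
log-normal factors (σ = 0.2) drawn once per participant. These magnitudes
are in the range typically reported for frontal task responses and systemic
oscillations after MBLL conversion; the in-band Mayer component is
intentionally larger than the white-noise floor so that short-channel
regression, not averaging, is what rescues the signal.

**Task block duration** is participant-paced in the experimental paradigm
this emulates, so it is a free parameter. The default is 60 s: a standard
fNIRS block-design length, and the shortest compatible with the largest
analysis window swept by the offline analysis (300 frames = 51.72 s).
Sample counts use a fixed rule, $\lfloor d \cdot f_s + 10^{-9}\rfloor$ with
$f_s$ fixed at exactly 5.8 Hz.

**What the generator does not emulate:** motion artifacts and spikes,
photon-transport forward modelling, phase (frequency-domain) measurements,
serial correlation of the white-noise floor, and task-correlated systemic
physiology (the superficial process is task-independent by construction).
Passing tests therefore demonstrate correctness of the pipeline's
machinery, not performance on real recordings — where superficial
physiology *can* correlate with the task, and short-channel regression is
correspondingly less clean.

## The processing chain

Order of operations: MBLL conversion → 0.1–0.4 Hz bandpass → RLS
short-channel regression → windowing → feature scaling → (online only)
F-test feature selection → classifier.

**Bandpass.** Third-order Butterworth, 0.1–0.4 Hz. Two modes: zero-phase
forward-backward filtering for offline analysis (no group delay), and a
causal single pass for the real-time path. Whether the original real-time
band was causal is not documentable from the analysis narrative alone; the
pipeline defaults to causal for training-and-replay and zero-phase for
cross-participant analysis, and either can be forced.

A consequence worth stating explicitly: a 0.1 Hz high-pass edge removes the
sustained plateau of a long block response almost entirely. What survives
is the onset transient (and filter ringing) in roughly the first 20 s of
each block. Windows that contain the onset are highly discriminable;
mid-block windows carry almost no task information. This is why larger
windows — which always contain the onset — classify better in the window
sweep, a trend the offline analysis of the underlying study also shows, and
why the 100-frame online pipeline is intrinsically hard: only one of the
three windows per 60 s block is informative.

**RLS.** One filter per (side, chromophore), regressors = that side's short
channel plus an intercept (the underlying description is silent on the
intercept; including it costs nothing and absorbs baseline offsets).
Standard recursion with forgetting factor λ = 0.999 and $P_0 = \delta I$,
δ = 100 — the cited adaptive-filtering method states no constants, so
defaults follow common RLS practice: λ near 1 for slowly varying coupling,
δ large enough to act as a weak prior. With λ = 1 the recursion converges
to batch least squares (verified against `lm()` to 1e-4 relative
tolerance). Coefficients are fitted on the concatenated task samples of the
training trials (rest excluded) and frozen for all later application.

**Features.** Non-overlapping windows of exactly W frames within each task
block, partial trailing windows dropped; rest is never windowed (the
classifier is binary). Online: max and mean per channel (12 channels × 2 =
24 features), z-scaled with training-set parameters, top 10 by one-way
ANOVA F statistic. Offline: five statistics (max, mean, sd, Fisher skew
defined as 0 at zero variance, OLS slope per *second* so values are
sampling-rate invariant), no selection, W swept over
{50, 100, 150, 200, 250, 300}. Scaling operates on features rather than on
the pre-windowing time series — the frozen-coefficient description of the
online path (train-time scaling parameters applied unchanged at test time)
is only coherent for feature scaling.

**Classifiers.** Fixed grids: SVM C ∈ {0.1, 1, 10}; KNN k ∈ {3, 5, 7, 9};
QDA regularisation ∈ {0.1, 0.5, 1}; ANN hidden layer ∈ {10, 50} at 5000 max
iterations; RF trees ∈ {10, 50, 100, 200}; LDA has no grid. The linear SVM
is libsvm's hinge-loss machine (`e1071`); the original online model was a
squared-hinge linear SVM — same model family and regulariser, slightly
different loss, immaterial at these separations. The regularised QDA is
implemented in-package as a Gaussian discriminant with
$\Sigma_r = (1-r)\Sigma + rI$ on standardised features (the classical QDA
implementations expose no such parameter); at $r = 1$ it reduces to a
nearest-mean rule and agrees with LDA on spherical classes, which is tested.
The ANN is `nnet`'s single-hidden-layer network (logistic units, BFGS) —
the one mature, dependency-free neural classifier in R — with size and
iteration cap as specified; remaining settings are the implementation's
documented defaults. KNN and RF predictions seed the RNG from the stored
model seed so distance/vote ties resolve deterministically.

## Evaluation

**Metrics.** Macro precision, recall and F1 are unweighted means of the
per-class quantities computed from the pooled confusion matrix; any 0/0 is
defined as 0, the convention under which degenerate folds print 0.000.
Cohort spread of per-participant macro F1 uses the population
(n-normalised) standard deviation — the convention that reproduces the
published cohort value (0.282; the sample estimator gives 0.302).

**Online replay.** The frozen bundle (RLS coefficients, scaler, selected
features, classifier) walks the test group in contiguous 100-frame steps,
emitting floor(n/100) predictions per block with no state updates; replay
is bit-reproducible.

**LOO-CV.** Each fold holds out one participant entirely; RLS and scaler
are refitted on the remaining cohort only, and hyperparameters are chosen
by an inner leave-one-participant-out loop over the training cohort (best
mean inner macro F1, ties to the smallest grid value). A structural leakage
guard fails hard if the held-out participant's windows appear in any
fitting call. Both pooled-count and per-fold-mean aggregations are
reported; they differ legitimately when folds have unequal window counts or
degenerate per-fold confusions, which is why neither is privileged.

## Problem sizes and power

The synthetic study conditions are 8 participants under the default
strong-effect regime. At W = 300 the cross-participant analysis reaches
pooled macro F1 ≈ 0.87–0.98 (RF / linear SVM), and the label-permutation
null at W = 50 (288 windows) sits near 0.5, bracketing the pipeline from
both sides. The per-participant online configuration is data-starved by
design (12 training windows, one informative test window per block);
development measurements put its pooled replay accuracy near 0.58. The
replay significance check therefore pools 128 independently seeded sessions
(768 windows): at accuracy 0.58 a one-sided binomial test at α = 0.01 then
has ≈ 99% power, so the check reflects the presence of signal rather than
sampling luck.

## Known limitations

* Short channels observe the superficial process noiselessly apart from
  white noise, and superficial physiology is task-independent; both are
  idealisations chosen to make filter recovery exactly testable.
* The CSV session format is the only on-disk format; SNIRF/HDF5 export is
  out of scope here.
* No motion-artifact model, no wavelet/PCA correction, no frequency-domain
  (phase) processing.
* Inner CV selects classifier hyperparameters only; window size and source
  subset are swept, not selected, mirroring the reporting structure of the
  analysis this package operationalises.
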