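---
title: "Detecting and classifying adventitious breath sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying adventitious breath sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auscultr)
```

## The problem

Chest auscultation separates pediatric lung sounds into three recording-level
classes: **crackles** (brief, explosive, discontinuous sounds associated with
pneumonia and other parenchymal disease), **wheeze** (continuous musical
sounds associated with airway obstruction and asthma), and **normal** breath
sounds. Recognition by ear is subjective and depends heavily on the
listener's training, which motivates algorithmic analysis of electronic
stethoscope recordings and, equally, a defensible procedure for constructing
reference labels from panels of human raters.

`auscultr` implements a complete recording-level pipeline:

1. **audio I/O and screening** — WAV input, metadata manifests, rejection of
   recordings that are too short (< 9 s, the length needed for at least two
   breathing cycles) or of low quality;
2. **rule-based event detection** — time-domain criteria for crackle and
   wheeze events;
3. **wavelet-packet features** and a **three-class SVM** at recording
   granularity;
4. **gold-standard consensus** over specialist rater triples with expert
   adjudication;
5. **evaluation statistics** — confusion matrices, per-class sensitivity /
   precision / specificity / F1, weighted Cohen's kappa with confidence
   intervals, Kendall's W, chi-square tests;
6. a **seeded synthetic simulator** that provides ground-truth event logs
   for end-to-end validation.

## The event rules

The classic time-domain operational criteria are:

* a **crackle** is a transient shorter than **20 ms** whose peak magnitude
  exceeds **twice the average magnitude** of the signal;
* a **wheeze** is an event lasting at least **500 ms**, found by comparing
  the peak of the **160 ms** window centred on each sample of the
  **200 ms Hamming-smoothed** magnitude envelope against the envelope mean.

These thresholds are exposed in `detector_config()` and are applied verbatim
as the *qualification* stage of detection. They are, however, not usable on
their own as a *candidate search* statistic: for band-limited noise roughly
10 % of samples exceed twice the mean absolute amplitude, so a raw threshold
crossing would emit dozens of spurious "crackles" on every normal recording.

### Candidate localization by linear-prediction whitening

Lung-sound background is narrowband and therefore highly *predictable*; a
crackle is impulsive and unpredictable. `detect_crackles()` exploits this by
running an AR(16) linear-prediction-error filter (Yule-Walker fit) over the
band-passed signal. The whitened background drops by an order of magnitude
while the transient passes nearly untouched: on simulated recordings the
background's whitened-envelope maxima measure about 5-6 times the robust
mean magnitude, while event responses measure 80 and above, even at event
peaks only 10 dB above the background RMS. Candidate runs are the excursions
of the 1 ms-smoothed whitened envelope above a constant-false-alarm guard
(`whiten_guard`, default 12 — approximately the geometric midpoint of that
measured gap on the logarithmic scale).

Two refinements matter in practice:

* **Two-pass fitting.** A recording containing many crackles flattens the
  autocovariance and halves the whitening gain. The AR model is therefore
  fit twice: candidates from the first pass are masked out of the fitting
  copy (2 ms dilation) before the second fit. Event-free recordings are
  unaffected (the first pass finds nothing to mask).
* **Edge handling.** The zero-phase Butterworth band-pass is applied over a
  0.5 s reflection-padded copy of the signal; without this the filter's edge
  transients dominate the whitened envelope at the recording boundaries.

Each candidate is then *qualified* by the field's rules: its duration,
measured as the −6 dB width of the band-passed envelope around the candidate
peak (a standard pulse-width definition), must be below 20 ms, and its peak
magnitude must be at least `crackle_peak_ratio` (2.0) times the average
magnitude. Candidate runs closer than 5 ms are bridged first, because the
rectified envelope of a damped oscillation dips between half-cycles and
would otherwise split one crackle into several sub-millisecond events.

For wheezes, the bare mean-crossing of the smoothed envelope fires on noise,
so the windowed peak must exceed the envelope mean by a margin
(`wheeze_margin`, default 2.0, parallel to the crackle criterion). Active
runs are refined to the envelope's own threshold crossings — the 160 ms
rolling maximum alone would smear each boundary by ±80 ms — merged across
gaps below 50 ms, and kept when at least 500 ms long.

All detector thresholds are ratios, so detection is invariant to positive
amplitude scaling of the input.

## The synthetic simulator

`simulate_recording()` emulates the statistical structure the detector
assumes, with ground-truth logs for every injection:

* **Background**: pink-weighted Gaussian noise band-passed to 100-1000 Hz
  (the band carrying most vesicular-sound energy), amplitude-modulated by a
  raised-sinusoid breath envelope with a 3 s period and modulation depth 0.6
  — a clearly audible but not silence-punctuated breathing rhythm.
* **Crackles**: exponentially damped sinusoids `A e^(-t/tau) sin(2 pi f t)`
  with `tau = duration/5`, centre frequency uniform in 200-2000 Hz, duration
  10 ms by default (the rules require < 20 ms).
* **Wheezes**: monophonic tones with 50 ms raised-cosine ramps at the
  requested frequencies, at least 500 ms long.
* **Event strength**: `snr_db` sets the injected peak amplitude relative to
  the background RMS. The default of 20 dB models the clearly audible
  adventitious sounds of a well-seated chest piece; detector performance is
  additionally validated down to 10 dB.
* One event *kind* per recording: corpora built by `build_corpus()` contain
  crackle, wheeze and normal recordings, never mixed ones, mirroring the
  exclusion of mixed findings from gold-standard corpora. (The detector
  itself labels mixed-event recordings rather than rejecting them.)

What the simulator does **not** emulate: heart sounds, crying/speech
interference (a tone-burst contaminant generator exists but is off by
default), sensor and airflow artifacts, polyphonic or inspiratory-gated
events, and the acoustic diversity of real patients. Passing the synthetic
recall and accuracy bars therefore demonstrates internal consistency of the
pipeline — the detector recovers exactly the structures the rules describe —
not clinical-grade performance on hospital recordings.

Every simulation is driven by an explicit integer seed; identical seeds give
bit-identical audio and logs.

## Features and classifier

`wpd_features()` computes a full wavelet-packet tree (default `db6`, depth
4) over the band-passed recording, implemented as periodized circular
convolution-decimation so that the transform is exactly orthogonal: the 16
terminal subband energies sum to the signal energy to machine precision
(the suite asserts 1e-8 relative over random signals). Signals are
zero-padded to a multiple of `2^depth`; terminal nodes are reported in
natural frequency order (the high-pass/decimate branch mirrors the frequency
axis, so child order alternates). Per subband the features are the log
energy (floored at 1e-12) and the normalized Shannon entropy of squared
coefficients — 32 values regardless of signal length. `db6` at depth 4 is
the common choice in the lung-sound wavelet literature: at 8 kHz it yields
250 Hz-wide subbands, fine enough to isolate a wheeze tone while keeping
the feature count modest. The whole recording is summarized by one vector
(classification is per recording, matching how reference labels are
assigned); a hybrid mode appending detected-event counts exists but is off
by default so the feature contract stays purely spectral.

`train_classifier()` fits one-vs-rest RBF SVMs (via `e1071`, default
`C = 1`, `gamma = 1/n_features`) on features standardized by the training
mean and variance, which travel inside the model bundle together with the
class order, the seed, the hyperparameters and an md5 fingerprint of the
training corpus. One-vs-rest (rather than libsvm's native one-vs-one) keeps
one calibrated decision value per class, and inverse-frequency class
weights guard against the imbalance typical of clinical corpora. Classifier
outputs are always one of crackle/wheeze/normal; `indeterminate` is a
human-rater-only value and is rejected in training labels.

## Gold-standard consensus

Each recording is rated independently by three specialists, any of whom may
mark it `indeterminate`. `specialist_round()` is total over the 4³ = 64
label triples:

* unanimous non-indeterminate → **accepted** (provenance `unanimous`);
* two or more indeterminate → **rejected**;
* exactly two agreeing on a non-indeterminate label → **expert
  adjudication** (`adjudicate()` either supplies the final label or
  rejects);
* anything else (no two raters agree) → **rejected**.

Exhaustive enumeration under these rules partitions the 64 triples into 3
accepted, 27 needing adjudication and 34 rejected; the test suite verifies
this against an independently written brute-force oracle, along with full
symmetry under rater permutation (rater identity never enters the rules).
One triple class is genuinely ambiguous: (X, X, indeterminate). The package
routes it to adjudication by default — only a fully consistent triple should
qualify directly, but a 2-vs-unsure split is evidence worth an expert look —
and exposes `indeterminate_pair_policy = "reject"` for the stricter reading
(which moves those 9 triples, giving 3/18/43).

## Evaluation statistics

All metrics reduce to the 3×3 confusion matrix (rows gold standard, columns
prediction). Per-class metrics use the one-vs-rest reduction; the "mean" row
averages the two adventitious classes only, as in the conventional summary
table. Zero denominators propagate `NA`, never 0. Percentages are computed
at full precision and rounded half-up to one decimal only in the reporting
layer (`metrics_table()`, `round_half_up()`).

`cohens_kappa()` supports identity, linear and quadratic agreement weights
over an explicit category order; the default is unweighted, because the
three breath-sound classes are nominal, and the weighting used should
always be stated next to the value. The confidence interval uses the
asymptotic Fleiss-Cohen-Everitt standard error (verified against an
independent implementation to 1e-9 in the suite). `kendalls_w()` embeds the
nominal labels in an explicit ordinal category order (default
normal < crackle < wheeze — arbitrary, configurable, and flagged in the
output) and applies mid-rank tie correction. `chi_square()` delegates to
`stats::chisq.test(correct = FALSE)` after checking the margins.

## Numerical and design choices

* Canonical analysis rate 8 kHz; other device rates are polyphase-resampled
  on load (lung-sound energy lies well below 4 kHz).
* Events use half-open time intervals `[onset, onset + duration)` in seconds
  from recording start.
* "Low quality" is operationalized as more than 1 % of samples at full scale
  (clipping) or RMS below 1e-5 (dead signal).
* The detector band-pass is 100-2000 Hz (4th-order zero-phase Butterworth),
  covering crackle and wheeze energy at 8 kHz sampling.
* The crackle magnitude reference is the whole-signal mean absolute
  amplitude by default; a 1 s windowed local reference is available
  (`reference = "windowed"`).
* Recordings rejected by validation are excluded from every metric
  denominator and reported as a count with the processed fraction.
* All randomness descends from explicit integer seeds; pipeline reports
  embed the md5 hash of the configuration that produced them (filesystem
  paths excluded).

## Problem sizes used by the validation suite

The suite validates detector rule fidelity and recall on 204 seeded
recordings (two corpora of 51 at each of 20 and 10 dB), energy conservation
on 100 random signals, and class recovery by 5-fold cross-validation on
30-recording corpora across 20/10/0 dB and five seeds — sizes chosen so the
full suite completes in a few minutes on one core while keeping the recall
and accuracy estimates stable to a few percent.

## Known limitations

* The detector is monophonic and respiratory-phase-agnostic; polyphonic
  wheeze decomposition and inspiratory/expiratory localization are out of
  scope.
* The classifier is single-label three-class; recordings containing both
  crackles and wheezes are assigned whichever class dominates the evidence.
* Synthetic validation bounds what the rules can recover under the
  simulator's assumptions; clinical performance requires real annotated
  recordings, which this package does not ship.
* Kendall's W on nominal labels depends on the chosen ordinal embedding;
  treat it as a descriptive statistic and report the embedding with it.
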