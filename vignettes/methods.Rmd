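---
title: "Forecasting perceptual reversals from EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting perceptual reversals from EEG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When an observer views an ambiguous figure such as the Necker lattice, the
percept alternates between two 3D interpretations without any change in
the stimulus. Several theories hold that a reversal is preceded by a
gradual *destabilization* of the neural representation of the current
percept. If that is true, the EEG recorded *before* a reversal should
already differ from the EEG recorded during perceptual stability — the
reversal would be forecastable.

The paradigm this package models is the discontinuous onset presentation:
lattices are shown for 1000 ms, separated by 400 ms blank intervals, and
the observer reports after each presentation whether the percept reversed
or stayed, relative to the previous presentation (a 1-back task). The
discontinuous mode synchronizes reversals with stimulus onset, giving the
EEG a usable time reference. Two conditions are contrasted:

* **Ambiguity** — the ambiguous lattice; reversals arise endogenously in
  the observer's visual system.
* **Disambiguation** — two disambiguated lattice variants swapped by the
  program with a 30% programmed rate; reversals are exogenous. Because the
  stimulus preceding an exogenous reversal contains no information about
  the upcoming swap, this condition is the control: any pre-reversal EEG
  difference should appear only under ambiguity.

Throughout, a *trial* is a consecutive pair of presentations: the first
stimulus of the pair (epoch time 0–1000 ms), the inter-stimulus interval
(1000–1400 ms), and the second stimulus (1400–2400 ms), in which the
reported percept is established.

# The synthetic cohort

Real recordings for this paradigm are not publicly distributed, so the
package ships a generator (`simulate_participant()`,
`simulate_eeg_recording()`) that produces data with exactly the
statistical structure the analysis assumes, making every downstream stage
testable with known ground truth.

A simulated recording is a sum of:

* **Background activity.** Spatially correlated 1/f ("pink") noise
  (sources mixed through a Gaussian spatial kernel over the montage,
  RMS 5 µV), a posterior 10 Hz oscillation with a slowly varying envelope
  (RMS 3 µV at the occipital peak), and white sensor noise (1.5 µV). The
  pink sources are amplitude-modulated, making them super-Gaussian: real
  cortical band activity waxes and wanes, and amplitude modulation also
  keeps the sources identifiable for ICA (a strictly Gaussian background
  has no unique independent decomposition).
* **Stimulus-evoked components**, identical on every presentation: an
  occipital negativity at 100 ms, a central positivity at 200 ms, and a
  parietal positivity at 380 ms.
* **A reversal-locked component** after onset of the pair's second
  stimulus on reversal trials (parietal, 400 ms peak). In the
  disambiguation condition this component is twice as large
  (`exo_response_gain = 2`): a physical stimulus change evokes a stronger
  response than an endogenous reinterpretation, mirroring the larger
  post-onset effect sizes reported for exogenous reversals.
* **The destabilization signature** — the construct under study. In
  ambiguity reversal trials only, an additive amplitude shift of
  `effect_strength` µV, weighted by a bilateral parietal topography peaked
  at Pz, over 300–1400 ms of the stimulus *preceding* the indicated
  reversal and the following blank interval (raised-cosine ramps at the
  window edges). The waveform of the real pre-reversal effect is unknown
  (only its field power and parietal localization are reported); a
  sustained additive shift is the simplest model consistent with both.
* **Eye blinks** (Poisson, default 12/min, ~150 µV on the vEOG) projected
  onto frontal channels, plus a vEOG channel.

Behavioral responses follow the true percept sequence with a lapse
probability (no press, default 3%), a wrong-key probability (2%), and a
truncated-normal latency (600 ± 120 ms after second-stimulus onset).

Defaults were fixed once, before the verification suite was written, to
values a practitioner would call realistic for this paradigm:
`endo_reversal_prob = 0.28` reproduces the included cohort's mean reversal
rate (~12/min at 42.9 trials/min); `effect_strength = 2` µV puts
single-trial decodability of effect observers in the 70% range,
consistent with reports that even clearly indicative observers stay below
80%; the default cohort (15 observers: 8 with the signature, 7 null)
mirrors the reference study's included sample and its roughly half-half
split between observers with and without detectable pre-reversal
information.

What the generator does **not** emulate: volume-conducted source mixtures
with realistic head geometry, heteroscedastic artifacts (muscle, sweat,
electrode drift), latency jitter of evoked components, learning or
fatigue trends, and any dependence between consecutive percepts beyond
the Bernoulli transition model. Passing tests on this generator therefore
demonstrate that the *pipeline* recovers what it is designed to recover —
not that the destabilization account of real reversals is true.

# Preprocessing

The chain is fixed (`preprocess_participant()`): zero-phase Butterworth
band-pass 0.01–25 Hz (second-order high-pass, fourth-order low-pass,
applied forward–backward so ERP latencies are preserved), re-reference to
the mastoid average (TP9/TP10), ICA blink removal, epoching on the
−400..2400 ms grid with ±100 µV peak-to-peak rejection (strictly greater
rejects; a tie at exactly 100 µV is kept, since the stated threshold has
no boundary semantics), baseline correction over −60..+40 ms around
second-stimulus onset (applied to the whole epoch; one epoch carries the
full pair), and response-validity labeling (latest task-key press between
150 ms after second-stimulus onset and the end of the following interval;
no press, wrong key, or out-of-window presses make the trial invalid).

ICA is a symmetric FastICA (logcosh contrast) on the EEG channels minus
the reference pair, after PCA reduction to the components explaining 99%
of variance; the unmixing is estimated on every 4th sample and applied to
all. Components are removed when the absolute Pearson correlation between
their 1–10 Hz filtered time course and the 1–10 Hz filtered vEOG (Fp1
when no vEOG exists) exceeds 0.8. Two implementation notes:

* Both sides of the correlation are restricted to the blink band. A blink
  component's raw broadband time course correlates with the filtered vEOG
  at only ~0.8 (threshold-marginal); filtered on both sides the blink
  component stands at ~0.98 against ~0.1 for all others.
* The symmetric rotation criterion rarely settles globally on EEG-like
  data, because the spatially smoothed background subspace is close to
  Gaussian; the blink direction itself stabilizes within a few
  iterations. Non-convergence therefore warns (with diagnostics) and the
  decomposition is used; only numerical failure is an error.

The QC report exposes rejection fractions both over all trials and over
validly labeled trials, since a rejection percentage can be defined
either way.

# Global field power and the temporal region of interest

Per participant, condition, and label, epochs are averaged into ERPs and
summarized by global field power — the spatial standard deviation across
electrodes at each time point, in its population (divide-by-n) form. GFP
is reference-free (invariant to common offsets), non-negative, and
integrates over electrodes, which is why the first-pass analysis uses it:
no spatial region of interest needs to be assumed.

The per-participant difference traces (reversal GFP − stable GFP) enter a
pointwise paired two-sided t-test across participants with paired Cohen's
d. No multiple-comparison correction is applied; significant *runs* are
reported with their extent so a reader can judge them (isolated
single-point crossings are expected at the 5% rate by construction).

The decoding window over the first stimulus is chosen from these
statistics: the first time point at or after 150 ms (earlier effects are
not physiologically plausible for percept-level processing) with p <
0.05, rounded *down* to the nearest 100 ms, extended by 400 ms to match
the interval length. If nothing is significant the pipeline falls back to
300–700 ms with a warning.

A subtlety worth knowing: the GFP of an average of n trials has a noise
floor that shrinks with n. With unequal trial counts (reversal trials are
the ~30% minority) the reversal ERP's floor is higher, biasing the
difference trace slightly positive everywhere. In cohorts of *identical*
simulated observers this small shared bias can reach significance in the
paired test even in the control condition; in real data it is buried in
inter-individual variability. The type-I calibration tests therefore use
balanced (reversal probability 0.5) null cohorts, where the bias vanishes
by symmetry.

# Single-trial decoding

Per participant, condition, and window (the data-driven first-stimulus
window, and the 1000–1400 ms interval), trials are split in acquisition
order into four contiguous quarters; each quarter serves once as the
untouched evaluation set while the other three train the classifier
("systematically selected" is read as contiguous temporal quarters, which
preserves the rotation of quarters; a randomized k-fold is available by
passing a custom fold plan). Training trials are shuffled (seeded), the
minority class is oversampled with replacement to balance, and every
trial is min–max normalized to [0, 1] jointly over its channels and
samples (a per-trial gain normalization; "all values in a single trial"
is read as one range per trial, not per channel). Evaluation trials are
only normalized — never resampled or shuffled. Accuracy is the fraction
of matching hard predictions; the participant's score is the median of
the four fold accuracies.

The default classifier is a shrinkage-regularized linear discriminant
(shrinkage 0.1 toward the scaled identity), computed in the span of the
training data so that feature dimension (channels × samples, ~3000) far
above the trial count is handled exactly rather than approximately. This
is the standard linear decoder for ERP classification, runs in well under
a second per fold, and is deterministic. The deep convolutional network
used in the reference analysis is not reproduced (no deep-learning stack
is available to this package, and its training regimen is unreported);
the classifier registry (`register_classifier()`) accepts any
`fit`/`predict` pair, so a heavier model can be plugged in without
touching the protocol. Prediction ties at the decision boundary go to
"stable", the majority class.

## Chance level and class imbalance

With ~30% reversal trials the evaluation sets are imbalanced. If a
classifier's predictions were independent of the truth with
P(predict reversal) = q, expected accuracy is `0.7 − 0.4·q` — 50% only at
q = 0.5. A finite-sample classifier trained on balanced-by-oversampling
data is *not* guaranteed q = 0.5: the minority class contributes fewer
unique trials, its statistics are noisier, and predictions drift toward
the majority. We verified on a provably label-free window (the interval
*preceding* the pair's first stimulus) that this pushes measured "null"
accuracy to ~0.55–0.60 without any label information. This is a property
of the protocol, not a bug, and it affects both conditions equally — the
ambiguity/disambiguation accuracy *ratio* and the KS separability remain
centered. Chance-level calibration, however, is only exact in a balanced
design: with reversal probability 0.5 expected accuracy is exactly 1/2
for *any* classifier whose predictions are independent of the truth. The
calibration tests and the chance-level acceptance computation therefore
use balanced null observers.

# Separability, indicative observers, ablation

Per participant, condition, and window, the pooled per-trial
(prediction, truth) pairs from all four evaluation quarters are
bootstrapped: 1000 draws of 70% of the pairs with replacement (draw size
rounded up), each yielding an accuracy value. The two conditions'
distributions are compared with the two-sample Kolmogorov–Smirnov
statistic (sup-distance of empirical CDFs, in [0, 1]; the asymptotic
p-value is reported but ancillary — bootstrap values are not independent
draws). A participant is *indicative* when KS ≥ 0.8 in either window.
Spearman's rank correlation (with Pearson alongside, since the reference
analysis does not name its ρ) quantifies the coupling of separability
across the two windows.

For the indicative observers the decoding is rerun with each of eight
electrode subsets removed (frontal, central, parietal, occipital, the two
hemispheres by odd/even electrode numbering, and the left and right
parietal halves; memberships are a package default over the 32-channel
extended 10-20 montage and fully configurable through a montage TSV).
The quantity reported per subset is the mean ambiguity/disambiguation
accuracy ratio, with the no-removal baseline. If removing a subset
lowers the ambiguity accuracy more than removing any other, that region
carried the discriminative pre-reversal information.

## A caution on the indicative threshold

The bootstrap distributions' widths reflect only within-dataset
resampling noise, but their *centers* differ by the two conditions'
pooled accuracies, which carry binomial noise of the same order. Under
the null (no signature), the standardized center offset has roughly unit
variance regardless of trial count, so the KS statistic exceeds 0.8 in
roughly 3–8% of null participant–window comparisons — a false-positive
rate that more trials cannot reduce. At cohort scale this matters:
with 7 null observers × 2 windows, the chance that at least one null
observer is flagged indicative is of order one third. The same
arithmetic applies to the reference analysis itself: a set of indicative
participants selected by this rule should be read as enriched for, not
identical to, the observers carrying pre-reversal information. The package's
verification suite asserts exact subgroup recovery on the default seeded
cohort; when a null observer crosses the threshold there, that is this
failure mode surfacing, not a pipeline defect.

# Numerical choices and degenerate inputs

* Epoch boundaries are half-open `[start, end)` at 0-based sample
  indices; the baseline window is closed.
* Rejection is strict (`> 100 µV` rejects); inclusion is non-strict
  (rate ≥ 5/min retained), both following the stated wording.
* A constant trial normalizes to 0.5 everywhere (with a warning); a
  constant GFP difference across participants masks p as undefined; an
  empty ERP cell is flagged missing, never zero-filled.
* All randomness flows from one master seed through
  `derive_seed(master, tags...)` (a 31-bit rolling hash), so any stage or
  participant can be rerun in isolation with identical draws.
* Simulations default to 250 Hz (acquisition-grade 1000 Hz is a
  parameter); the default cohort uses 240 trials per condition — the
  scale of one experimental block — which keeps a full pipeline run at
  desk scale (minutes on one core).

# Known limitations

* The generator's destabilization signature is one admissible model; the
  real effect's waveform is uncharacterized. Recovery results transfer to
  real data only insofar as the effect is a sustained parietal amplitude
  change.
* The indicative-selection rule has the intrinsic false-positive rate
  discussed above.
* The GFP difference of unequal-count averages is slightly positive-biased;
  group heterogeneity masks it in practice, identical simulated cohorts
  do not.
* Linear decoding bounds the recoverable information from below; a
  nonlinear model could raise absolute accuracies, though not change the
  protocol-level properties tested here.
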