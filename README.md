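# revforecast

EEG correlates of perceptual destabilization before endogenous reversals
of an ambiguous Necker lattice, analyzed at the single-trial level — with
a synthetic-data generator that makes the whole pipeline verifiable
without access to raw recordings.

## The problem

Viewing an ambiguous figure, perception alternates between two
interpretations while the stimulus stays constant. If the neural
representation of the current percept *destabilizes gradually* before a
reversal, the EEG preceding a reversal should already differ from the EEG
preceding a stable percept — and an upcoming reversal should be
decodable. In the discontinuous onset paradigm (1000 ms lattice
presentations, 400 ms blanks, a 1-back same/reversed judgment), reversals
synchronize with stimulus onset, so "before the reversal" is a
well-defined epoch: the stimulus S_i preceding the pair's second stimulus
S_i+1 in which the reversed percept is established, plus the blank
between them. A control condition swaps disambiguated lattice variants
exogenously (30% programmed rate): there, S_i carries no information
about the upcoming swap.

## What the package computes

For each (simulated or imported) participant and condition:

1. **Preprocessing** — zero-phase 0.01–25 Hz band-pass, mastoid
   (TP9/TP10) re-reference, ICA blink removal (components whose 1–10 Hz
   time course correlates with the vEOG at |r| > 0.8), epochs on the
   −400..2400 ms pair grid, ±100 µV peak-to-peak rejection, baseline at
   −60..+40 ms around S_i+1 onset, response-validity labeling, and the
   < 5 reversals/min participant-exclusion rule.
2. **Global field power** — the spatial standard deviation over the n
   electrodes at time t,
   GFP(t) = sqrt( Σ_j (v_j(t) − v̄(t))² / n ),
   computed on reversal and stable ERPs; pointwise paired t-tests and
   Cohen's d on the difference traces across participants; a data-driven
   temporal region of interest (first plausible significant time point,
   rounded down to 100 ms, + 400 ms).
3. **Decoding** — per participant: four contiguous-quarter folds (75%
   train / 25% untouched evaluation), minority-class oversampling, [0, 1]
   per-trial normalization, a shrinkage-regularized linear discriminant
   (pluggable via `register_classifier()`), median of the four fold
   accuracies.
4. **Separability** — 1000 bootstrap draws of 70% of the pooled
   (prediction, truth) pairs per condition; two-sample Kolmogorov–Smirnov
   statistic between the ambiguity and disambiguation accuracy
   distributions; participants with KS ≥ 0.8 in the S_i window or the
   interval are *indicative*; ambiguity/disambiguation accuracy ratios;
   Spearman correlation of KS across windows.
5. **Ablation** — the decoding rerun with each of eight electrode subsets
   removed (frontal, central, parietal, occipital, hemispheres, parietal
   halves), ranking scalp regions by their contribution.

The generator (`simulate_participant()`) produces percept sequences,
button presses, and 32-channel EEG with a configurable bilateral-parietal
destabilization signature injected only into ambiguity reversal trials
during S_i and the following blank — the ground truth the pipeline is
asked to recover. BrainVision (.vhdr/.vmrk/.eeg) writer/reader,
behavioral TSV, a montage TSV carrying the subset definitions, and a
binary + JSON-sidecar epoch container round-trip the standard formats.

## Worked example

```r
library(revforecast)

report <- run_pipeline(run_config(seed = 1))   # ~5 min on one core
print(report)
#> <run_report> 15 participants (15 included), master seed 1
#>   ROI: [300, 700] ms (data)
#>   mean median accuracy (ambiguity, ROI window): 70.4%
#>   mean median accuracy (disambiguation, ROI window): 58.1%
#>   indicative: P01, P02, P03, P04, P05, P06, P07, P08, P14
```

The default cohort has 15 observers; P01–P08 carry a 2 µV parietal
destabilization signature in the ambiguity condition, P09–P15 are null.
Reading the output: the region of interest was recovered from the group
GFP statistics at 300–700 ms after S_i onset (the injected effect starts
at 300 ms); ambiguity trials decode well above the disambiguation
control; and the indicative rule recovers the eight effect observers —
plus here one null observer (P14), illustrating the known false-positive
rate of comparing bootstrap accuracy distributions whose centers carry
binomial noise (see the methods vignette). The ablation table in
`report$ablation$summary` shows mean ambiguity accuracy dropping to
~0.58 when the parietal band is removed, against ~0.72–0.80 for every
other subset — the injected signature is parietal, and the pipeline says
so.

Per-stage functions (`simulate_participant()`,
`preprocess_participant()`, `compute_gfp()`, `select_temporal_roi()`,
`train_and_evaluate()`, `bootstrap_accuracy_distribution()`,
`ks_separability()`, `ablate_and_rank()`) expose every intermediate
object; `write_run_report()` persists JSON + TSV tables.

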