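# auscultr

Detection and classification of adventitious breath sounds in chest
auscultation recordings.

Pediatric lung auscultation distinguishes three recording-level classes —
**crackles** (brief discontinuous sounds, associated with pneumonia),
**wheeze** (continuous musical sounds, associated with airway obstruction)
and **normal** breath sounds — but recognition by ear is subjective and
varies strongly with listener experience. `auscultr` is an R toolkit for
the algorithmic side of that problem, aimed at researchers working with
electronic-stethoscope recordings: it implements rule-based event
detection, a wavelet-packet + SVM recording classifier, the multi-rater
consensus procedure used to build gold-standard labels, the full
evaluation-statistics suite, and a seeded synthetic lung-sound simulator
for end-to-end validation against exact ground truth.

## The method

**Event rules.** A *crackle* is a transient shorter than 20 ms whose peak
magnitude exceeds 2× the signal's average magnitude. A *wheeze* lasts at
least 500 ms, found where the peak of a 160 ms window over the 200 ms
Hamming-smoothed envelope exceeds the envelope mean (with a 2× margin).
Crackle candidates are localized on the AR(16) linear-prediction-error
("whitened") envelope with a constant-false-alarm guard — background lung
sound is narrowband and predictable, impulsive crackles are not — and then
qualified by the rules above. All thresholds are ratios, so detection is
amplitude-scale invariant.

**Features and classifier.** A full wavelet-packet tree (db6, depth 4;
exactly orthogonal, energies conserved to machine precision) summarizes
each band-passed recording as 16 subband log-energies plus 16 normalized
Shannon entropies; a one-vs-rest RBF SVM with standardized features and
inverse-frequency class weights maps the vector to crackle/wheeze/normal.

**Consensus.** Each recording is rated by three specialists (who may mark
it *indeterminate*): unanimity accepts, two-or-more indeterminate or full
disagreement rejects, and a 2-vs-1 split goes to an expert group for
adjudication. Exhaustive enumeration of all 64 triples gives 3 accepted /
27 adjudicated / 34 rejected under the default policy.

**Statistics.** Confusion matrices; per-class sensitivity, precision,
specificity and F1 = 2·S·P/(S+P); the adventitious-class mean row; weighted
Cohen's kappa with Fleiss-Cohen-Everitt confidence intervals; Kendall's W
with tie correction; Pearson chi-square.

## Worked example

Simulate a 30-recording corpus (10 per class, event peaks 12 dB above the
background RMS), run the full pipeline — validate, detect, extract
features, cross-validate the classifier, evaluate — and read the report:

```r
library(auscultr)
out <- file.path(tempdir(), "demo")
cfg <- run_config(out_dir = out, n_per_class = 10, snr_db = 12, seed = 42)
rep <- run_pipeline(cfg)
cat("analyzed:", rep$n_analyzed, "of", rep$n_total, "\n")
cat("accuracy:", round_half_up(rep$metrics$accuracy), "%\n")
cat("kappa vs ground truth:", round(rep$kappa$kappa, 3), "\n")
read.csv(file.path(out, "metrics_table.csv"))
```

```
analyzed: 30 of 30
accuracy: 96.7 %
kappa vs ground truth: 0.95
    class sensitivity precision specificity    f1
1 crackle          90       100         100  94.7
2  wheeze         100       100         100 100.0
3    mean          95       100         100  97.4
```

All 30 recordings pass validation; the cross-validated classifier labels 29
of 30 correctly (one crackle recording is called normal, hence crackle
sensitivity 90 %), and agreement with the ground-truth labels is
near-perfect (kappa 0.95). The detector's event table gives each event's
onset, duration and measured peak ratio:

```r
sim <- simulate_recording(sim_spec(n_crackles = 5, snr_db = 20, seed = 7))
detect_events(sim$recording)
```

```
          kind  onset_s duration_s peak_ratio
start  crackle 0.806125   0.002000  12.137276
start1 crackle 1.123250   0.002125   9.590288
start2 crackle 2.318625   0.001750  13.240894
start3 crackle 3.025125   0.001625  12.268207
start4 crackle 3.985625   0.001750  14.283235
```

All five injected crackles are recovered at millisecond onset accuracy,
with the −6 dB event widths (about 2 ms) far below the 20 ms crackle limit
and peak ratios far above the 2× criterion.

A command-line wrapper over the same functions ships in
`inst/scripts/auscultr`:

```sh
Rscript inst/scripts/auscultr pipeline --out-dir demo --n-per-class 10 --seed 42
```

## The methods vignette

`vignettes/breath-sound-pipeline.Rmd` documents the science in detail: the
detector's two-stage design and why a raw 2×-mean threshold cannot work as
a candidate statistic, the simulator's assumptions and what passing
synthetic tests does and does not show, the wavelet and classifier choices,
the consensus rules and their one genuinely ambiguous triple class, and the
package's numerical conventions.
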