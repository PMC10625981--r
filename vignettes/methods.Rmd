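---
title: "Phenotyping CVD hospitalisations from visit notes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping CVD hospitalisations from visit notes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetes outpatient clinics accumulate long streams of free-form visit notes.
Whether a patient was recently hospitalised for cardiovascular disease (CVD)
is often mentioned in those notes but rarely coded in the structured record.
`cvdnotes` implements a pipeline that learns to recover this information: it
links a visit table to a hospital discharge registry to build ground-truth
labels, trains a recurrent text classifier on the notes, and converts its
probabilities into decisions — optionally with a reject option that flags a
calibrated fraction of visits for manual review.

A visit is *positive* under a look-back window of $w$ months when a
qualifying discharge (ICD-9-CM circulatory diagnosis in categories 390–459,
or a revascularisation procedure code) precedes the visit by at most $w$
months. Four windows are studied — infinite, 24, 12 and 6 months — ordered by
increasing difficulty: the narrower the window, the more often a note
mentions an old event that no longer counts, and the fewer positives remain.

## Cohort construction

**Harmonisation.** Visits are kept only inside the observation interval and
inside the patient's healthcare-eligibility period, and patients must have at
least one visit per calendar year in at least three distinct years
(non-consecutive years qualify; the reasoning for this choice sits in the
package's code-level documentation). These filters run before labelling.

**Labelling.** Month arithmetic is calendar-based: the window start is the
visit date shifted back $w$ calendar months, with day-of-month overflow
clamped to month end (31 March minus one month is 28/29 February). Both
endpoints are inclusive; a discharge exactly $w$ months before, or on the
visit date itself, counts as prior. Whether a same-day discharge should count
is genuinely ambiguous in routine data; we include it and state it here as an
assumption. Visits whose look-back window is not fully covered by the
patient's eligibility period ("incomplete windows") are removed for finite
windows — eligibility start is the anchor defining observability.

**Splits.** Patients — never visits — are partitioned 80/10/10 into
train/validation/test with largest-remainder apportionment, so 1000 patients
give exactly 800/100/100. All of a patient's visits share a split, and the
by-patient evaluation reuses the same assignment. The by-patient ground truth
is the OR of the patient's visit labels.

## Text preprocessing

The order is fixed: lowercase → whitespace tokenisation → stop-word removal →
Snowball Italian stemming → rare-type pruning → minimum-length filter.

- The stop-word list is a frozen plain-text file shipped with the package
  (articles, prepositions, pronouns, auxiliary-verb conjugations), so results
  do not depend on an external toolkit version.
- The stemmer implements the Snowball algorithm for Italian (accent
  normalisation, intervocalic i/u marking, R1/R2/RV regions, attached-pronoun
  and standard/verb suffix removal, final-vowel deletion). Note that Snowball
  stemming is not idempotent in general — a vowel-final stem can lose more
  material on a second pass — so the pipeline stems exactly once.
- "Deletion of the 1% least frequent words" is read as *types*, not token
  mass: the `ceiling(0.01 × |V|)` lowest-frequency distinct tokens are
  dropped, ties broken lexicographically. Frequencies are counted after
  stemming, consistent with the pipeline order. Both the fraction and the
  reading are configurable.
- Visits shorter than 3 tokens after cleaning are excluded.
- Sequences are encoded with index 0 reserved for padding and 1 for
  out-of-vocabulary tokens, right-padded/truncated to `max_len`, whose
  default is the 99th percentile of training-sequence lengths. The vocabulary
  is built from the training split only; encoding held-out splits cannot
  modify it (a checksum guards this in the tests).

## The classifier

The network is an embedding layer, a bidirectional LSTM (sigmoid gates, tanh
cell/output), and a cascade of dense ReLU layers, each half the width of its
predecessor, ending in a single sigmoid unit. The implementation is the
package's own, written in C++ (RcppArmadillo) in float32 with
length-bucketed batching, so no padded timestep is ever processed and
prediction is invariant to batch order. Initialisation is Glorot-uniform
with forget-gate bias 1; a fast range-reduced polynomial `exp` replaces the
standard-library call, which otherwise dominates the runtime at these layer
sizes.

Training minimises unweighted binary cross-entropy with Adam. Class
imbalance (~3% positives) is deliberately left unweighted — re-balancing is
available via `pos_weight` but off by default, reflecting that weighting did
not help in this application domain. The learning rate decays per iteration
as `lr0 / (1 + (lr0 / max_epochs) · t)`. Early stopping halts training after
`patience` epochs without a validation-loss improvement of at least
`min_delta = 1e-4` (the minimum improvement that "counts" is not something a
loss curve defines by itself; 1e-4 is our choice) and restores the
best-validation weights.

**Hyperparameter search.** A random draw of `n_search` distinct
configurations from the factorial grid (embedding 32–256, LSTM 16–128, LSTM
dropout 0/0.15/0.3, 2–6 dense layers from width 16–128, dense dropout 0/0.1;
1920 combinations) is scored by mean validation cross-entropy over 5
patient-disjoint folds of the training split. Grouping folds by patient is
an assumption — visit-level folds would leak a patient's phrasing habits
across folds. The winning configuration is re-trained `n_restarts` times from
fresh initialisations and the restart with the best validation loss is kept.
`window_presets()` ships the tuned architectures per window (the 24- and
12-month windows share one; the 6-month window trades dense depth for a
larger embedding).

**Scale.** Two protocols are built in. `full_scale = TRUE` reproduces the
full-scale protocol: learning rate 5·10⁻⁵, 200 epochs, 200 search draws, 100
restarts — appropriate for corpora of tens of thousands of visits. The
desk-scale defaults (learning rate 10⁻³, 60 epochs, 20 draws, 5 restarts,
batch 64) keep the identical protocol *structure* at a budget that runs on
one CPU in minutes. The learning rate must rise at desk scale because the
number of gradient steps shrinks by roughly 40×; with 5·10⁻⁵ and a few
thousand Adam steps the weights simply cannot travel far enough to fit
anything. Inside search folds a reduced screening budget (12 epochs,
patience 4) is used: screening only ranks configurations, and the ranking
stabilises long before convergence. Final restarts always use the full
budget.

## Decision rules

The single-threshold rule classifies positive when $p \ge th$; $th$ is the
F1-maximising cut among all unique validation probabilities (ties resolve to
the lowest threshold, favouring recall). The double-threshold rule abstains
on $th_{low} < p < th_{high}$, decided positive at or above $th_{high}$ and
negative at or below $th_{low}$. For each target uncertainty level
$U \in \{5, 10, 15, 20\}\%$ the pair minimising

$$J_{th} = |F1_{th} - 1| + |U_{th} - U|$$

is selected on the validation set, where $F1_{th}$ is computed on certain
decisions only and $U_{th}$ is the abstained fraction. Candidate pairs are
all ordered pairs of unique validation probabilities when there are at most
`n_candidates` (500,000) of them — making the search exhaustive at
validation sizes in the hundreds — and a seeded uniform subsample of pairs
otherwise; how the candidate budget is spent is our design, stated rather
than inherited. Cost ties resolve to the smaller achieved uncertainty, then
the smaller low threshold, with a 10⁻¹⁰ tolerance so that algebraically
equal costs are not separated by floating-point noise.

## Evaluation

By-visit reports carry AUPRC (computed on the raw probabilities, before any
thresholding) plus precision, recall and F1 after thresholding; uncertain
visits are excluded from the counted population. AUPRC uses step-curve
(average-precision) integration over all unique score thresholds —
trapezoidal interpolation of PR curves is optimistically biased, and with
constant scores the step curve correctly collapses to the prevalence.
Metrics with zero denominators are reported as 0 with a `degenerate` flag
rather than dropped, so report tables stay complete. In the by-patient
setting, thresholded visit decisions aggregate with an OR (any
certain-positive visit makes the patient positive; otherwise any
certain-negative makes it negative); patients whose visits are all uncertain
are excluded and counted. AUPRC is not defined in this setting because
aggregation happens after thresholding.

## The synthetic cohort generator

Real visit/registry linkages of this kind are proprietary, so the package
ships a generator that emulates the statistical structure the analysis
relies on, with every rate explicit in `generator_config()`:

- 2000 patients by default, each with 3–7 visits uniformly placed over their
  eligibility period within a 2011-01-01–2018-09-30 observation window; 90%
  of patients are eligible throughout, 10% over a random sub-interval (these
  exercise the eligibility and incomplete-window filters).
- Discharges arrive as a Poisson process (`hosp_rate` per patient-year);
  a fraction `noncvd_code_rate` (default 15%) carries only non-CVD codes,
  and a quarter of CVD discharges are revascularisation-procedure-only, so
  both arms of the code policy are exercised. The default rate is calibrated
  analytically — prevalence at a complete $w$-month window equals
  $1 - e^{-\lambda_{cvd} w/12}$ — to put ~3% of visits positive under the
  24-month window, the class imbalance this analysis lives in. A 15-seed
  check gives mean observed prevalence 3.004%.
- Notes are assembled from templated pseudo-Italian clinical phrases
  (glycaemia, diet, therapy, examinations) interleaved with function words.
  A note within `mention_horizon_months` (default 24) after a CVD discharge
  contains hospitalisation phrasing ("ricovero per infarto miocardico…")
  with probability `mention_given_recent_hosp`; beyond the horizon the
  mention probability drops to zero, which is what makes narrow windows
  suffer stale-mention false positives. Notes with no recent discharge carry
  CVD vocabulary with probability `spurious_mention_rate`, phrased as risk
  factors or history ("familiarità per cardiopatia…") — lexically
  distinguishable in kind but sharing content words with true mentions.

**What passing tests do and do not show.** The generator provides learnable
lexical signal with controllable noise: positives that never mention the
event (capping recall), spurious mentions (stressing precision), and visit
counts that are small per patient. It does not emulate fluent Italian,
spelling variation, negation, topic drift over years, or clinician-specific
style — so end-to-end results on it validate the *machinery* (labelling,
leakage-free splits, threshold calibration, metric arithmetic) and the
qualitative behaviour of the reject option, not clinical performance on real
notes. Dataset-dependent headline numbers from real data are reproduced only
qualitatively, by direction: degrading the mention probability degrades
single-threshold F1, and allowing 5–20% abstention buys it back.

## Numerical choices and degenerate inputs

- All randomness flows from explicit integer seeds (generation, splits,
  folds, initialisation, dropout, shuffling, candidate subsampling); the
  C++ core uses its own Mersenne Twister so results do not depend on R's
  RNG state, and training is bit-reproducible given the seeds.
- Sequences of length zero (possible after aggressive cleaning) bypass the
  recurrent layer and still produce a valid probability; they are excluded
  from analysis by the 3-token filter upstream.
- Empty discharge-code strings are skipped with a warning rather than an
  error; empty validation classes, empty training sets, and malformed dates
  in CSV inputs raise typed errors naming the offending stage or line.
- Problem sizes in the shipped tests and the acceptance script: cohorts of
  1200–2000 patients (5–10k visits), search over 10 draws × 5 folds,
  3 restarts, 60-epoch cap. One full strong-signal experiment takes on the
  order of ten minutes on one CPU.

## Known limitations

- The stop-word list and stemmer target Italian only.
- The candidate-pair scheme for the double threshold is exact only when the
  number of unique validation probabilities is ≤ 1000 or so; beyond that it
  subsamples (seeded), matching the stated budget rather than enumerating.
- Probabilities are used raw; no Platt/isotonic calibration is applied, so
  saturated classifiers place the single threshold at the extreme of the
  validation distribution, which generalises imperfectly to test data — an
  inherent property of the unique-probability candidate rule.
- `full_scale = TRUE` is provided but takes hours on one CPU; the shipped
  defaults are the desk-scale protocol.
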