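---
title: "HVec: model, training strategy, and synthetic-cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HVec: model, training strategy, and synthetic-cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

Survivors of in-hospital cardiac arrest (IHCA) face high 30-day mortality
and readmission risk. Given a patient's longitudinal claims history — a
dated sequence of coded inpatient/outpatient records — the package predicts,
after every record, whether a mortality event or a readmission will occur
within the next 1–30 days. Four task subsets matter:

* **ALL-mortality / ALL-readmission** — the label attached to every
  (eligible) record;
* **CA-mortality / CA-readmission** — the same labels restricted to records
  carrying an IHCA procedure code (99.60, 99.63). These are the clinically
  interesting tasks and the extremely imbalanced ones: in the regime the
  package targets, roughly 0.5% of CA records are mortality-positive.

## Labeling rules

The mortality event day is the date of the (single) record flagged
"discharged dead or under critical condition". A record is
mortality-positive iff the event falls 1–30 days after it, both ends
inclusive, in integer-day arithmetic. The flagged record itself is always
negative: terminal records carry features (e.g. resuscitation codes) that
trivially reveal the outcome, and a model allowed to use them learns
nothing actionable. This anti-leakage rule is load-bearing; the labeler and
its brute-force oracle in the test suite both enforce it. A configuration
flag (`drop_mortality_records`) removes the flagged records from the
analysis set entirely, for the stricter reading in which such records are
excluded rather than kept as negatives; keeping them as negatives is the
default.

Readmission is measured from hospital discharge (`date + hospital_stay`):
an inpatient record is positive iff a later inpatient admission starts 1–30
days after discharge. Outpatient records have no discharge day, so their
readmission label is `NA` and they are excluded from the readmission loss
and metrics. An admission at or before a discharge (overlapping stays)
never counts and is reported with a warning.

## Features: the 707-dimensional record vector

Each record maps to a fixed-layout vector:

| span | width |
|---|---|
| code-embedding sums (diagnosis, procedure, medication, test, other) | 5 × 128 |
| claim type, age, gender | 2 + 1 + 2 |
| care-site type / specialization / rank (one-hot) | 21 + 5 + 17 |
| hospital stay, per-category costs, per-category counts | 1 + 5 + 5 |
| past hospitalization days and admissions (90/180/365/730-day windows) | 4 + 4 |

for a total of 707. Codes of one category are embedded individually and
**summed** (a multiset sum: a duplicated code counts twice), so the span is
the zero vector when a category is empty.

Code embeddings are deterministic hashed random vectors: each
`(category, code)` pair is hashed to a seed and a unit-variance Gaussian
vector of dimension 128 is drawn from it, so the same vocabulary and seed
reproduce the identical table on any machine. No semantic similarity
between related codes is represented — the information carried is code
identity, which is exactly where the synthetic generator plants its signal.
A pretrained medical-concept embedding could be substituted behind the same
table interface.

Scalar spans (age, stay, costs, counts, history) are z-scored with
statistics fitted on the **training split only**; costs are `log1p`
transformed first because raw claim costs are lognormal and destabilize
recurrent training. One-hot spans are left exact. Applying the scaler never
updates it, so validation/test featurization cannot leak.

## Model

The HVec network processes one person at a time:

1. **Record encoder** — a single affine map + tanh from the 707-dim record
   vector to a 200-dim record embedding, with dropout (rate 0.5) on its
   output in training mode only. Dropout is applied to the encoder output
   and not inside the recurrence; where it acts is unspecified territory,
   and restricting it to the encoder keeps the recurrent dynamics
   deterministic given the embeddings.
2. **Person state** — an LSTM (standard sigmoid/tanh gates, hidden size
   128) consumes the embeddings in date order (ties broken by record id)
   and emits the person vector after every record. Predictions at record
   *t* therefore depend only on records 1..*t*; the test suite asserts this
   causality directly.
3. **Heads** — eight independent affine maps from the person vector: the
   two main-task logits (mortality, readmission), three autoencoder heads
   reconstructing the three natural groupings of the input (code spans,
   640; demographic + care-site context, 48; statistics + history, 19),
   two cost regressions, and an IHCA-record classification logit.

Default sizes (visit embedding 200, recurrent output 128, learning rate
1e-3, dropout 0.5, L2 weight 0.01, code embedding 128) give 401,896
trainable parameters, audited in closed form by the tests.

Head-design choices that were genuinely open: the three autoencoder heads
reconstruct the three input groupings above (the narrative names embedding,
information, and statistics groups without enumerating them); "current
cost" is the log1p of the record's total cost, standardized on the training
split; "future cost" is the same quantity for the person's *next* record, 0
if none — the horizon of the future-cost task is undefined, and next-record
cost is the minimal well-defined choice. Reconstruction targets are the
scaled record vectors, with mean-squared-error loss.

## Multitask training with cosine-gated gradients

Let `G` be the flat main-task gradient over all parameters and `V_i` the
gradient of auxiliary task *i* (reconstructions, costs, IHCA). The update
direction is

```
G + sum_i max(0, cos(G, V_i)) * V_i
```

so an auxiliary gradient contributes in proportion to its agreement with
the main task and is gated out entirely when orthogonal or conflicting; the
cosine with a zero vector is defined as 0. With several auxiliaries each is
gated independently against `G` — the rule is stated for a single auxiliary
field, and independent pairwise gating is its natural extension. Single-task
mode simply passes an empty auxiliary list. The printed form of the update
rule in the source literature is typographically garbled (unbalanced
parentheses, a scalar cosine added to vectors); the implementation uses the
reading above, the only one under which the accompanying convergence claim
makes sense, and matches the adaptive auxiliary-task rule it cites.

The optimizer is Adam at the configured learning rate (the optimizer is
otherwise unspecified; a fixed first-order adaptive method keeps runs
reproducible), with L2 decay 0.01 applied to weight matrices and never to
biases; decay is added to the combined direction so the gate compares pure
task gradients.

## Imbalance strategy

Two mechanisms, both confined to training batches:

* **Person upsampling** — persons carrying a CA-positive record for the
  main task appear `rate` times in the epoch's batch stream (rate 1 = off).
  Validation and test sets are never touched; the tests assert that scored
  validation/test records are unique.
* **CA record weighting** — every per-record loss is weighted `w_pos` on CA
  records and `w_neg = 1` elsewhere, normalized by the total weight
  (`sum(w·L)/sum(w)`). The weighted *mean* (rather than the raw weighted
  sum) keeps the effective learning rate comparable across weight settings.
  The emphasized class is CA-record status, not label positivity: the point
  is to make the objective sensitive to CA records.

Batches are sets of persons (batch size = number of persons), each sequence
processed full-length with the state reset per person. Upsampled duplicates
are treated as independent samples with independent dropout draws. Early
stopping monitors validation AUROC of the main task with patience 5.

## The synthetic cohort generator

Access to the claims database that motivates this model is restricted, so
the package ships a generator reproducing the statistical structure the
method assumes, with a planted, recoverable signal:

* a latent severity `s ~ N(0,1)` per person drives (a) code draws — severe
  persons draw more often from the top 20% "severe" sub-vocabulary of each
  category, (b) CA-record probability (log-odds `+0.5 s`), (c) mortality
  triggers, (d) readmission probability (log-odds `+0.25·severity_effect·s`
  per unit), and (e) costs (lognormal, increasing in severity and code
  count);
* record counts per person are `1 + Geometric` with configurable mean
  (default 9.3); visits are ~30 days apart, 30% inpatient with
  `1 + Poisson(3)` day stays;
* each record triggers a mortality event with a calibrated probability:
  the per-class intercepts are solved (by root-finding against the drawn
  severities) so the mean trigger rate over non-CA records equals
  `base_mortality_rate` (default 0.004) and over CA records equals
  `ca_mortality_target_rate` (default 0.0053) whatever the severity effect
  is. A trigger truncates the sequence and appends a terminal outpatient
  mortality record 1–30 days later. This lands the CA-mortality positive
  rate in the intended ~0.5% regime and the CA-record share near 11% of
  records, matching the cohort the model targets;
* readmissions are generative draws that always materialize: a drawn
  readmission schedules the next inpatient admission 1–30 days after
  discharge, and non-readmission admissions are pushed at least 31 days
  out, so labels are exactly the draws and the configured rate is exact
  when effects are zeroed.

What the generator does **not** emulate: real ICD-9 semantics and
co-occurrence structure, care-site taxonomies, cost scales, multi-morbidity
trajectories, or the ~52% person-level mortality of a real IHCA cohort
(most real CA deaths are 0-day deaths during the index hospitalization,
which the labeling rule marks negative anyway). Passing tests certify that
the pipeline recovers a planted severity signal under extreme imbalance —
not clinical performance on real claims.

## Scaled experiment defaults

The package's reference comparison (single-task vs multitask vs multitask +
upsampling at rate 10) is run at desk scale: 5,000 generated persons
(~46,000 records), a reduced network (visit embedding 64, recurrent output
32, code embedding 32), 16-person batches, 3 epochs, 5 fitting seeds; the
acceptance script runs the same comparison with 3 seeds. Small batches matter more
than epochs here: they give the optimizer enough steps to move off its
initialization. At this scale the comparison checks the *ordering* of
the imbalance techniques in seed-averaged means (single-task ≤ multitask ≤
multitask + upsampling, up to one standard error of the paired seed
differences — with
single-digit positive counts in the CA test subset, individual fits are
noisy and the effect sizes are small relative to that noise); absolute
AUROCs are properties of the synthetic cohort and are not comparable to
values reported on real claims data.

## Numerical and degenerate-input conventions

* AUROC is the Mann–Whitney statistic (ties 1/2) computed from rank sums;
  a single-class subset reports `NA`, never 0.
* F1/precision/recall use threshold 0.5 by default (the reference
  threshold is unstated); `select_threshold()` provides the
  best-validation-F1 alternative, reported separately.
* Same-date records are ordered by record id — a total order is required
  for reproducible recurrence, and the source material sorts by date only.
* Dates are integer day indices; all windows are inclusive integer ranges.
* Weight initialization is uniform Glorot; all randomness (split,
  embeddings, initialization, shuffling, upsampling, dropout) derives from
  the fit seed, making fits bitwise reproducible.

## Limitations

The model ingests claims only — no vital signs or laboratory values; the
embedding table carries no medical semantics; the "other" code category is
opaque; cause of death and competing risks are not modeled; and nothing
here is validated on real NHIRD-like data. Interpretability of the learned
person vectors is out of scope.
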