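---
title: "Predicting functional effects of small molecules: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional effects of small molecules: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ligand-based target prediction usually answers "does this compound bind target
T?" but not "does it *activate* or *inhibit* T?" — yet for mechanism-of-action
work the direction of modulation is what connects a hit to a phenotype.
`moacascade` models that direction. Given per-target sets of activating,
inhibiting, binding-only (direction unknown) and inactive compounds, it trains
and compares three random-forest architectures:

* **Arch1** — a single probability forest over every (target, function) effect,
  trained only on functional actives. Scores are spread across all effects and
  must sum to 1 per compound, so calls are made by a decision threshold
  $\theta$ tuned for F1 on cross-validated scores.
* **Arch2** — a per-target cascade: a *Stage 1* binding gate (active vs
  inactive) followed by a *Stage 2* activator-vs-inhibitor forest whose output
  is Platt-calibrated; its two probabilities are complementary.
* **Arch3** — the same gate, but Stage 2 consists of *two independent*
  calibrated forests (activator-vs-inactive and inhibitor-vs-inactive). Their
  probabilities need not sum to 1; Platt scaling is what makes them
  comparable, and it is the mechanism that protects the minority
  (usually activating) class from being swamped by the majority label.

All three enforce a functional call once a compound passes the gate (no
"binding, direction unknown" output), so the architectures can be compared on
the same three labels: `inactive`, `activating`, `inhibiting`.

## Data assembly rules

The assembly pipeline (`assign_activity_class()`, `remove_conflicts()`,
`sphere_exclusion_sample()`, `apply_minimum_size_filters()`,
`build_target_datasets()`) is rule-exact:

* **Activity threshold.** Functional endpoints (IC50/EC50) and binding
  endpoints (Ki/Kd) at values *better than or equal to* 10 µM are active; the
  boundary is inclusive (10.0 µM is active, 10.01 µM is not).
* **Functional label.** An eight-term BioAssay Ontology vocabulary maps to the
  binary labels: Activation, Agonism, Opening → activator; Antagonism,
  Blocking, Closing, Inhibition, Inverse agonism → inhibitor. When both a BAO
  term and an endpoint unit are present, the term wins; the unit rule
  (EC50 → activator, IC50 → inhibitor) is the fallback.
* **Conflict removal.** Per (compound, target): both activator and inhibitor
  evidence drops the compound from that target's functional sets; active plus
  non-binding evidence drops it from the inactive set. Conflicts never leak
  across targets, and removal never relabels anything.
* **Putative inactives.** Extra inactives are sampled from a background pool
  by sphere exclusion: a candidate is eligible only if its maximum Tanimoto
  similarity to every active of the target is ≤ 0.4. Because the reference set
  is fixed, the accept-loop is equivalent to a static eligibility filter
  followed by a seed-shuffled draw, which is how it is implemented (the pool
  is sorted by compound id before shuffling, so the result is invariant to
  pool row order). The per-target quota defaults to 100× the active-set size —
  a knob, since no canonical value exists.
* **Minimum sizes.** Targets keep their models only with ≥ 10 activating *and*
  ≥ 10 inhibiting compounds; a binding-only set smaller than 5 (the CV fold
  count) is emptied rather than carried.

**Chemistry.** Structures are standardized by a documented pipeline — largest
connected fragment, charge neutralization, canonical SMILES — via OpenBabel
(tautomers are not enumerated). Drug-likeness requires ≥ 1 carbon, molecular
weight in [100, 1000] Da, and no atom with atomic number in
[21, 32] ∪ [36, 52] ∪ (53, ∞); the retained set (H–Ca, As, Se, Br, I) is the
organic-chemistry complement of those ranges, and the rule is a configurable
argument. Fingerprints are 2048-bit circular fingerprints of radius 2
(ECFP4 family), computed natively at 4096 bits and folded by bitwise OR; bit
positions are implementation-defined but deterministic and invariant to SMILES
atom ordering, and every similarity in the package is the Tanimoto coefficient
(defined as 0 for two empty bit sets).

## Model hyper-parameters

| Parameter | Value | Where |
|---|---|---|
| trees | 100 | all forests |
| feature sampling | ⌊√2048⌋ = 45 per split | all forests |
| max depth | 20 (Arch1); unlimited (stages) | `train_arch1()` / stage trainers |
| class weights | balanced (n / 2n_c) | Stage 1 |
| instance weights | × inactive:active ratio for actives | Stage 1 (switchable) |
| calibration folds | 3 (stratified) | Stage 2 |
| gate | p(bind) > 0.5, strict | `cascade_rule()` |

The stage trainers' "auto" depth is read as unlimited, since depth has no
meaningful automatic value; Arch1 keeps its explicit depth of 20. Stage 1
composes balanced class weights *and* ratio-based instance weights as
prescribed; the composition is redundant (the effective weight of an active
instance is n/(2n_act) × n_inact/n_act) and `use_instance_weights = FALSE`
disables the second factor.

**Calibration.** `platt_fit()` fits σ(s) = 1/(1 + exp(As + B)) by
unregularized logistic regression — the exact minimizer of the calibration
log-loss. The common calibrated-classifier recipe fits one classifier and one
sigmoid per fold and averages them; here one forest is trained on all Stage 2
data and a single sigmoid is fitted to pooled out-of-fold scores from an
internal stratified 3-fold split. This keeps the number of folds, yields one
deterministic sigmoid, and requires ≥ 3 members per class (guaranteed after
the ≥ 10 filters, guarded for direct library use).

**Ties and degenerate cases.** Arch1: both labels at or above θ → the larger
wins, an exact tie goes to inhibiting (the majority prior). Cascade:
p(bind) = 0.5 exactly → inactive (strict gate); p_act = p_inh past the gate →
inhibiting. θ can only be set from an `optimize_arch1_threshold()` result,
which searches the 1st–100th percentiles of the pooled *out-of-fold* score
distribution for the best mean F1 over the three labels, breaking ties toward
the larger threshold; a degenerate score distribution collapses to a single
candidate, which is returned.

## Evaluation protocol

* **Cross-validation.** Stratified 5-fold (`stratified_kfold_split()`, built
  on `caret::createFolds` with guards: k ≥ 2 and every class ≥ k). Cascades
  stratify jointly over the four roles; binding-only compounds enter Stage 1
  training folds but are never tested. Arch1 pools out-of-fold scores across
  folds to fit θ; the inactive truth at a target is every tested compound not
  functionally annotated there. One caveat: fold assignment is per
  (compound, target) row, so a compound annotated at several targets could sit
  in a training fold for one and a test fold for another; the synthetic
  benchmarks contain no such promiscuity.
* **Metrics.** One-vs-rest precision/recall/F1 per (target, label). Two
  conventions, logged distinctly: a label present in the truth but never
  predicted scores precision = recall = 0; a label absent from a target's test
  truth is *excluded* from averages rather than zeroed. Aggregates are
  unweighted means over targets ("target-averaged") and over the four protein
  classes ("class-averaged"), each with a dispersion; the conditional variant
  restricts functional labels to Stage-1 true positives, isolating Stage 2
  performance from gate recall losses.
* **Temporal validation.** `temporal_validate()` refuses any train/test
  compound-id overlap and emphasizes class-averaged metrics, since per-target
  temporal test sets can be arbitrarily small.
* **Architecture comparison.** Two-sample Kolmogorov–Smirnov test
  (`ks_compare()`, `stats::ks.test`) on per-target metric distributions, read
  at the 0.05 level.
* **Applicability domain.** Each functional test compound gets the mean
  Tanimoto similarity of its k = 5 nearest training neighbors *of its true
  label at its target*; similarities are binned at width 0.05 (chosen to match
  the protocol's worked "similarity between 0.8 and 0.85" granularity, and
  configurable) and the per-bin true positive rate is the recall of the true
  functional label, with the bin's activating+inhibiting truth count as
  denominator. AD-AUC is the trapezoidal area of TPR over the distance axis
  (1 − similarity) across populated bins; empty bins carry no TPR and are
  excluded. Since the distance axis already spans [0, 1], the area is on the
  normalized scale; the axis orientation and trapezoid convention are
  documented package choices rather than a universally fixed definition.

## The synthetic benchmark generator

Real functional-pharmacology training corpora are proprietary, so
`generate_universe()` draws benchmark universes that reproduce their
*statistical shape*: per-target activator/inhibitor/binder clusters with
controllable nearest-neighbor separations, a configurable
inhibitor:activator imbalance, and a large diffuse inactive background.

The model is deliberately simple: each class at a target is a prototype bit
pattern (64 on-bits of 2048 by default, a typical circular-fingerprint density
for drug-like molecules) and members are independent per-bit corruptions of it
(default flip rate 5 × 10⁻⁴, giving intra-cluster similarity ≈ 0.97). The
expected Tanimoto similarity between members of two prototypes sharing *o*
on-bits has a closed form (ratio of expectations over the four bit
categories), and the generator inverts it by bisection to set prototype
overlaps from the requested knobs. Defaults emulate reported corpus
structure: activator–inhibitor separation 0.835, binder–inhibitor 0.958,
imbalance 5:1, inactive-to-active similarity 0.10. Realized *nearest-neighbor*
medians sit slightly above the calibrated pairwise expectation (the maximum
over many neighbors favors low-noise pairs); the bias is ≈ 0.01–0.03 at
default noise, within the ± 0.05 the generator promises. Counts are exact,
and the whole generator is a pure function of (spec, seed).

`generate_temporal_batch()` emits later-period compounds at controlled
distance from the training clusters (per-compound similarity drawn around a
`novelty` knob and hit by calibrating the flip rate; `novelty = 1` duplicates
training compounds under fresh ids), optionally with a label-flip probability
that grows with distance (`error_gradient`) so applicability-domain behavior
can be tested against a known gradient. An auxiliary fragment-grammar SMILES
generator (`generate_smiles()`) provides real parseable molecules for
end-to-end tests of the standardization path; it makes no medicinal-chemistry
claims.

**What the generator does not emulate — and why it matters.** Prototype +
uniform-flip clusters make every prototype-exclusive bit an almost perfectly
reliable marginal feature: if the activator and inhibitor prototypes differ in
even two or three bits, a forest separates a 25-vs-500 imbalanced pair
essentially perfectly, which real assay data never allows. Consequently the
"overlapping classes" regime used to study minority-class behavior is
instantiated as *coincident* functional prototypes (separation knob equal to
the intra-cluster expectation, i.e. maximal distributional overlap). There the
documented domination failure reproduces: the head-to-head Stage 2 (Arch2)
stops predicting the activating label at all (F1 = 0), while Arch3's
independent Platt-scaled models keep producing activating calls and score a
small positive F1. Passing tests on this generator therefore demonstrate
rule-exactness, calibration behavior and the direction of the imbalance
effect — not absolute performance levels on real chemistry, where
near-duplicate analog series, assay noise and partially informative features
dominate.

## Problem sizes and reproducibility

The shipped tests and the acceptance script size their simulations for a
single CPU: the main benchmark uses 8 targets with 40 activating / 200
inhibiting / 60 binding-only / 400 inactive compounds per target (700
compounds × 2048 bits per target); the imbalance study uses 2 targets at
25:500 over 10 seeds; AD analyses use 80-compound-per-target temporal batches.
Every stochastic step derives its stream from one root seed via a documented
per-component hash (`derive_seed()`), all forests run single-threaded with
fixed seeds, and repeated runs are byte-identical — which the test suite and
the acceptance script both verify.

## Known limitations

* Two functional labels only; partial agonism, allosteric modulation and
  efficacy spectra are out of scope by design.
* Arch1's evaluation treats unannotated (compound, target) pairs as inactive
  truth — standard practice, but wrong wherever annotations are merely
  missing.
* The AD-AUC convention (trapezoid over distance, populated bins only) is one
  of several in use; compare AD-AUC values only within this package.
* Synthetic benchmarks are shape-realistic, not chemistry-realistic (see
  above); conclusions about absolute accuracy require real data.
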