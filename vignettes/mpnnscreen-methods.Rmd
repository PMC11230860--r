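---
title: "Multi-target MPNN screening: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target MPNN screening: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

First-line pharmacotherapy for obsessive–compulsive disorder targets the
serotonin transporter (SERT); refractory cases motivate augmentation through
the dopamine D2 receptor and modulation of the NMDA glutamate receptor. A
ligand-based repurposing strategy asks, for every compound in a drug library:
how likely is it to bind each of these three targets? `mpnnscreen` implements
that strategy end to end: one binding likelihood model per target, an
unweighted ensemble of the three scores, and an external-validation protocol
for the heavily imbalanced libraries virtual screening actually faces.

Because the original training selections (nanomolar BindingDB actives, DUD-E
decoys, DrugBank inhibitor annotations, Drug Repurposing Hub negatives) are
not deposited anywhere, the package ships a synthetic-data module that
generates populations with the same statistical structure and known ground
truth. Every empirical statement in this vignette is one the test suite or
`scripts/acceptance.R` computes; nothing here reports a number obtained any
other way.

## Per-target model

A molecule enters as SMILES and is parsed (OpenBabel via ChemmineR) to its
heavy-atom graph. Featurization produces the four blocks the encoder
consumes:

* **atom features** (26 dims): one-hot element over
  C/N/O/S/F/Cl/Br/I/P/other, one-hot heavy-atom degree 0–5, one-hot formal
  charge clipped to [−2, 2], an aromatic flag, one-hot hybridization class
  (sp/sp²/sp³/other);
* **arc features** (6 dims): one-hot bond order
  (single/double/triple/aromatic), conjugation flag, in-ring flag — each
  chemical bond expanded into two directed arcs;
* **atom neighbor table**: incoming arcs of every atom;
* **arc neighbor table**: arcs feeding each arc's source atom, excluding its
  own reverse.

The hybridization class is derived from bond orders (sp for a triple bond or
two cumulated doubles, sp² for aromatic or one double, sp³ otherwise) rather
than perceived by a chemistry kernel; like the rest of the vocabulary it is a
documented convention, fixed and versioned, and models refuse to score
molecules featurized under a different vocabulary.

The encoder is a directed message-passing network. With arc states
initialised from the source atom's features concatenated with the arc
features, `h⁰ = relu([x_src, e] Wᵢ)`, each of the remaining `depth − 1` steps
aggregates incoming arc states (excluding the reverse arc, so information
does not immediately bounce back) and applies a skip-connected update
`hᵗ = relu(h⁰ + (Σ h_in) W_h)`. Atom states read in their incoming arcs,
`h_v = relu([x_v, Σ h_in] W_o)`, and mean pooling over atoms gives the
molecule embedding. A feed-forward head with hidden widths 1024/1024/512 and
ReLU activations, ending in a sigmoid unit, maps the embedding to a score in
[0, 1]. Defaults: depth 3, message dimension 64 — conventional MPNN settings,
configurable via `model_config()`.

Training minimises minibatch MSE between the sigmoid output and the 0/1
labels — a regression-style objective paired with a bounded output — for
exactly `epochs` epochs at learning rate 0.001 and batch size 128. The
optimiser is Adam (the de-facto default of the deep-learning toolkits this
design follows); weights use Glorot-style initialisation, biases start at
zero. Gradients are analytic (verified against numerical differentiation in
the test suite to ~1e−6 relative error) and the whole computation is base
matrix algebra plus sparse aggregation operators, so training is exactly
reproducible: fixed (data, config, seed) gives bit-identical parameters.

The 70/10/20 train/validation/test split floors each share and assigns the
remainder to the training split (400 molecules → 280/40/80; 302 → 212/30/60),
stratified by label by default because the datasets are small and balanced.
The validation split selects the epoch whose parameters are kept (lowest
validation MSE); `select = "last"` disables this. A stratified split that
would leave a non-empty part without one of the classes is refused rather
than silently degraded.

## Ensemble and thresholding

The ensemble score is the exact unweighted mean
`(Score(SERT) + Score(D2) + Score(NMDA)) / 3`; weighted variants are
deliberately out of scope. Classification is boundary-inclusive
(`score ≥ threshold` is positive) — the convention matters when sweeping
thresholds up to 1.0 and is therefore stated wherever predictions are
reported. `screen_library()` ranks descending by ensemble score with ties
broken by molecule id, so rankings are stable and reproducible.

## External validation under imbalance

With ~37 times more negatives than positives, headline metrics at a fixed
threshold are dominated by the negatives. The protocol therefore keeps all
positives and, in each of `n_reps = 1000` repetitions, draws as many
negatives (without replacement, independently across repetitions) as there
are positives, evaluates the balanced set at each threshold in
{0.5, 0.6, 0.7, 0.8, 0.9, 0.95}, and averages over repetitions.

Averaging admits two orders and the distinction is visible at the third
decimal: the *average of per-repetition metrics* and the *metrics of the
averaged confusion counts*. `balanced_resampling_validation()` reports both
(`mean_of_metrics`, `metrics_of_mean_counts`); the tabular export defaults to
the counts-derived form because averaged counts are what such reports print,
and the two differ only through the nonlinearity of ratios. Per-repetition
metrics with zero denominators are excluded from the average and counted
(`n_excluded`) — coercing them to 0 would bias the mean. The report also
carries the running average of the sampled false-positive count per
threshold, which converges by the law of large numbers to the
hypergeometric expectation `n_sample × (pool FP rate)`; the acceptance suite
checks agreement within three standard errors.

Structural invariants hold by construction and are asserted in tests: TP + FN
equals the positive-set size in every threshold row, TN + FP equals the
per-repetition sample size, and TP is anti-monotone in the threshold.

Metric conventions: AUROC is the Mann–Whitney pairwise-concordance
probability with half-credit ties (tested against a brute-force oracle on
1000 random instances); AUPRC is the step-wise, non-interpolated summation
(mean precision at the positives' ranks, descending-score order, ties broken
by original position) whose random-classifier baseline is the positive
prevalence. Interpolated AUPRC variants give different numbers; the
convention here is fixed and documented.

## The synthetic study populations

`synthetic_spec()` defaults mirror the real study's design: SERT and D2 train
on 200 actives vs. 200 decoys, NMDA on 152 vs. 150, and the external screen
holds 154 positives against 5744 negatives. Actives embed a target-specific
substructure motif — indole (SERT), pyridine (D2), thiophene (NMDA), three
distinct ring systems so the three models learn three different functions —
decorated with random alkyl/oxy fragments; decoys are built from
carbon/oxygen-only scaffolds, so motif-freedom holds by construction (every
motif contains N or S) and is re-verified in tests by exhaustive SMARTS
matching. Ki values are sampled log-uniformly (affinity data is log-scaled in
practice) inside (0.1, 10] nM for actives and [10³, 10⁵] nM for decoys, so
the entire active set survives the nanomolar activity filter and actives are
strictly more potent than decoys. Screen positives may carry several motifs
with frequencies weighted 109/65/18 (≈1.25 motifs per positive), emulating a
population of annotated inhibitors in which some drugs hit multiple targets;
screen negatives are motif-free. The generator guarantees, and
`assert_disjoint()` re-checks, that no library molecule coincides by
canonical SMILES with any training molecule.

What the synthetic data does *not* emulate: property-matched decoys (DUD-E
matches physicochemical profiles; motif-free scaffolds are an easier
negative), chemotype diversity of real actives (a shared motif is a stronger,
cleaner signal than a real structure–activity landscape), assay noise in Ki,
and 3-D/stereochemical effects. Passing the packaged benchmark therefore
demonstrates that the pipeline learns and ranks a constructed recoverable
signal correctly — not that it would reach the same metrics on BindingDB
selections, which are undeposited and out of scope.

One consequence worth stating: because most synthetic screen positives carry
a single motif, a molecule scored ~1 by one model and ~0 by the other two
lands near ensemble 0.33, below the 0.5 threshold. The synthetic screen
therefore shows strong *rank* enrichment of positives (which the acceptance
suite asserts) alongside low threshold-0.5 sensitivity. In the real study
the three pharmacological profiles are correlated across psychoactive
drugs, which is precisely why its ensemble could score known inhibitors
close to 1 on several targets at once.

## Problem sizes and runtimes

The packaged benchmark trains the three study-sized models for 30 epochs
(the constructed signal saturates well before that; the real study's regime
of 100 epochs remains the `model_config()` default) and screens the
5898-molecule library once; unit tests run on 0.08–0.15-scale populations
and a 16-dimensional encoder. These sizes are the package's own benchmark
choices and are stated here so that reported quantities are interpreted at
the scale that produced them.

## Known limitations

* The featurization vocabularies and the encoder's depth/width are fixed
  conventions, not fitted to any external reference implementation.
* Canonicalization is OpenBabel's; no salt stripping or tautomer
  normalization is attempted, so two salt forms of one molecule count as
  distinct.
* No hyperparameter search, no GPU path, no alternative encoders
  (SMILES-CNN, Morgan fingerprints) — single-CPU training of a ~400-molecule
  dataset takes well under a minute, which is the intended operating point.
* The resampling report quantifies sampling variability only through the
  convergence trace; it deliberately reports point averages, not confidence
  intervals.
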