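---
title: "Signal-feature engineering and leakage-safe evaluation for protein-DNA hot-spot prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-feature engineering and leakage-safe evaluation for protein-DNA hot-spot prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdhotspot)
```

## The problem

Alanine scanning at a protein-DNA binding interface assigns each mutated
residue a change in binding free energy, ddG (kcal/mol). Residues with
ddG >= 1.0 kcal/mol are *hot spots*: the small set of interface residues
carrying most of the binding energy. Experimental scanning is expensive, so
hot spots are predicted from structure-derived descriptors of the wild-type
complex. `pdhotspot` implements such a predictor as a pipeline of five
stages — signal-feature extraction, class rebalancing, two-step feature
selection, gradient-boosted classification, and repeated cross-validated
evaluation — together with a synthetic residue-table generator so that every
stage is testable end to end without structural software.

The package consumes *precomputed* per-residue descriptor tables. Computing
accessibility, secondary structure, depth/protrusion or hydrogen bonds from
coordinates requires external (partly license-restricted) tools and is out
of scope; the expected columns are documented in
`conventional_feature_names()`.

## Input data model

One row per mutation site, grouped by complex:

* 24 solvent-accessibility values: absolute and relative area over four atom
  classes, in the bound complex (`ASA_*`, 8 values), the unbound monomer
  (`uASA_*`, 8) and their difference (`dASA_*`, 8);
* 6 secondary-structure descriptors (`SS_*`);
* 12 depth-index / protrusion-index summaries (`DPX_*`, `CX_*`): per index,
  all-atom mean and side-chain standard deviation in both states plus their
  changes;
* 1 hydrogen-bond count;
* a ddG value and/or a binary label (`label_from_ddg()` applies the
  inclusive 1.0 kcal/mol rule when only ddG is present).

That is 43 *conventional* features. The exact composition of the 8
accessibility values per state is fixed by the shipped schema registry
(`inst/extdata/schema_default.json`) — four atom classes crossed with
absolute/relative area — because published descriptions of such feature
sets name the counts but not the ordering; the registry makes the order a
package contract rather than a convention in someone's head.

## Signal features

The pipeline's distinctive step treats four short descriptor blocks — the
three accessibility states and the secondary-structure block — as digital
signals and summarizes their multi-scale structure.

### Wavelet block (132 features)

Each signal is decomposed with the Haar (db1) wavelet, both as a plain DWT
cascade and as a full level-3 wavelet packet tree (8 leaves, natural order;
inputs are zero-padded to a multiple of 8). Per signal, 33 summaries:
approximation-band energies at levels 1-3 with their mean and standard
deviation, the level-3 detail energy, five coefficient entropies (Shannon,
SURE, threshold, 1.5-norm, log-energy) on the concatenated DWT
coefficients, the total leaf energy, 8 absolute leaf energies, the same five
entropies on the concatenated packet leaves, and 8 relative leaf energies.
Four signals x 33 = 132.

Numerical conventions, chosen once and fixed: entropies follow the classical
MATLAB-style `wentropy` family definitions on unnormalized coefficients; the
SURE/threshold parameter defaults to 0.2 (`wavelet_config()`); relative leaf
energies of an all-zero signal are defined as 0 rather than NaN; leaves are
reported in natural (filter-bank) order. Haar orthonormality gives a strong
internal invariant — leaf energies must sum to the input energy — which the
test suite checks to 1e-10 relative on a thousand random signals, alongside
a cross-check of the leaf coefficients against an independent wavelet
library.

### EMD block (43 features)

Empirical mode decomposition splits each signal into intrinsic mode
functions (IMFs): components whose interior-extremum and zero-crossing
counts differ by at most one and whose upper/lower spline-envelope mean is
near zero. Sifting iterates "subtract the envelope mean" until a
Cauchy-type criterion (relative change below 0.2) and the count condition
hold, with a 10-iteration soft cap; decomposition stops when the residual is
monotone or has fewer than 2 interior extrema. Because the signals here are
very short (6-8 samples), boundary policy is decisive: the implementation
mirrors the two extrema nearest each end about the endpoints before fitting
cubic splines. Each kept IMF contributes four statistics: mean, variance
(N-1 denominator), energy, and the lag-1 autocorrelation value
`sum(x[i] x[i+1])` over the overlapping range.

The block layout keeps all four statistics of IMFs 1-3 for the three
accessibility signals (36 values) and, for the shorter secondary-structure
signal, IMF 1 fully plus the mean/variance/energy of IMF 2 (7 values), for
43 in total. Short signals often exhaust before three IMFs exist; absent
IMFs fill their slots with zeros, keeping rows fixed-width. The layout is
data-driven (`emd_slot_table()`), not hard-coded, since a 4 x 3 x 4 grid
would give 48 slots and any 43-slot convention is necessarily a choice; this
one privileges the longer, more decomposable accessibility signals.

Two invariants guard the implementation: exact reconstruction (IMFs plus
residual reproduce the input to 1e-9 relative) and the count condition on
every returned IMF; both are enforced on a thousand random signals. A
from-scratch Python/scipy reference implementation, shipped under
`inst/oracle/`, provides an independent cross-check (IMF counts and
first-IMF correlation).

## Rebalancing: SMOTE + Tomek links

Hot spots are the minority (roughly 102:179 in a typical training split).
`smote()` synthesizes minority rows by interpolating a minority sample
toward one of its 5 nearest minority neighbors, `x + (xn - x) * u`,
`u ~ U(0,1)`, until the classes are 1:1; neighbors are found on z-scored
features, interpolation happens in the original space. A `sign = "reflect"`
variant (`x + (x - xn) * u`) is provided because the reflected form also
appears in the literature; interpolation is the default since it is the
behavior the rest of the standard SMOTE description implies.
`tomek_links()` then finds opposite-class mutual nearest neighbors in the
expanded data and `smote_tomek()` removes the majority member of each link,
sharpening the class boundary. Both the post-SMOTE and post-cleaning class
counts are reported, since cleaning reduces the majority side below exact
parity. ADASYN and random oversampling are included as comparator
contracts. Balancing is always fitted on training rows only.

## Two-step feature selection

`mrmr_rank()` ranks features by greedy maximum-relevance
minimum-redundancy in the MID (difference) form — the first pick maximizes
mutual information with the label, each next pick maximizes relevance minus
mean redundancy against the picks so far — using a plug-in MI estimate on
3-bin quantile-discretized columns. Ties break by column order, making the
ranking fully deterministic. `sfs()` then walks the ranked candidates,
appending a feature whenever it improves a 10-fold cross-validated AUC and
stopping after 5 consecutive non-improvements. The CV evaluator defaults to
a fast logistic backend so the wrapper search stays tractable; the composed
`mrmr_sfs()` is the pipeline default. The optimal subset size is data
dependent (around 11 on the kind of curated data this pipeline targets);
the package imposes no fixed size. Random-forest importance and linear
SVM-RFE rankings are available as comparators.

Discretization, MI estimator and the SFS objective are all unavoidably
open choices; the package fixes quantile bins (robust to monotone
transforms), the plug-in estimator (exactly testable against a contingency
table) and AUC (threshold-free, the pipeline's headline metric),
configurable where that matters.

## Classifier and evaluation

The reference classifier is a gradient-boosted decision tree with 150
rounds, learning rate 0.03, depth 6 and seed 42 (`model_config()`),
delegated to \pkg{xgboost}; logistic regression, an RBF SVM and a random
forest sit behind the same `train()` / `predict_scores()` contract for
configuration sweeps. Evaluation reports TP/FP/TN/FN at threshold 0.5 and
the seven standard metrics (SEN, SPE, PRE, F1, ACC, MCC, AUC); any metric
with a zero denominator is defined as 0, matching common tooling. AUC is
the Mann-Whitney statistic with midranks for ties, checked against a
brute-force pair count.

`repeated_cv()` runs repeated stratified k-fold cross-validation (the
reference protocol is 50 x 10-fold) with balancing and selection fitted
*inside* each training fold. This is the pipeline's critical hygiene
property: with permuted labels the cross-validated AUC must center at 0.5
even with balancing and selection enabled, and the acceptance suite checks
exactly that. Dataset splitting is always at the complex level
(`split_by_complex()`), never by row, so homologous mutation sites cannot
straddle the train/test boundary.

## Synthetic data

`generate_records()` emulates the statistical shape of a curated dataset:
117 complexes, 2-5 sites each, hot fraction 131/339; ddG from a
two-component model (hot: N(2.0, 0.8) truncated to >= 1, non-hot:
N(0.2, 0.4) truncated below 1 — invented values chosen to straddle the
threshold realistically, since no ddG distribution is published for such
curated sets); descriptor signals are low-order sinusoids plus unit
Gaussian noise, so EMD typically finds 1-3 IMFs and the zero-fill rules are
exercised; five conventional slots (one per descriptor block) carry a
1-SD class shift by default. What the generator does *not* emulate:
correlations between descriptor families, heavy-tailed accessibility
distributions, homology structure within complexes, or any physical
coupling between ddG magnitude and the descriptors beyond the planted
shifts. Passing tests therefore demonstrate pipeline correctness and
calibration, not real-data accuracy.

`generate_matrix_table()` provides plainer benchmark tables (independent
normal features, a planted informative subset) for selection-recovery and
permutation-null experiments.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest sizes —
up to 160 synthetic complexes, selection recovery at n = 300 with 50
features over 10 seeds, permutation nulls at n = 500 with 5 x 10-fold CV —
sizes at which every experiment completes in minutes on a single core while
leaving the measured quantities stable. Every stochastic step takes an
explicit seed; the pipeline fans a single master seed out to per-stage
seeds via a string hash, so stages are independently reproducible, and
identical configurations produce byte-identical artifacts.

## Known limitations

* The EMD boundary policy and the 43-slot layout are fixed conventions;
  other defensible conventions exist and would change feature values.
* The plug-in MI estimator is biased upward on small samples; with 3 bins
  and the sample sizes used here the bias is shared across features and
  barely affects ranking.
* SVM probability calibration (comparator backend) uses internal
  cross-validation; determinism is ensured by seeding, but probabilities
  differ across platforms more than tree-based backends do.
* On tables with constant columns, discretization collapses to a single bin
  and the feature becomes unrankable (MI 0) — intended, but worth knowing.
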