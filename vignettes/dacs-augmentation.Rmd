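---
title: "Augmenting drug-synergy data by DACS-guided compound substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting drug-synergy data by DACS-guided compound substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A synergy screen yields records (drug A, drug B, cell line, synergy
score): positive scores mean the combination inhibits growth beyond the
single-agent expectation, negative scores mean interference. The working
hypothesis behind substitution-based augmentation is that two drugs with
(i) similar chemistry, (ii) overlapping protein targets and (iii)
concordant monotherapy potency profiles are pharmacologically
interchangeable inside a combination, so replacing one partner with such a
neighbour yields a new, plausibly correctly-labeled instance.

`dacsaug` quantifies (i) with the Tanimoto coefficient over path
fingerprints, (ii) with the Matthews correlation of target-set membership
over a fixed protein universe, and (iii) with Kendall τ_b over shared
pIC50 profiles. Chemistry and mechanism combine into

$$\mathrm{DACS} = \sqrt{TC^2 + \max(\mathrm{MCC}, 0)^2} \in [0, \sqrt 2],$$

with negative MCC clamped so an anti-correlated target pattern never
erodes a chemical match; τ_b is reserved as the independent yardstick
used to pick the cutoff. Substitution then replaces exactly one slot of a
record with a candidate whose DACS to the replaced drug reaches the
cutoff, copying the synergy score (and therefore the class) from the
parent.

## Tunable parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| fingerprint length | 1024 bits | — | path-fingerprint convention |
| τ_b minimum overlap | 2 cell lines | count | below it τ_b is defined as 0 (no evidence ≠ evidence of similarity) |
| DACS cutoff | selected from curves | [0, √2] | fidelity/coverage trade-off; the curves on real-scale data cross near the low 0.5s |
| label thresholds | +20 / −20 | synergy score | reliable classes; the (−20, 20) band is excluded as ambiguous |
| ladder | 0, 5, 10, 15, 20 | synergy score | probes classifier confidence as ambiguity grows; t = 0 uses strict inequalities |
| unseen TC bound | 0.4 | Tanimoto | external compounds with TC ≥ 0.4 to any training compound are not "unseen" |
| folds | 5 | — | both protocols |
| class-ratio tolerance | 0.005 | fraction | augmented training pools mirror the fold's class balance; the check floors at the sampling granularity 1/n |
| embedding dimension | 300 per block | — | 2 drug blocks + 1 cell block = 900-d instances; tests run 16-d blocks for speed |

Classifier defaults are deliberately fixed (LR: L2, C = 0.45, tol 1e-4,
500 iterations; SVM: linear, C = 0.42, tol 1e-3, calibrated
probabilities; RF: 300 trees, ≥ 85 samples per leaf, √p features; GBT:
650 stages, ≥ 120 samples per leaf, √p features, learning rate 0.28,
depth 5; all with balanced class weights). These are scikit-learn
semantics, and fitting is delegated to scikit-learn through a subprocess
bridge — the pre-installed R stack has no SVM or tree-ensemble
implementation, and re-expressing these exact hyperparameters in a
different library would silently change the model family. Any override is
recorded in the spec and echoed in every report (parameter audit).

## Threshold selection

`build_threshold_curves()` tabulates, over an ascending DACS grid
(default 0–1.41 by 0.01), the *fidelity* — the fraction of drug pairs at
or above the threshold whose τ_b is strictly positive — and the
*coverage* — the number of candidate substitutes still available, divided
by its grid maximum so both curves live on [0, 1]. The inclusive `≥` at
the boundary is a documented choice so grid endpoints behave predictably.
`select_dacs_threshold()` returns the crossing abscissa, linearly
interpolated between adjacent grid points, and *validates* that fidelity
is non-decreasing and normalized coverage non-increasing: raw empirical
fidelity on noisy data jitters, and the selector refuses such input
rather than silently picking one of several crossings. `smooth = TRUE`
(isotonic regression on fidelity) is provided as an explicit opt-in for
empirical curves.

## What the generator emulates — and what it does not

`simulate_world()` plants substitutability clusters: cluster mates share
a template fingerprint (each template bit relocated with probability
1 − `within_cluster_bit_overlap`), a template target set (swaps at
1 − `within_cluster_target_overlap`), and a latent per-cell-line potency
profile disturbed by Gaussian pIC50 noise (`response_noise_sd`, default
0.3 against unit profile spread). Synergy classes are assigned at the
*cluster-pair* level — every pair drawn from clusters (i, j) shares a
class — with scores ±`synergy_effect` (30) plus Gaussian noise (8), a
class balance of 0.767 synergistic (the balance of the reference
real-world dataset), and cell lines spread round-robin over five tissues
so every tissue fold contains both classes. Cluster-pair-level class
assignment is what makes label transfer *valid by construction*; it is
the generative form of the protocol's premise, not evidence for it.

Consequently a green pipeline test establishes that the machinery —
similarity scoring, retrieval, label transfer, fold hygiene, training —
extracts planted signal correctly. It does **not** establish that real
drugs satisfy the premise, that real synergy noise is Gaussian, or that
real fidelity/coverage curves cross where the synthetic ones do. Real
data also carry replicate measurements, missing monotherapy profiles and
batch structure that the generator does not model.

## Numerical choices and degenerate inputs

- τ_b returns 0 when fewer than two cell lines are shared or when either
  profile is constant (denominator 0); pairs tied in *both* lists are
  excluded from the tie terms n₁ and n₂.
- MCC returns 0 whenever a denominator factor vanishes (empty target
  set); the quotient is clamped to [−1, 1] against floating-point drift.
- Tanimoto of two all-zero fingerprints is 0 by contract.
- Metric ratios with zero denominators (e.g. PPV with no positive calls)
  are reported `NA`, never 0, and excluded from fold averaging with a
  recorded count.
- Augmentation dedupes on (canonical pair, cell line); colliding records
  keep the copy with the highest DACS to its substitute, ties broken by
  lexicographic parent order. Augmented keys equal to an original record
  are dropped.
- Capped subsampling apportions per class by largest remainder, so the
  class fraction deviates from the pool by at most the granularity 1/cap.
- The decision threshold is 0.5 with `≥` mapping to the positive
  (synergistic) class; mean ROC curves average TPR vertically over a
  fixed FPR grid; per-fold seeds are `seed + fold`.

## Design decisions taken where the design was open

- **Fingerprint backend.** No cheminformatics toolkit is assumed at the R
  level; the default backend parses SMILES and hashes linear atom paths
  (up to 7 atoms) into 1024 bits. Path fingerprints from different
  toolkits are not bit-identical, so the producing backend is recorded on
  every library and mixed-backend comparisons fail on the length check.
  Physicochemical descriptors (logP, HBD, HBA, QED) come from RDKit via a
  subprocess and the backend version is stamped into every summary.
- **Pair canonicalization.** Synergy is symmetric; records and feature
  vectors use the lexicographically ordered pair, making featurization
  invariant to input orientation.
- **Substitute eligibility.** Only identity with either parent-pair
  member is forbidden; a substitute may already occur elsewhere in the
  dataset. One slot is replaced per augmented instance, never both.
- **Fold inheritance.** An augmented instance belongs to its parent's
  fold; with training-only use this is the only reading that prevents
  parent-derived leakage into validation.
- **Replicates.** Identical (pair, cell line) records with different
  scores are kept as separate instances by the readers; the generator
  dedupes its own draws.
- **Target-link cutoff.** The chemical–protein link score cutoff is a
  configuration value (default: keep all links); which confidence channel
  defines a "target" is dataset policy, not package policy.
- **Config files.** The CLI reads JSON configuration (jsonlite) rather
  than YAML, keeping the runtime dependency set to packages the
  deployment image declares.
- **Acceptance scale.** The pipeline-level acceptance test runs 10 seeds
  of a 600-record world with 16-d embedding blocks and a 2000-record
  augmented cap; these sizes were fixed from the runtime budget before
  measuring the criterion and are not tuned to outcomes.

## Known limitations

- The SMILES parser covers the organic subset, brackets, branches, rings
  and aromatic forms but ignores stereochemistry, charge and explicit
  hydrogens; it is a fingerprint substrate, not a validator.
- SVM probabilities come from internal Platt calibration and are not
  unique; reports carry a note to that effect.
- The hashed fallback embedders preserve fingerprint similarity in
  expectation but are no substitute for learned chemical or expression
  embeddings; real analyses should load pretrained vectors via
  `load_embedding_csv()`.
- `fraction_positive_tau()` treats τ_b = 0 as "not positive", which is
  conservative for drugs with sparse monotherapy coverage.
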