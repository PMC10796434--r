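# dacsaug

Data augmentation for anti-cancer **drug-synergy prediction** by compound
substitution, guided by the **drug action/chemical similarity (DACS)
score**.

## The problem

Supervised models that predict whether a drug pair acts synergistically or
antagonistically on a cancer cell line are starved for labeled data:
experimental synergy screens cover thousands, not millions, of
(drug, drug, cell line) instances. `dacsaug` implements a protocol that
expands a synergy dataset by replacing one compound of a measured
combination with another molecule whose pharmacology is expected to be
equivalent, transferring the parent's class label to the new instance. It
is aimed at computational pharmacologists building synergy classifiers and
at methodologists who want a testbed for substitution-based tabular
augmentation.

## The score at the core

Drug equivalence is judged by three pairwise measures:

- **Tanimoto coefficient** over path fingerprints,
  `TC = |A ∩ B| / |A ∪ B|` on set bits (chemistry);
- **target MCC**, the Matthews correlation of the two drugs' protein-target
  memberships over a fixed interactome universe of `T + N + A + B`
  proteins,
  `MCC = (T·N − A·B) / √((T+A)(T+B)(N+A)(N+B))`
  (mechanism of action);
- **Kendall τ_b** between monotherapy pIC50 profiles over shared cell
  lines, with the tie-corrected denominator
  `τ_b = (n_c − n_d) / √((n_c+n_d+n_1)(n_c+n_d+n_2))`
  and τ_b ≡ 0 when fewer than two cell lines are shared (pharmacology).

The first two combine into the substitution criterion

```
DACS = √(TC² + max(MCC, 0)²)   ∈ [0, √2]
```

and τ_b is the *validation* axis: the augmentation cutoff is chosen where
the fraction of drug pairs with τ_b > 0 above the threshold (fidelity)
crosses the max-normalized count of available substitutes (coverage).

Downstream, labeled instances (synergistic at score ≥ 20, antagonistic at
≤ −20, the ambiguous middle excluded) are featurized as
`[drug_a | drug_b | cell]` embedding blocks and evaluated with logistic
regression, linear SVM, random forest and gradient boosting under two
5-fold protocols: random-stratified and tissue-held-out (no tissue ever
appears in both training and validation). Augmented instances are used
for **training only** and never descend from a validation-fold parent.

## Worked example

The package ships a planted-cluster generator, so the whole pipeline runs
without any external data:

```r
library(dacsaug)
sim   <- simulate_world(sim_config(seed = 1))
pairs <- drug_pair_similarity(sim$library, sim$target_map, sim$responses)

# planted structure: cluster mates are highly similar, others are not
fraction_positive_tau(pairs, 0.6)       # 1.000 at DACS >= 0.6

aug <- augment_dataset(sim$synergy, sim$library, sim$target_map,
                       cutoff = 0.5, max_records = 2000, seed = 1)
lab <- build_labeled_dataset(sim$synergy)       # 522 labeled originals
dp  <- hashed_drug_embedder(sim$library, dimension = 16, seed = 1)
cp  <- hashed_cell_embedder(dimension = 16, seed = 1)
X   <- featurize_dataset(lab, dp, cp)
auglab <- build_labeled_dataset(aug, origin = "augmented")
Xa  <- featurize_dataset(auglab, dp, cp)
asg <- assign_folds(lab, "random_stratified", seed = 1)

crossval(lab, X, asg, model_spec("RF", seed = 1))
#> <metrics_report RF | random_stratified | original>
#>   mean over 5 fold(s): ACC 0.761 TPR 0.725 FPR 0.136 PPV 0.939
#>   AUC 0.858 MCC 0.521 F1 0.818
crossval(lab, X, asg, model_spec("RF", seed = 1), augmented = auglab,
         augmented_features = Xa, use_augmented = TRUE)
#> <metrics_report RF | random_stratified | augmented>
#>   mean over 5 fold(s): ACC 0.858 TPR 0.818 FPR 0.023 PPV 0.990
#>   AUC 0.957 MCC 0.716 F1 0.894
```

The report means are averaged over the five validation folds, which always
contain only original instances; here augmentation lifts the random forest
AUC from 0.858 to 0.957 because the extra same-cluster substitutions let
the (deliberately conservative, min-85-samples-per-leaf) trees actually
split.

A command-line wrapper covers the same steps
(`inst/cli/dacs-augment <similarity|select-threshold|augment|build-dataset|crossval|simulate>`),
reading and writing the plain CSV/TSV formats documented in the function
reference.

## Scope

The package operates on local files only: no live STITCH/PubChem queries,
no pretrained embedding models (the embedding contract accepts any
entity-id → 300-d CSV), no neural networks, and no generative chemistry —
substitutes come exclusively from the supplied candidate library. See
`vignettes/dacs-augmentation.Rmd` for the modeling assumptions and design
decisions.
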