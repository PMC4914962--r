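# SubLocML

Multi-label prediction of protein subcellular localization with
instance-based classifiers and ensemble voting.

Many proteins reside in several subcellular compartments at once, so
localization prediction is a multi-label problem: each protein carries a
*set* of location labels and a predictor must rank all q candidate
locations and pick a label subset. SubLocML is an R package for the full
workflow:

* **Dataset integration** — merge labelled protein sets from multiple
  sources (FASTA + label tables, with per-source label-name maps), collapse
  identical sequences with label-set union, and reduce redundancy with a
  CD-HIT-style greedy longest-first clustering so every retained pair of
  sequences has identity below a threshold (default 40%; identity =
  maximal aligned matches under free gaps divided by the shorter length).
* **Feature extraction** — the 188-dimensional
  composition/transition/distribution vector (20 amino-acid frequencies +
  24 physicochemical group contents + 24 transition frequencies + 120
  distribution descriptors over 8 properties × 3 groups), 20D and 420D
  PSSM-derived vectors (logistic-normalized column means, optionally
  conditioned on the query residue), and classic type-1 PseAAC.
* **Multi-label classifiers** — MLkNN (per-label Bayes rule over neighbor
  counts, Laplace-smoothed), BRkNN (neighbor label frequencies, with the
  empty-set-avoiding "a" variant), IBLR-ML (per-label logistic regression
  on leave-one-out neighbor label frequencies), and a binary-relevance
  wrapper over tree / forest / logistic / kNN base learners.
* **Ensemble voting** — mean, majority-vote (±1 votes, ties positive) and
  top-K fusion of P base classifiers: for each instance × label cell,
  `fused = mean(scores)`, `mean(votes) ≥ 0`, or the mean of the K largest
  scores; `topK(K = P)` coincides with the mean rule.
* **Evaluation** — ranking average precision
  `AP = (1/N) Σ_i (1/|y_i|) Σ_{λ∈y_i} |{λ'∈y_i : rank_i(λ') ≤ rank_i(λ)}| / rank_i(λ)`
  (AP = 1 exactly for perfect rankings), Hamming loss, subset accuracy,
  macro/micro precision/recall/F, a uniformly-random-scores AP baseline,
  and a seeded k-fold cross-validation driver with per-fold reports.
* **Synthetic data** — a generator that emulates a labelled localization
  set with controllable signal: Ising-like label co-occurrence, per-label
  composition directions, and synthetic PSSM profiles — so the whole
  pipeline is testable without any database download.

## Worked example

Simulate a 120-protein, 4-location dataset with strong composition signal,
then cross-validate a mean-vote ensemble of four multi-label classifiers on
188D features:

```r
library(SubLocML)

gen <- generateDataset(generatorConfig(n = 120, q = 4, effectSize = 3,
                                       seed = 7))
ds <- gen$dataset
ds
#> MultiLabelDataset with 120 proteins and 4 labels
#>   locative count: 191
#>   multi-label records: 56
#>   sequence lengths: 51 - 200
#>   vocabulary: Loc1, Loc2, Loc3, Loc4

report <- kfoldCrossValidate(
  ds,
  featureSpec = list(extractor = "188d"),
  modelSpecs = list(list(name = "brknn", k = 10),
                    list(name = "mlknn", k = 10),
                    list(name = "iblr",  k = 10),
                    list(name = "br", base = "tree")),
  ensemble = "mean", k = 5, seed = 7)
report
#> EvaluationReport
#>   ap               0.9146
#>   hammingLoss      0.1875
#>   subsetAccuracy   0.4917
#>   macroPrecision   0.8098
#>   macroRecall      0.6749
#>   macroF           0.7350
#>   microPrecision   0.8176
#>   microRecall      0.6806
#>   microF           0.7429
#>   (5 folds; AP mean 0.9146, sd 0.0241)

randomBaselineAP(labelMatrix(ds), trials = 100, seed = 7)
#> [1] 0.6173
```

The held-out ranking AP of 0.91 against a random-ranking baseline of 0.62
shows the ensemble recovering the composition signal the generator planted;
at `effectSize = 0` the same pipeline is statistically indistinguishable
from the baseline (see the test suite). The locative count (191 > 120) is
the "count a protein once per site" accounting used for multi-label
datasets.

A command-line wrapper covering the same workflow
(`simulate` / `integrate` / `features` / `train` / `predict` / `evaluate`)
is installed at `inst/cli/sublocml.R`:

```sh
Rscript inst/cli/sublocml.R simulate --n 60 --q 3 --effect-size 3 \
    --seed 5 --out-dir sim
Rscript inst/cli/sublocml.R evaluate --fasta sim/proteins.fasta \
    --labels sim/labels.tsv --models brknn,mlknn,iblr,br:tree \
    --ensemble mean --folds 5 --seed 2 --out-dir eval
```

See `vignettes/multilabel-localization.Rmd` for the full account of the
models, parameter defaults, tie-handling and design decisions.

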