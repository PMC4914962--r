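---
title: "Multi-label subcellular localization: methods and design notes"
author: "SubLocML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label subcellular localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubLocML)
```

# The problem

A protein's subcellular compartment constrains its function, and many human
proteins reside in several compartments at once — a nuclear/cytoplasmic
shuttling protein genuinely belongs to both locations. Prediction from
primary sequence is therefore a *multi-label* classification problem: each
protein carries a non-empty *set* of location labels, and a classifier must
output a scored ranking over all q candidate locations plus a hard
bipartition into predicted-relevant and predicted-irrelevant labels.

SubLocML implements this workflow end to end: integration of heterogeneous
labelled sources with redundancy reduction, sequence- and profile-based
feature extraction, instance-based multi-label classifiers, ensemble voting
fusion, and ranking-based evaluation under seeded cross-validation. A
synthetic-data module generates datasets with controllable label-composition
signal so that every stage is testable without any database download.

# Dataset integration

`mergeSources()` combines per-source FASTA + label-table pairs. Two records
are "the same protein" only when their residue-normalized sequences are
exactly equal; in that case their (canonically mapped) label sets are
unioned and the record keeps the id from the earliest source. Near-identical
cross-source duplicates are deliberately left to the redundancy-reduction
step, so merging stays a cheap exact-hash operation.

Label vocabularies differ across databases, so each source may carry a map
from its own label names onto the canonical vocabulary; the canonical column
order is first-seen order and is frozen with the dataset. We merge first and
reduce redundancy afterwards; doing it in the other order would let two
sources each contribute a member of a near-duplicate pair.

`reduceRedundancy()` replicates the greedy incremental clustering scheme of
CD-HIT: records are sorted longest-first (ties by id, so the scan order is
deterministic), and a record is retained only if its identity to every
already-retained record is below the threshold (default 0.4, the standard
setting for localization benchmarks). Identity between two sequences is the
maximum number of identical aligned pairs over all global alignments with
free gaps — equivalently the longest-common-subsequence length — divided by
the length of the shorter sequence, which is the denominator convention of
the clustering tool this emulates. The label sets of dropped near-duplicates
are discarded (the retained representative keeps only its own labels); an
alternative would be to union them, but a near-duplicate's labels are not
necessarily valid for the representative. At desk scale the O(N²) alignment
loop is acceptable; no k-mer prescreen is applied.

One caveat worth knowing: for unrelated random sequences the free-gap
identity concentrates near 0.45 for the 20-letter alphabet, i.e. *above*
0.4. A 40% threshold under this definition is therefore aggressive on
unrelated sequences, which is visible in the synthetic fixtures (a 30-
sequence fixture typically keeps only a handful of representatives). The
guarantee that matters — every retained pair sits strictly below the
threshold — holds by construction and is verified exhaustively in the tests.

# Feature extraction

Three extractor families are provided; all are deterministic functions of
the sequence (and profile) alone.

**188-dimensional composition/physicochemical vector** (`extract188D()`).
The layout is 20 + 24 + 24 + 120:

* 20 amino-acid composition frequencies;
* 24 group-content fractions: 8 physicochemical properties
  (hydrophobicity, normalized van der Waals volume, polarity,
  polarizability, charge, secondary-structure propensity, solvent
  accessibility, surface tension), each partitioning the alphabet into 3
  groups;
* 24 transition ("bivalent") frequencies: per property, the frequency of
  adjacent residue pairs falling in each unordered group pair, divided by
  L−1 (a length-1 sequence has a well-defined all-zero transition block);
* 120 distribution descriptors: per property × group, the relative sequence
  position (1-based position / L) of the first, 25%, 50%, 75% and 100%
  occurrence of that group, 0 when the group is absent. Fractional
  occurrence indices use the ceiling (the 25% checkpoint of 5 occurrences is
  the 2nd), matching common CTD implementations.

The group memberships ship as a documented, overridable table
(`ctdGroupings()`); the standard published CTD groupings are used. Adjacent
pairs are counted unordered, which is what keeps the transition block at
exactly 8 × 3 = 24 components.

**PSSM-derived vectors** (`extractPSSM20()`, `extractPSSM420()`). Profiles
are consumed as PSI-BLAST ASCII files (only the log-odds block is used) or
generated synthetically. Each raw log-odds score is passed through the
logistic map 1/(1+e^(−x)) before averaging, so components live in (0,1) and
an all-zero profile maps to 0.5; a raw-average mode is available behind the
`normalize` argument for users who prefer unsquashed means. The 20D vector
is the per-column mean over positions. The 420D vector appends 400
residue-conditioned components: for each amino-acid type a and column j, the
mean normalized score over the positions whose query residue is a (0 when a
is absent). This residue-conditioned reading is one of two plausible
interpretations of a "420-dimensional PSSM feature"; classic type-1 PseAAC
is exposed separately (`extractPseAAC()`) so the other reading — a PseAAC
vector of matching dimension — is also available.

**PseAAC** (`extractPseAAC()`). Chou's type-1 formulation: 20 normalized
frequencies plus lam sequence-order correlation factors computed from three
property scales (hydrophobicity, hydrophilicity, side-chain mass), each
z-standardized over the 20 residues (population denominator). The vector
sums to 1 by construction. Defaults lam = 4, w = 0.05 are the classic
settings; the sequence must be longer than lam.

Non-standard residues are normalized at parse time: B→D, Z→E, J→L, U→C,
O→K, and X/* positions are dropped so every 20-dimensional contract stays
exact; composition denominators use the retained length.

# Classifiers

All neighbor-based models use Euclidean distance on raw feature vectors
(per-column min-max scaling is available via the cross-validation driver's
`scale` option and is fit on training folds only). Distance ties are broken
by training id, never by storage order, so permuting the training set can
never change a prediction.

**MLkNN** applies a per-label Bayes rule to c, the number of the query's k
nearest neighbors carrying the label: smoothed priors
P(H) = (s + #positives)/(2s + N) and count-conditional likelihoods
P(c | H), P(c | ¬H) estimated from leave-one-out neighbor counts with
Laplace smoothing s over the k+1 bins. Defaults k = 10, s = 1.

**BRkNN** scores each label by its frequency among the k nearest neighbors.
The default "a" variant prevents empty predictions by emitting the
top-scoring label when nothing reaches 0.5 (ties resolve to the lowest
column index).

**IBLR-ML** fits, per label, a maximum-likelihood logistic model on
meta-features: the q leave-one-out neighbor label frequencies. Each label's
model therefore sees the local evidence for *all* labels, which is how label
correlations enter. This is a deliberate simplification of the published
instance-based logistic scheme (the variant that concatenates raw features
is not implemented). A label with a single training class cannot support a
logistic fit and degenerates to the empirical prior with a warning. Note
that with strongly separable training data the per-label MLE does not exist
and fitted probabilities saturate; this is inherent to unpenalized logistic
regression, not a defect of the meta-feature construction.

**Binary relevance** wraps one independent probabilistic binary learner per
label: recursive-partitioning trees, random forests, binomial GLMs, or a
neighbor-vote kNN, covering the single-label base-classifier roles (decision
tree / forest / IBK) of ensemble experiments. Single-class labels degenerate
to constant scores 0 or 1.

Hard bipartitions threshold scores at 0.5; the cross-validation driver's
`minOneLabel` option (default on) forces the top-scoring label when a set
would otherwise be empty, which makes accuracy comparisons on single-label
data fair.

# Ensemble voting

Three fusion rules combine P base classifiers over a shared vocabulary:

* **Mean**: per-cell arithmetic mean of the P probabilistic scores; predict
  when the mean reaches 0.5.
* **Majority vote**: each classifier votes ±1 per cell (probabilistic
  scores are bridged through `scoresToVotes()` at 0.5); the fused value is
  the mean vote and the rule is "≥ 0 is positive", so an exact tie counts
  as positive.
* **Top-K**: per cell, the mean of the K largest of the P scores; K = P
  recovers the mean rule exactly and K = 1 is the per-cell maximum. K
  defaults to ⌈P/2⌉, since the only guidance available is that K depends on
  P. The per-cell reading of "sort the P values in each column" is
  implemented; selecting the K globally most accurate classifiers would be
  a different estimator and is intentionally not what `topKEnsemble()`
  does.

The 0.5 boundary belongs to the positive class for mean/top-K, consistent
with the ≥ 0 rule of majority voting. All three rules are monotone in every
input score and invariant to classifier order; these properties are
property-tested over thousands of random matrices.

# Evaluation

**Ranking average precision** is the primary metric: for each instance,
the mean over its true labels of (true labels ranked at or above it) /
(its rank), averaged over instances. Ties are handled by the counting
convention — rank(l) is the number of labels scoring at least score(l), and
the numerator counts true labels the same way. We chose this over
average-tied-ranks deliberately: with averaged tied ranks, an instance
whose true labels tie at the top scores *above* 1, breaking the defining
property that AP = 1 is the ceiling attained exactly by perfect rankings
(classifiers that emit few distinct score values, such as neighbor
frequencies, tie constantly). Instances with no true label are excluded
from the mean with a logged count. AP is invariant under any strictly
increasing per-instance transform of the scores.

**Bipartition metrics**: Hamming loss (fraction of disagreeing
instance-label cells), subset accuracy, macro/micro precision, recall and
F. A label with no positives in either truth or prediction contributes
precision/recall/F of 1 by default (logged, configurable to 0).

**Cross-validation** (`kfoldCrossValidate()`) uses a plain seeded shuffle
into near-equal folds — not label-stratified, mirroring protocols that
leave stratification unstated; rare labels may produce single-class
training folds, which the classifier-level degenerate contracts absorb
without crashing. Any training-data-dependent featurization (scaling) is
fit on training folds only. The fold assignment is kept in the report, and
identical seeds reproduce the entire report byte for byte.

`randomBaselineAP()` gives the Monte-Carlo reference point used by the
signal-recovery tests: the mean AP of uniformly random score matrices
against the truth. For a single uniformly ranked true label among q, its
expectation is the mean of 1/r over r = 1..q, which the tests verify.

# Synthetic data

`generateDataset()` emulates an integrated localization training set with a
purely compositional signal:

* **Label sets** come from a pairwise (Ising-like) model: field terms are
  the logits of the marginal priors, pairwise terms are a symmetric
  log-odds co-occurrence matrix, sampled by Gibbs sweeps and resampled if
  empty. With a zero interaction matrix the sampler is exactly independent
  Bernoulli conditioned on non-emptiness — the tests compare empirical
  marginals and pairwise correlations against that conditional model's
  analytic values (the conditioning induces a small negative correlation,
  which is expected, not a bug).
* **Sequences**: each label owns a fixed composition direction (a Dirichlet
  draw, log-transformed, centered, scaled to unit norm); a protein's
  residue distribution is softmax(log background + effectSize × mean of its
  labels' directions), with residues i.i.d. and lengths uniform in range.
  The background is a realistic large-database amino-acid frequency table.

Defaults — n = 200, q = 5, prior 0.3 per label, effectSize = 2, lengths
50–200, conservation 0.9 — are intended as a plausible desk-scale stand-in
for a curated localization set: a few hundred proteins, a handful of
frequent compartments, moderate multi-locativity (about a third of proteins
carry ≥ 2 labels under these priors). The signal-recovery checks use n =
400 and effectSize = 3 (strong, cleanly separable composition bias) and 10
seeds at effectSize = 0 for the null; these sizes keep a full 4-classifier,
5-fold ensemble run around a few seconds.

Because the signal is composition-only, the amino-acid-composition block of
the 188D vector and the PSSM column means can provably capture it, which is
what makes parameter-recovery tests meaningful. Conversely, passing those
tests says nothing about order-sensitive structure (motifs, domains,
homology) in real proteins — real localization signal is partly positional
(targeting peptides), and no synthetic result here transfers to real data
accuracy claims.

`generatePSSM()` writes a profile whose rows mix a sharp signal (+7 at the
true residue, −2 elsewhere) with uniform integer noise in [−4, 4] under a
conservation weight; at conservation 1 the per-row argmax is exactly the
sequence, at 0 the profile is sequence-independent noise. All generator
randomness derives from one master seed through a per-stream splitting
scheme, so label sampling, direction drawing and sequence emission are
individually reproducible regardless of call order.

# Command-line interface

A thin wrapper (`inst/cli/sublocml.R`) exposes `simulate`, `integrate`,
`features`, `train`, `predict` and `evaluate` subcommands over the exported
functions; every run writes its resolved configuration as JSON next to its
outputs and logs structured progress to stderr. The R functions remain the
primary interface; the CLI adds nothing the API does not have.

# Numerical choices and degenerate inputs

* Identity threshold comparisons are strict (`< t` retained), matching the
  "each pair below 40%" reading.
* Euclidean neighbor ties: (distance, training id) lexicographic order.
* MLkNN smoothing keeps every posterior strictly inside (0, 1).
* Length-1 sequences: transition block defined as all zeros, not an error;
  empty sequences (after dropping X/*) are errors.
* An all-zero predicted bipartition row is written as an empty label field,
  and `minOneLabel` exists precisely to avoid producing it.
* Fold counts up to k = N (leave-one-out) are supported.

# Known limitations

* The redundancy reducer is O(N²) in alignments and meant for thousands of
  sequences, not databases.
* IBLR-ML's unpenalized logistic fits saturate on separable training sets;
  a ridge-penalized variant would be the natural extension.
* The ensemble weights all base classifiers equally; trained stacking is
  out of scope by design.
* The synthetic generator has no homology structure, so redundancy
  reduction and cross-validation leakage interact differently than on real
  families.
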