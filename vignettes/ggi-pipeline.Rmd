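---
title: "Classifying gene-gene interactions from heterogeneous expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene-gene interactions from heterogeneous expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ggiforest` treats gene–gene interaction (GGI) detection in two-class
expression data as binary classification of gene *pairs*. The premise is a
failure mode of correlation thresholding: when expression within one
condition is heterogeneous — large spread, inconsistent response across
patients, as is typical of complex neurodegenerative disease cohorts — the
within-class correlation of genuinely disease-relevant pairs is weak, and
no global cutoff on Pearson's r or mutual information separates them from
background. What often *does* distinguish such pairs is the change in their
marginal behaviour between conditions: shifted class means, inflated
class variance, widened range. A decision-tree ensemble over features that
expose both marginal contrast and (residual) association can learn that
regime; a single similarity score cannot.

A pair (A, B) is summarised by its four class-conditional expression lists
(gene x class label, after normalisation) and encoded as 22 features:
per-list mean, sample SD and max−min range (12); Welch's t statistic for
the four list pairings — the two cross-gene within-class contrasts and the
two cross-class within-gene contrasts (4); Pearson correlation within each
class (2); and mutual information within each class plus cross-class MI per
gene (4). Welch's form is used because the two lists being contrasted have
unequal sizes and, in the heterogeneous regime, unequal variances by
design. The t statistic itself is the feature; no p-value is computed.

## Normalisation

Expression is z-scored per gene across *all* samples pooled, before any
split by class: subtracting per-class means instead would erase exactly the
class-mean differences the features rely on. The sample SD (denominator
n − 1) is used everywhere in the package, matching the Welch convention.
Zero-variance genes become all-zero rows, are flagged, and are kept rather
than dropped so the gene universe stays aligned with the interactome. The
transform is idempotent in effect, so re-normalising a normalised matrix is
harmless.

## Numerical choices and degenerate inputs

The feature vector must always be finite for the learner, so degenerate
cases have documented values rather than NaN:

* `welch_t`: if both variance terms are zero, the statistic is 0 for equal
  means and a signed sentinel ±1e12 otherwise (logged). Sign convention is
  first argument minus second, in the listed feature order.
* `pcc`: zero-variance input gives 0, and results are clamped to [−1, 1]
  against rounding.
* `mutual_information`: the estimator is an equal-width histogram over each
  vector's own [min, max], default 10 bins, log base 2 (bits). The choice
  of estimator is deliberate: it is the simplest reproducible one, and the
  bin count is exposed as configuration. A constant vector has zero
  marginal entropy, hence MI 0. Negative rounding residue is clipped at 0.
* Cross-class MI compares lists of unequal length (the two class sizes), so
  the longer list is undersampled uniformly *without replacement,
  preserving relative order*, to the shorter length, and elements are then
  paired by position. A single draw is used by default; `mi_repeats`
  averages several draws. The undersampling stream is seeded from the
  global seed and the *gene id*, which makes feature matrices independent
  of pair order and makes the A↔B swap symmetry of the vector exact.

## Labelling

Positives start from a curated answer set of disease interactions. Because
curated sets are typically too small to train on, they are boosted from the
interactome: with a list of disease seed genes, every interactome edge
incident to a seed or to a first neighbour of a seed is added
(`k` iterations of the neighbourhood are supported; the default depth is 1,
and an induced-subgraph mode restricted to edges *inside* the seed+N1 set
is available). Without seeds, the positives are the answer set unioned with
the chosen interactome's edges. Pairs touching genes absent from the
expression matrix are dropped and counted.

Negatives are drawn uniformly from unordered gene pairs of the expression
universe, excluding the positives *and all interactome edges* — class 0
should represent non-interacting pairs, and excluding only the positives
would contaminate it with known interactions (the exclusion is
configurable). Exactly one negative per surviving positive is drawn, so the
labelled set is balanced by construction. Sampling enumerates all pairs
exactly when the universe is small and otherwise rejection-samples, which
remains uniform over eligible pairs; feasibility is checked exactly first.

## The forest

The classifier is a bagged ensemble of `t = 100` CART-style trees,
implemented in compiled code inside the package (no external learner):
each tree is grown on a bootstrap sample (size = training-set size by
default; a fixed bootstrap size is available), choosing at each node the
best Gini-impurity split among `⌊log₂ M⌋ + 1 = 5` randomly drawn candidate
features, until leaves are pure, hold fewer than 2 instances, or no sampled
feature admits an improving split. Prediction scores are the fraction of
trees voting class 1; an exact 0.5 tie resolves to class 0. All randomness
flows through R's RNG, so a seed fully determines training, and the JSON
model serialisation round-trips to bit-identical predictions.

One design point was genuinely open: the pseudocode convention for the
per-node feature-subset size ties it to the logarithm of the *tree count*,
which is independent of the feature dimension and conflicts with standard
ensemble practice; the package uses the Breiman/Weka convention
`⌊log₂ M⌋ + 1` over the M = 22 features and exposes it as configuration.

Feature importance is mean decrease in Gini impurity (split gain weighted
by the fraction of bootstrap instances reaching the node, averaged over
trees, normalised to sum to 1), not permutation importance; ties keep the
fixed feature order.

## Evaluation

`cross_validate()` stratifies each class separately into folds (default
10), trains on the complement and predicts the held-out fold. The five
summary metrics — accuracy, precision, recall, F-measure, ROC area — are
support-weighted and computed from the pooled out-of-fold predictions
(aggregated-confusion convention); per-fold values are retained in the
report. ROC area integrates the threshold sweep of the vote scores by the
trapezoid rule, with tied scores collapsed to a single ROC point.

## The synthetic world

`simulate_dataset()` generates the regime the method targets, as a stated
world with fixed defaults: 500 genes, 60 + 60 samples, 100 planted disease
pairs. Background genes are i.i.d. N(0, 1) in both classes. Each planted
gene receives, in the disease class only, a mean shift (0.8), an SD
inflation (×1.5) and independent per-sample heterogeneity noise
(SD 0.5). Because the two genes of a planted pair are perturbed
independently, their within-class correlation is weak; a rejection step
regenerates any planted pair with |PCC| ≥ 0.3 in either class, so the
"correlation fails, marginal features succeed" regime is guaranteed rather
than probable. Defaults not fixed elsewhere were chosen once as plausible
for brain-cohort microarray data after z-scoring (a ~0.6–0.8 SD shift with
50% variance inflation is a strong but not caricatural disease signature)
and are not tuned.

The interactome is the planted pairs plus a scale-free
preferential-attachment graph (2 edges per node) over the *background*
genes, with uniform edge confidences; seeds are a random 20% of planted
genes and the answer set a random 50% of planted pairs. Keeping the
background graph off the planted genes is deliberate: the planted pairs are
the interactome's disease module, so seed-neighbour expansion recovers
disease pairs, as the labelling model assumes. If planted genes also
carried arbitrary background edges, expansion would flood class 1 with
pairs carrying no expression signal and no classifier could meet the
recovery properties — that would test the generator, not the method.

What a green benchmark does establish: the full pipeline (normalisation →
labelling → features → forest → CV) separates planted heterogeneous pairs
from non-interacting pairs (accuracy ≥ 0.85, ROC ≥ 0.90 across seeds)
while a |PCC|-only baseline stays near chance, and a model transfers to an
independently simulated dataset (>90% planted-pair recovery). What it does
not establish: performance on real cohorts — the generator emulates
neither platform/batch effects, probe-level noise, correlated background
co-expression, nor identifier mismatch between expression and interactome
namespaces.

A caveat worth knowing when building nulls: labelling scale-free
interactome *edges* positive is not a null even with i.i.d. expression.
Hub genes recur in many pairs on both sides of the fold split, their
per-gene statistics (sample means, SDs) are memorisable, and the forest
reaches ROC ≈ 0.7 with zero class signal. This gene-identity leakage is
inherent to pair-level cross-validation with shared genes; the package's
null test therefore draws both classes from the same non-edge distribution,
which sits at ROC ≈ 0.5. For real applications this means CV estimates are
optimistic to the extent that test pairs share genes with training pairs.

## Network analysis

Applying a model to a new dataset is restricted to candidate pairs that
exist in the interactome, which keeps the candidate space tractable and
biologically anchored. Predicted-positive pairs (score > 0.5) form the GGI
network. The hub subnetwork ranks nodes by degree (ties broken
lexicographically for reproducibility), keeps the top 20 by default, and
returns hubs + first neighbours + all incident predicted edges — an
expanded-neighbourhood summary; an induced hub-only mode is a flag. The
correlation audit recomputes within-class PCC and MI for predicted edges
missing from the answer set, documenting that novel predictions are
low-correlation pairs a threshold would have missed.

## Limitations

* The MI estimator is a fixed-width histogram; k-NN or adaptive-binning
  estimators may be preferable at small sample sizes and are out of scope.
* Cross-class MI depends on one undersampling draw by default; averaging
  (`mi_repeats`) reduces that variance at linear cost.
* Identifier mapping between protein and gene namespaces, probe-to-gene
  collapse beyond duplicate-row averaging, and batch correction are out of
  scope; inputs are assumed to share one namespace.
* Pair-level CV shares genes between folds (see above); gene-disjoint fold
  construction would be stricter and is not implemented.
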