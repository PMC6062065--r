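# ggiforest

Random-forest identification of gene–gene interactions (GGIs) from
heterogeneous two-class gene expression profiles.

## The problem

Co-expression network inference usually scores each gene pair with a
correlation measure (Pearson's r, mutual information) and keeps pairs above
a threshold. In clinically heterogeneous conditions — late-onset
neurodegeneration is the motivating case — expression of disease genes
varies so much *within* the disease group that informative pairs have weak
within-class correlation, and no threshold separates them from noise.

`ggiforest` recasts the decision as supervised classification. Each
candidate pair (A, B) is reduced to its four class-conditional expression
lists E<sub>A,L0</sub>, E<sub>A,L1</sub>, E<sub>B,L0</sub>,
E<sub>B,L1</sub> (L0 = normal, L1 = disease, after per-gene z-scoring) and
encoded as 22 statistics:

| block | features |
|---|---|
| location / spread | mean, sample SD, max−min of each of the 4 lists (12) |
| class contrast | Welch t for (A·L0, B·L0), (A·L1, B·L1), (A·L0, A·L1), (B·L0, B·L1) (4) |
| linear association | Pearson r within class 0 and within class 1 (2) |
| non-linear association | binned mutual information within each class, and cross-class MI per gene after order-preserving undersampling equalises list lengths (4) |

Class-1 training pairs come from a curated disease interaction list (the
*answer set*), boosted by taking every interactome edge incident to known
disease *seed genes* and their first neighbours; class-0 pairs are sampled
uniformly from non-interacting gene pairs, one per positive, so classes are
balanced. A 100-tree random forest (Gini splits over
⌊log₂ 22⌋ + 1 = 5 randomly drawn features per node, bootstrap bagging,
majority vote) is evaluated by stratified 10-fold cross-validation with
support-weighted accuracy, precision, recall, F-measure and trapezoidal ROC
area. A trained model applied to the interactome-restricted pairs of a new
dataset yields a predicted GGI network, summarised by its top-degree hub
subnetwork.

Everything is seeded and deterministic, and a synthetic generator
(`simulate_dataset()`) builds a complete benchmark — expression matrix with
planted low-correlation disease pairs, scale-free interactome, seed list,
answer set, ground truth — so the whole pipeline is testable offline.

## Worked example

```r
library(ggiforest)

sim <- simulate_dataset(simulation_config(rng_seed = 1))
ds  <- zscore_normalise(sim$dataset)
ds
#> ggi_expression: 500 genes x 120 samples (60 class 0, 60 class 1), z-scored

labeled <- build_labeled_set(sim$answer_set, sim$net, sim$seeds, ds, rng_seed = 1)
labeled
#> ggi_labeled_set: 69 positives, 69 negatives

pairs <- Map(pair_from_dataset, list(ds),
             labeled$pairs$gene_a, labeled$pairs$gene_b)
X <- feature_matrix(pairs, rng_seed = 1)

cross_validate(X, labeled$pairs$label, folds = 10, rng_seed = 1)
#> ggi_evaluation (10-fold CV): accuracy 0.891, precision 0.893, recall 0.891,
#>   F 0.891, ROC area 0.935

model <- train_forest(X, labeled$pairs$label, rng_seed = 1)
head(feature_importance(model), 5)
#>        feature importance
#> 1      SD_B_L0 0.14086257
#> 2 WT_A_L0_A_L1 0.12567259
#> 3    Mean_A_L1 0.12564733
#> 4 WT_B_L0_B_L1 0.08696866
#> 5    Mean_A_L0 0.07686066

# apply the model to an independent dataset
app    <- simulate_dataset(simulation_config(rng_seed = 2))
app_ds <- zscore_normalise(app$dataset)
net <- classify_network(model, candidate_pairs(app_ds, app$net),
                        rng_seed = 2, seeds = app$seeds)
net
#> ggi_network: 192 nodes, 96 predicted edges

sub <- hub_subnetwork(net, top_k = 20)
```

Reading the numbers: of 138 balanced training pairs, ten-fold CV classifies
89% correctly with ROC area 0.935, while a single-feature |Pearson r|
baseline on the same pairs stays near chance (AUC ≈ 0.51) — the planted
pairs are constructed with |r| < 0.3 in both classes, so only the marginal
heterogeneity features can find them. The importance ranking shows exactly
that: spread and class-contrast statistics (SD, Welch t, means) dominate;
correlation features rank low. Applied to a fresh dataset, the model keeps
96 of ~700 candidate interactome edges, recovering >90% of the 100 planted
disease pairs. (In this synthetic world planted pairs are disjoint, so
predicted degrees are all 1 and the "hub" subnetwork is flat; hubs become
meaningful on real interactomes, where the analysis reports each hub's
degree, seed status and first neighbours.)

## Command line

```sh
Rscript inst/cli/ggi.R simulate       --config run.yaml
Rscript inst/cli/ggi.R build-training --config run.yaml
Rscript inst/cli/ggi.R train          --config run.yaml
Rscript inst/cli/ggi.R evaluate       --config run.yaml
Rscript inst/cli/ggi.R classify       --config run.yaml
Rscript inst/cli/ggi.R network        --config run.yaml
```

`run.yaml` holds paths and knobs (see `default_run_config()`); flags such
as `--seed`, `--trees`, `--folds`, `--top-k`, `--top-fraction`,
`--no-seed-expansion` override it. Every artefact gets a
`*.meta.json` sidecar recording the seed and a config hash; identical
config + seed reproduce every output byte for byte.

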