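# jsnmf

Joint similarity nonnegative matrix factorization for multi-omics
co-module discovery.

## The problem

Tumor cohorts are increasingly profiled on several axes at once — for
example patient-level features quantified from pathology images, gene
expression, and per-sample pathway activity scores. Each modality is a
nonnegative sample-by-feature matrix over the same patients, and the
question is which cross-modal feature groups move together and track a
clinical outcome such as local recurrence. `jsnmf` is for
bioinformaticians and computational biologists who have such matrices in
hand and want interpretable, outcome-linked *co-modules*: sets of image
features, genes and pathways that load on a shared latent factor.

## The model

Given three nonnegative blocks `X_I` (n samples × q_I features,
I = 1, 2, 3), the package factorizes them jointly over a shared
nonnegative basis `W` (n × K) with per-modality coefficients `H_I`
(K × q_I), minimizing

```
sum_I ( ||X_I − W H_I||_F²  +  (β/2) ||H_I H_Iᵀ − M||_F² )  +  α ||W − R||_F²
```

subject to `W ≥ 0`, `H_I ≥ 0`. The two penalties are the method's core:

* **Similarity prior** `α‖W − R‖²`: `R` (n × K) is distilled from the
  data themselves by similarity network fusion — per-modality Euclidean
  distances → scaled-exponential kernel → row-stochastic k-NN affinity →
  convex fusion across modalities — followed by PCA of the fused network
  and per-component min-max scaling to [0, 1]. `R` anchors the basis in
  the cohort's fused patient-similarity structure (semi-supervision).
* **Orthogonality** `(β/2)‖H_I H_Iᵀ − M‖²` with `M` the K × K identity
  (or all-ones) target, which sparsifies the coefficient rows and
  de-correlates components.

Optimization is by NNDSVD-initialized multiplicative updates whose
traced objective is provably non-increasing (checked property-wise in
the test suite); fits are fully deterministic. Co-modules are read off
per component by a z-score rule on each `H_I` row, linked to recurrence
through Pearson association of the `W` columns with the clinical table,
and scored for cross-modal consistency by hypergeometric gene-set
enrichment and the overlap ratio `O = m/n` (the fraction of pathways
enriched in a module's genes that are also among its selected
pathway-score features). Rank-sum differential screens and per-feature
ROC/AUC with DeLong intervals support biomarker triage.

## Worked example

The package ships a synthetic-cohort generator that plants known
factors, couples one component to a binary recurrence label, and builds
a matching toy gene-set collection:

```r
library(jsnmf)

sim <- generate_synthetic(synthetic_spec(seed = 42))
sim$dataset
#> multiomics_dataset: 100 samples, blocks 50 / 80 / 60
#>   recurrence: 50 / 100 positive
#>   covariates: age

cfg <- jsnmf_config(K = 4, alpha = 0.1, beta = 0.1, max_iter = 300)
run <- run_pipeline(sim$dataset, cfg, collection = sim$truth$collection)

run$prior$spectral$agreement   # ARI of fused-network clustering vs label
#> [1] 1

run$metrics$sample_cor
#>   block  mean_cor     ci_lo     ci_hi n_samples
#> 1     1 0.8011196 0.7681689 0.8307426       100
#> 2     2 0.6711613 0.6358197 0.7030450       100
#> 3     3 0.7352783 0.6983127 0.7686459       100

run$comodules
#> comodule_set: 4 components; recurrence-selected component: 2
#>   C1: features 10/10/10; overlap ratio 1.000
#>   C2: features 10/10/10; overlap ratio 1.000
#>   C3: features 10/10/10; overlap ratio 1.000
#>   C4: features 10/10/10; overlap ratio 1.000

match_components(run$model$W, sim$truth$W_true)$mean_cor
#> [1] 0.973
```

Reading the output: the fused network separates the planted recurrence
groups perfectly (ARI 1); reconstructed per-sample profiles correlate
0.67–0.80 with the observed ones at noise sd 0.1; every planted
co-module is recovered with all ten features per modality and full
cross-modal overlap; and the fitted basis columns match the planted ones
at mean Pearson 0.97 after permutation matching. Component 2 of the fit
is the one whose basis column tracks the recurrence label — it
corresponds to the planted label-coupled component.

Real data enter through `read_dataset()` (three delimited matrices plus
a clinical table with a binary `recurrence` column) and `read_gmt()`;
`grid_search()` reproduces the usual K × α × β model-selection sweep by
relative error. A thin command-line front end with `simulate`, `fuse`,
`fit`, `evaluate`, `comodule`, `grid` and `pipeline` subcommands lives
at `inst/cli/jsnmf-cli.R`.

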