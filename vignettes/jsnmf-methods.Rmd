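---
title: "Network-regularized joint NMF for multi-omics co-modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-regularized joint NMF for multi-omics co-modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `jsnmf`, in the spirit of a methods section: what is
computed, under which assumptions, and where the genuinely open design
choices were resolved.

# The factorization model

Three nonnegative blocks $X_I \in \mathbb{R}_{\ge 0}^{n \times q_I}$
($I = 1,2,3$) over the same $n$ samples are factorized jointly as
$X_I \approx W H_I$ with one shared basis $W \in \mathbb{R}_{\ge 0}^{n
\times K}$ and per-modality coefficients $H_I \in \mathbb{R}_{\ge 0}^{K
\times q_I}$. The fitted objective is

$$
J(W, H) \;=\; \sum_{I=1}^{3} \Big( \lVert X_I - W H_I \rVert_F^2
  + \tfrac{\beta}{2} \lVert H_I H_I^{\top} - M \rVert_F^2 \Big)
  + \alpha \lVert W - R \rVert_F^2 ,
$$

with $M$ either the $K \times K$ identity (default) or the all-ones
matrix, selected by `ortho_target`. Four nested variants are exposed:
`jnmf` ($\alpha = \beta = 0$), `oc_jnmf` ($\alpha = 0$), `snf_jnmf`
($\beta = 0$) and the full `jsnmf`. Assumptions worth stating: samples
are exchangeable rows shared across blocks; every feature is nonnegative
and not identically zero (all-zero columns are dropped at load time with
a warning, because a multiplicative update can never move them and they
break correlation-based metrics); and $K$ is far below $n$.

## Why the orthogonality penalty carries a factor 1/2

The multiplicative H-update used here solves the KKT stationarity
condition
$W^{\top} X_I = W^{\top} W H_I + \beta (H_I H_I^{\top} - M) H_I$.
A penalty written as $\beta \lVert H H^{\top} - M \rVert_F^2$ has
gradient $4\beta (H H^{\top} - M) H$, i.e. twice that condition's
$\beta$-term; the penalty whose gradient matches the update exactly is
$\tfrac{\beta}{2}\lVert H H^{\top} - M \rVert_F^2$. The package
therefore traces and tests $J$ with the $\beta/2$ convention — the
objective the update provably does not increase — and
`jsnmf_objective(..., ortho_scale = 1)` evaluates the face-value penalty
for anyone who wants it. Only the bookkeeping scale of one term is
affected; the $\alpha$ term and the fits themselves are identical either
way.

## Update rules and the sign-split denominator

One iteration updates $W$ first and then every $H_I$ with the fresh $W$
(standard block practice):

$$
W \gets W \circ \frac{\sum_I X_I H_I^{\top} + \alpha R}
  {\sum_I W H_I H_I^{\top} + \alpha W}, \qquad
H_I \gets H_I \circ \frac{W^{\top} X_I + \beta M H_I}
  {W^{\top} W H_I + \beta H_I H_I^{\top} H_I}.
$$

The H-denominator deserves a note. Writing it as
$W^{\top} W H_I + \beta (H_I H_I^{\top} - M) H_I$ is algebraically the
same stationarity condition, but that form can turn negative — routinely
so for $\beta = 10$ with the all-ones target, where $H H^{\top} - M$
starts far below zero — and clamping a near-zero denominator makes the
multiplicative ratio explode, destroying both nonnegativity of the
objective decrease and numerical sanity. Splitting the penalty term by
sign and moving $\beta M H_I$ to the numerator keeps numerator and
denominator nonnegative, leaves the fixed points unchanged, reduces
bitwise to the unconstrained update at $\beta = 0$, and empirically
restores the monotone objective across the whole
$\alpha, \beta \in \{0.01, 0.1, 1, 10\}$ grid (the property suite checks
20 seeded instances per run). A small guard ($10^{-10}$) is still added
to every denominator so exact zeros cannot divide.

## Initialization, stopping, scaling

* **NNDSVD.** $W, H$ are initialized by nonnegative double SVD of the
  column-concatenation $[X_1\, X_2\, X_3]$, splitting the coefficient
  matrix back into blocks. Structural zeros are floored at $10^{-6}$ so
  updates can escape them; components beyond the numerical rank are
  seeded at the floor with a warning. The initialization — and therefore
  the whole fit — is deterministic, which is what makes the pipeline
  bitwise reproducible.
* **Stopping.** Iterations stop when the relative objective change drops
  below `tol` ($10^{-6}$ default) or at `max_iter` (500 default, the
  conventional cap for this family). `max_iter = 0` returns the
  initialization, which is occasionally useful for diagnostics.
* **Block scaling.** By default every feature column is min-max scaled
  to $[0, 1]$ before fitting, because image-derived, expression and
  pathway-score blocks live on very different scales and would otherwise
  contribute wildly unequal Frobenius terms. Constant columns map to 1.
  All reported reconstruction metrics are computed on the scaled
  matrices actually fitted. One consequence of the min subtraction is a
  rank-one offset: exactly rank-$K$ data are no longer exactly rank-$K$
  after scaling, so analyses that rely on exact recovery at the true $K$
  (such as the noiseless-plant test) disable scaling.

## Convergence trace and relative error

Each iteration records the objective, the relative error, and the
Frobenius distances between successive $W$ and $H_I$ iterates. The
relative error — also the model-selection criterion of `grid_search()` —
is

$$
\mathrm{RE} = \sum_{I=1}^{3}
  \frac{\operatorname{mean}\lvert X_I - W H_I \rvert}
       {\operatorname{mean} X_I},
$$

i.e. per block the grand mean of the absolute residual over the grand
mean of the data. A per-column normalization is a defensible alternative
reading of this statistic; the grand-mean form was chosen because it is
robust to near-zero-mean columns and coincides with the per-column form
whenever column means are equal. The summed (not averaged) Frobenius
distance $\sum_I \lVert X_I - W H_I \rVert_F$ is reported alongside.

# The similarity-network prior

The prior $R$ is built in four steps per modality and one fusion step:

1. **Distances:** pairwise Euclidean distances between sample rows.
2. **Kernel:** scaled-exponential similarity
   $S_{ij} = \exp(-D_{ij}^2 / (\mu \sigma_{ij}))$ with the local
   bandwidth $\sigma_{ij} = (\bar d_i + \bar d_j + D_{ij})/3$, where
   $\bar d_i$ is the mean distance of $i$ to its $k$ nearest neighbors.
   This is the canonical kernel of the similarity-network-fusion
   literature; nothing in the co-module method depends on its fine
   details, and it degrades gracefully when modalities have
   heterogeneous scales. $\mu = 0.5$ by default.
3. **k-NN affinity:** row $i$ gives mass $1 - \varepsilon$ to its $k$
   nearest neighbors proportionally to similarity and $\varepsilon$ to
   everyone else, making rows exactly stochastic. Defaults:
   $\varepsilon = 0.01$ ("a small number" made concrete),
   $k = \lceil n/10 \rceil$ (the usual heuristic), both exposed in the
   configuration. Neighborhoods exclude self; ties at the $k$-th
   neighbor break toward the smaller sample index so runs are
   deterministic. A row with zero out-of-neighborhood mass folds its
   $\varepsilon$ share into the neighborhood instead of dividing by
   zero.
4. **Fusion:** the fused network is the convex combination
   $A = \sum_m w_m A^{(m)}$ with uniform weights by default. This is a
   single weighted average, not iterative cross-diffusion — the simplest
   fusion that preserves row-stochasticity — and the weights are a
   configuration simplex.
5. **PCA distillation:** $A$ is column-centered, the leading $K$
   principal-component score vectors are taken, each component's sign is
   fixed so the largest-magnitude loading is positive (a deterministic
   convention; PCA is otherwise sign-ambiguous), and each score column
   is min-max scaled into $[0, 1]$. Scores can be negative while the
   update $\alpha R$ must keep $W$ nonnegative; min-max scaling
   guarantees nonnegativity while preserving the sample ordering within
   every component, and the per-column min/max are stored for
   reproducibility.

A diagnostic `spectral_check()` clusters the symmetrized fused network
into two groups (normalized spectral embedding, then 2-means seeded at
the farthest embedded pair — deterministic) and reports the adjusted
Rand index against the recurrence label. It validates that fusion
carries outcome signal; it feeds nothing downstream.

# Co-module extraction and evaluation

* **Feature selection:** feature $j$ belongs to component $k$ when
  $H_{kj} > \operatorname{mean}(H_{k\cdot}) + T \cdot
  \operatorname{sd}(H_{k\cdot})$ with the population ($1/n$) standard
  deviation and $T = 1.5$ by default — the usual exceedance rule in the
  joint-NMF co-module literature, where no sharper definition of a
  "significant" coefficient exists. Raising $T$ can only shrink the set.
* **Clinical association:** Pearson $r$ with two-sided $p$ between every
  $W$ column and every clinical variable, binary variables coded 0/1 and
  categorical ones intended to be one-hot coded by the caller. The
  recurrence module is the column with maximal $|r|$ against the label
  among columns with $p < 0.05$.
* **Differential screen:** per-feature two-sided Wilcoxon rank-sum test
  via the normal approximation with tie correction and no continuity
  correction — the latter so that the implementation agrees exactly with
  an independent scalar oracle of the same statistic. Raw-$p$
  thresholds (0.01 default, 0.05 for small cohorts) follow common
  practice; BH q-values are reported per block as the multiplicity
  family.
* **Enrichment and overlap:** one-sided hypergeometric tests of the
  selected gene set against a user-supplied GMT collection, BH-adjusted
  within the collection, enriched at $q < 0.05$. The overlap ratio
  $O = m/n$ divides the enriched-and-selected pathway count by the
  enriched count; when nothing is enriched, $O$ is reported as missing
  rather than 0, so empty modules are not silently scored as failures.
* **Biomarker ROC:** per-feature AUC by the rank ($U$-statistic)
  formulation with a DeLong 95% interval.

# The synthetic cohort generator

`generate_synthetic()` emulates the structure of the motivating cohorts
— three nonnegative blocks over shared patients, a binary recurrence
label, a pathway-to-gene GMT — at desk scale. Each planted component is
elevated (by 0.4 over a 0.05–0.30 baseline) in a random half of the
samples; the label component is elevated by `label_strength` (default 1)
and its active half *is* the recurrence group, with labels defined by
the median split of that basis column. Coefficient rows load strongly
(0.8–1.2) on `module_size` disjoint features per block over a weak
background (0.02–0.10) that keeps every column nonzero, blocks are
$W H_I$ plus Gaussian noise clipped at zero, and each planted pathway
feature gets a gene set holding that component's planted genes plus
decoys, alongside one unrelated decoy set per component. Defaults —
$n = 100$, blocks of 50/80/60 features, $K_{\mathrm{true}} = 4$, ten
features per module, noise sd 0.1 — were fixed once as a realistic
miniature of a few-hundred-patient cohort with strong but noisy latent
structure, and the fixed scenario suite (`default_acceptance_suite()`)
pins these and two smaller two-group scenarios under distinct seeds.

What the generator does *not* emulate: count-distributed noise
(clipped Gaussian only), correlated or overlapping modules, batch
effects, missing samples across modalities, or label noise. Passing the
recovery tests therefore demonstrates correctness of the machinery on
clean planted structure, not performance on real tumor cohorts.

# Numerical conventions, sizes, limitations

Degenerate inputs are handled explicitly: fewer than three samples is an
error (neighborhoods undefined); an all-identical cohort is a degenerate
kernel input; constant rows/vectors are excluded from correlation
metrics with a warning; a constant coefficient row selects nothing.
Component matching for recovery scoring is an exhaustive permutation
search over column correlations (fine up to $K = 8$; recovery scenarios
use $K = 4$). Bootstrap intervals (2000 resamples by default) are
seeded and leave the caller's RNG state untouched.

The test and validation suites run at deliberately modest sizes chosen
as sufficient for the properties they check: monotonicity on 20 seeded
$60 \times (30, 40, 50)$ instances for 200 iterations across all
variants, both orthogonality targets and the full penalty grid; recovery
on three $100 \times (50, 80, 60)$ cohorts; the 64-combination grid
sweep at $n = 40$ with a reduced iteration cap, which exercises the
selection and tie-break logic (smaller $K$, then $\alpha$, then
$\beta$) in full.

Known limitations: exactly three modalities (the natural generalization
to $m$ blocks is mechanical but untested); dense matrices only; the
fusion weights are fixed, not learned; survival-style analyses (Cox
models, Kaplan–Meier curves) and database-backed enrichment are out of
scope — enrichment is generic against any GMT the user supplies.
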