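---
title: "Discovering block-interaction models with sparse multi-block CCA"
author: "blockcca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering block-interaction models with sparse multi-block CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcca)
```

## The problem

Multi-omic studies routinely measure the same samples on several assays — a
host transcriptome, a 16S microbiome profile, copy-number variation — next to
clinical covariates such as sample location, sex or time since treatment.
Regularized generalized canonical correlation analysis (RGCCA) integrates such
data by finding, for each block $X_j$ ($n$ samples $\times\ p_j$ features), a
loading vector $a_j$ whose latent component $Y_j = X_j a_j$ co-varies with the
components of the blocks it is declared to interact with. Which blocks
interact, and how strongly, is encoded in a symmetric design matrix
$C = (c_{jk})$, $c_{jk} \in [0, 1]$ — and in most applied work this matrix is
simply written down a priori.

This package treats the design itself as the unknown. It enumerates candidate
designs over weight grids, keeps only those forming a single connected
network, fits each candidate, ranks them by the *inner average variance
explained* of their components, and quantifies the stability of competing
models by bootstrap resampling. The output is not only a fitted latent-variable
model but an explicit, data-driven statement about which block interactions a
dataset supports.

## The fitted criterion

For a scheme function $g$ and per-block regularization $\tau_j$, fitting
maximizes

$$\sum_{j \le k} c_{jk}\, g\!\left(\operatorname{cov}(X_j a_j,\ X_k a_k)\right)
\quad \text{s.t.} \quad a_j^\top M_j a_j = 1,\qquad
M_j = \tau_j I + (1 - \tau_j)\tfrac{1}{n} X_j^\top X_j .$$

* **Schemes.** `horst` uses $g(x) = x$, `centroid` $g(x) = |x|$, `factorial`
  $g(x) = x^2$. The centroid scheme (the default) counts negative component
  correlations as evidence of interaction too, which matters because component
  signs are arbitrary; horst and centroid coincide whenever all pairwise
  covariances stay positive during the iterations.
* **Tau.** $\tau_j = 0$ constrains components to unit variance (a correlation
  criterion; for two blocks this is classical CCA), $\tau_j = 1$ constrains
  loadings to unit norm (a covariance criterion, PLS-like). In between, the
  Schaefer–Strimmer shrinkage estimate (`estimate_tau()`) provides a
  data-driven compromise; blocks of dummy-coded categorical covariates are
  always fitted at $\tau = 1$, because only covariance with other blocks is
  meaningful for 0/1 indicators.
* **Diagonal design entries** $c_{jj}$ add a within-block term
  $c_{jj}\, g(\operatorname{var} Y_j)$, interpreting a self-edge as
  interaction among a block's own features. They are part of the search space
  but excluded from the inner AVE (a component trivially "explains" itself).
* **Sparsity.** `fit_sgcca()` replaces the $M_j$-norm constraint by
  $\lVert a_j\rVert_2 = 1,\ \lVert a_j\rVert_1 \le s_j \sqrt{p_j}$, solved by
  soft-thresholding with a bisection on the threshold. $s_j = 1$ reproduces
  the dense fit at $\tau = 1$; $s_j = 1/\sqrt{p_j}$ selects a single feature.

Blocks enter after `scale2()` standardization: every feature centered and scaled
to unit sample variance, then the block divided by $\sqrt{p_j}$ so every
block carries total variance 1 regardless of width. Covariances inside the
objective use the population denominator $n$, consistent with that
normalization.

## Model selection by AVE

For a component $y$ and block $X$, the block AVE is the variance-weighted
mean of $\operatorname{cor}^2(x_k, y)$ over features — after `scale2()`, the
plain mean. The **outer AVE** size-weights block AVEs by $p_j$ and says how
well components summarize their own blocks. The **inner AVE**,

$$\text{AVE}_\text{inner} =
\frac{\sum_{j<k} c_{jk}\operatorname{cor}^2(y_j, y_k)}{\sum_{j<k} c_{jk}},$$

says how well the declared interactions are realized, and is the selection
criterion: among connected candidates, higher inner AVE = better model. The
design weights enter as multipliers (not a 0/1 mask) so that the criterion
sees the same weights the fit used; a mask mode exists for sensitivity
checks. With several components, selection uses the first component's AVE —
the dominant shared structure — with per-component values reported alongside.

## The search

`search_models()` expands a `model_template()` over its free edges — by
default the coarse grid $\{0, 0.5, 1\}$, the `fine` stage uses $0$ to $1$ in
steps of $0.1$, optionally restricted to $\pm 0.2$ around the coarse winner —
symmetrizes, drops disconnected designs (connectivity depends only on the
zero pattern), fits every survivor with shared settings, and ranks. Tau is
estimated once per block on the full data, not per candidate, so candidates
differ only in their design. Exact ties in inner AVE resolve toward fewer
nonzero edges, then the lexicographically smaller weight vector, making
rankings fully deterministic. A superblock (`add_superblock()`) — the
concatenation of all blocks, connected to each — can be appended for
hierarchical interpretation; its features are excluded from outer-AVE totals
to avoid double counting.

## Bootstrap stability

`bootstrap_model()` resamples the $n$ samples with replacement — one index
vector applied jointly to all blocks, preserving sample linkage —
re-standardizes each resampled block (resampling changes feature means and
variances, and the fit assumes the `scale2()` normalization), refits with
fixed scheme/tau/sparsity, and records first-component inner and outer AVE.
Replicate $b$ draws its indices from a stream seeded `seed + b`, so
enlarging $B$ never perturbs earlier replicates. Replicates with degenerate
resampled blocks (e.g. a dummy column that became constant) are dropped and
counted; convergence failures are kept, since the AVE remains computable. A
model that truly captures the block relationships shows both a higher mean
and a smaller standard deviation of the bootstrapped inner AVE than a
misspecified competitor — `summarize_dispersion()` flags such dominance.

## What the synthetic generator emulates

`generate_blockset()` plants the structure the pipeline is meant to find:
per-sample latent factor vectors drawn from a multivariate normal whose
correlation matrix is `cor_scale` (default 0.8) times the planted design
(feasibility is checked on every call; semidefinite targets such as perfectly
shared factors are allowed), sparse loadings with equal-magnitude random
signs (so an $\ell_1$ budget of $\sqrt{k}$ corresponds to exactly $k$ active
features, making support recovery a well-posed target), i.i.d. Gaussian
feature noise (default sd 0.5 against a unit-scale signal), and categorical
covariates that shift the latent factors by centered, equally spaced level
effects. `make_confounded_scenario()` specializes this to the pure-confounder
case: a two-level covariate drives the latent factors of both omic blocks
(default separation 2 latent standard deviations) with no direct inter-block
edge, so the covariate-including model should, and in our experiments does,
beat the two-block model on bootstrapped inner AVE in both mean and spread.

What the generator does **not** emulate: compositionality, zero inflation
and sequencing-depth artifacts of real 16S data, count overdispersion of
RNA-seq, batch effects, or nonlinear block relationships (a `heavy_tail`
option adds exponentiated, rounded copies for skew, but that is cosmetic).
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated linear-Gaussian conditions — not performance
on any particular real cohort.

## Numerical choices

* Convergence: absolute objective gain per sweep below `tol` ($10^{-8}$ by
  default), `max_iter = 1000`; both configurable. Closed-form comparisons in
  the test-suite tighten `tol` to $10^{-14}$, since loading accuracy scales
  as the square root of the objective tolerance near an optimum.
* Initialization: the first right singular vector of each block —
  deterministic, so searches and bootstraps are exactly reproducible. The
  objective is multimodal in general (notably under `horst` with mixed-sign
  covariances); `n_starts > 1` adds seeded random restarts and keeps the best
  first-component objective. Validation against exhaustive grid search uses 8
  starts.
* The within-block surrogate: the self-edge term $g(\operatorname{var} Y_j)$
  is quadratic in $a_j$, so its linearization in the ascent update carries a
  factor 2, exactly as in power iteration; omitting it breaks monotonicity.
* The $\ell_1$ projection handles a degenerate case explicitly: with exactly
  tied $|v|$ entries (a standardized two-feature block's leading singular
  vector is exactly $(1,1)/\sqrt 2$), the soft-threshold path skips the
  optimum, which weights tied coordinates asymmetrically; an infinitesimal
  ordered perturbation ($10^{-12}$, below any reported precision) restores
  it. At budget $\le 1$ the projection returns a signed coordinate vector,
  first index on ties.
* $M_j$ is factored once per (block, component) by Cholesky; if conditioning
  fails, a jitter of $10^{-12} \cdot \overline{\operatorname{diag}}$ is
  applied once, and a persistent failure raises an error suggesting a larger
  tau.
* Reported loadings follow a deterministic sign convention (largest-magnitude
  entry positive); AVEs are invariant to it.
* Deflation is per block against its own component,
  $X \leftarrow X - y (y^\top X)/(y^\top y)$; AVEs for component $h$ are
  computed on the data deflated by components $1..h-1$, i.e. on the variance
  that component could still explain.
* Monotonicity of the ascent is asserted in tests at $-10^{-10}$ — exact
  non-decrease up to accumulated floating-point error in the objective
  evaluation.

## Validation problem sizes

The shipped validation uses sizes chosen to make every claim checkable by an
independent oracle in seconds to minutes: exhaustive sphere-grid comparisons
on 200 random instances with $p_j = 2$ and 721 angles per block; planted-design
recovery and confounder dominance at $n = 200$, $p_j = 50$, 20 seeds with an
18/20 pass rule to bound flakiness; bootstrap experiments at $B = 100$ per
seed. The acceptance script (`scripts/acceptance.R`) re-runs the main
workflow at these sizes from a single command-line seed.

## Known limitations

Only linear block relationships are modeled; missing values are a hard error
(impute upstream); the search is exhaustive over the declared grid rather
than heuristic, so its cost is $|grid|^{\#\text{free edges}}$ (capped, with
the local fine-stage window as the escape hatch); MCIA and other consensus
methods are not reimplemented — `auc()` accepts any external score vector
for side-by-side comparison; and bootstrap summaries cover AVEs only, not
loading-level confidence intervals.
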