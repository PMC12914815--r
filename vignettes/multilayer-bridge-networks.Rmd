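---
title: "Multilayer partial-correlation networks: models, choices and limits"
author: "mlbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer partial-correlation networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlbridge)
```

## The statistical model

`mlbridge` analyses a cohort of `n` participants measured on `p` variables
that belong to declared layers (for instance four mental-health
questionnaire scores, six cognitive test scores, and eight regional
gray-matter volumes). The working model is a Gaussian graphical model
(GGM): conditional on all other variables, a pair is independent exactly
when the corresponding entry of the precision matrix `K = Σ⁻¹` is zero.
Edges are reported as partial correlations
`w_ij = −K_ij / √(K_ii K_jj)`, so an edge is the association between two
variables with every other variable in the network controlled for.

Because `p` here is moderate (18 in the canonical tri-layer layout) and
edges are noisy, `K` is estimated with an L1 penalty (graphical LASSO) on
the off-diagonal entries, leaving the diagonal unpenalized:

    K̂(λ) = argmax_K  log det K − tr(SK) − λ Σ_{i≠j} |K_ij|

The solver is a block coordinate descent written in C++ (RcppArmadillo):
each column update is itself an L1-penalized regression on the current
working covariance, solved by cyclic coordinate descent. At `λ = 0` and a
well-conditioned `S` the solution equals `S⁻¹`; the test suite checks this
limit and the Karush–Kuhn–Tucker conditions of the penalized objective
directly.

### Model selection

λ is chosen by minimizing the Extended Bayesian Information Criterion over
a log-spaced descending path of 100 penalties from
`λ_max = max_{i<j} |S_ij|` (the empty-graph point) down to `0.01·λ_max`:

    EBIC(λ) = −2 L(K̂) + E log n + 4 E γ log p,
    L = (n/2) (log det K̂ − tr(S K̂) + p)

with `E` the number of nonzero off-diagonal pairs and `γ = 0.5` by default
(γ = 0 reduces to BIC). The additive constant `np/2` in `L` normalizes the
likelihood so the empty independence model (`K = S = I`) scores exactly
zero; since it does not depend on `K`, model selection is unaffected — it
only anchors the reported scores. EBIC ties are resolved toward the larger
penalty, i.e. the sparser model, a parsimony default. An absolute partial
correlation at or below `edge_zero_tol = 1e-6` counts as "no edge"; this
threshold defines the reported edge count and density. Density is banded as
high (≥ 50% of possible edges), medium (30–50%) and low (< 30%).

## The correlation matrix for mixed data

Questionnaire sum-scores are coarse, skewed and integer-valued; volumetric
and timed-test variables are continuous but not always normal. The input
matrix `S` is therefore assembled pair by pair:

* a variable is classified **ordinal** when all its values are integers
  with at most 7 distinct levels, else **continuous**;
* continuous variables are screened for normality with Shapiro–Wilk at
  0.05 (for cohorts beyond the test's n = 5000 limit, a deterministic
  evenly spaced subsample is used — the statistic is order-invariant);
* a pair uses **Spearman** if either member is ordinal or fails the screen,
  **Pearson** otherwise.

A deliberate design choice: ordinal-involving pairs use Spearman rather
than polychoric/polyserial correlations. Rank correlations need no latent
threshold estimation, are robust to monotone transforms, and behave
predictably at the sample sizes involved; polychoric estimation is a
possible future extension. Mixing correlation types can make the assembled
matrix indefinite, so it is projected to the nearest positive semi-definite
correlation matrix by eigenvalue clipping (eigenvalues floored at 1e-8,
reconstruction, rescaling to unit diagonal); matrices that are already PSD
pass through unchanged, and the correction is flagged in the result.

## Residualization

Before estimation each node is replaced by its least-squares residual on
its covariate set: age for every node; total intracranial volume (TIV, mm³)
and scanning site additionally for gray-matter nodes. Site enters by
reference-cell dummy coding (first level alphabetically as reference — the
residuals do not depend on this choice). Rank-deficient designs (for
example a single-site cohort with site in the specification) raise an error
naming the node and covariate rather than silently dropping columns.
Residualization is idempotent and never increases a node's variance; both
properties are asserted in the tests.

## Bridge strength and designation

With communities fixed a priori by layer, a node's bridge strength is the
sum of absolute weights of its interlayer edges. Two conventions had to be
fixed because "80th percentile threshold" does not determine them:

* the threshold is the linear-interpolation percentile
  (`stats::quantile` type 7), the common statistical default;
* designation uses the **strict** inequality, so an all-tied strength
  vector designates nobody rather than everybody.

Under these conventions 10 nodes with distinct strengths always yield
exactly 2 bridge nodes and 18 distinct strengths yield exactly 4 — the
counts a bi-layer (4 + 6) and tri-layer (4 + 6 + 8) analysis of this design
produce.

## Stability: the case-dropping bootstrap

Centrality orderings from regularized networks can be fragile. For each
bootstrap replicate a drop proportion is sampled from a grid (0.05 to 0.75
in steps of 0.05), that fraction of participants is removed without
replacement, the entire estimation chain is re-run on the subsample, and
the Pearson correlation between subsample and full-sample bridge strengths
(over all nodes) is recorded. The CS coefficient is the largest proportion
`q` such that **every** proportion up to `q` retains, with probability at
least 0.95, a correlation of at least 0.70 — requiring the smaller
proportions to pass too prevents non-monotone flukes from inflating CS.
Replicates whose strength vector is constant (typically an empty selected
network) have no defined correlation; they are excluded from the tally, and
a proportion whose tally is empty counts as failing — no evidence of
stability is not stability. Bands: ≥ 0.5 stable, 0.25–0.5 interpret with
caution, < 0.25 uninterpretable; these cutoffs were calibrated on
single-layer psychometric networks and should be read as conventions, not
laws. The default is 2000 replicates; 250 gives a fast approximation that
is still fully deterministic in its seed.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without access
to restricted cohort data. It emulates the statistical structure the
analysis assumes, at the canonical design scale: 457 participants; layers
of 4 (mental health, ordinal), 6 (cognition, continuous) and 8 (GMV,
continuous) nodes; a sparse SPD precision matrix with denser within-layer
(default 50% of pairs) than between-layer structure, between-layer weights
scaled to 60% of within-layer magnitude; age confounding on all nodes
(|β| = 0.25 SD per SD of age, negative on GMV, where volume declines with
age); TIV loading (0.5) and additive site shifts (SD 0.3) on GMV nodes
only. Sites default to 4 categories — enough to exercise multi-site
confounding and dummy expansion while keeping small-cohort designs
(n = 60) well conditioned. Ordinal nodes are produced by cutting the
(age-confounded) latent normal at fixed cutpoints placed at cumulative
probabilities 0.5 … 0.97, yielding right-skewed 0–4 scores like short
questionnaire scales. Positive definiteness is enforced by diagonal
inflation (add δ·I, doubling δ, until the smallest eigenvalue reaches
0.05), which preserves the sampled sparsity pattern exactly.

For recovery experiments the generator can **plant bridge nodes**: all
between-layer edges are concentrated on a designated set, each planted node
receiving 3 interlayer edges whose partners are chosen load-balanced so
that no non-planted node accumulates enough interlayer weight to rival a
planted one (every interlayer edge credits both endpoints, so unbalanced
partner reuse would blur the planted answer). With this construction, the
full pipeline at n = 2000 recovers the planted 4-node bridge set in at
least 8 of 10 seeded replicates with ≥ 90% sign agreement on recovered
planted edges, and the CS coefficient degrades sharply from n = 2000
(stable/caution) to n = 60 (uninterpretable) — the qualitative behaviour a
practitioner should expect from sample-size planning.

What the generator does **not** emulate: the covariance of any real
instrument battery (published marginals do not determine it, so effect
sizes are free design parameters); item-level questionnaire structure;
missing data (the pipeline is complete-case by design); neuroanatomy or
scanner physics. Passing recovery tests therefore demonstrates that the
estimator chain is correct and well calibrated under its own assumptions —
not that any particular empirical dataset satisfies those assumptions.

## Numerical choices, degenerate inputs, problem sizes

* Graphical-lasso convergence: outer tolerance 1e-4 × mean |off-diagonal
  of S|, inner coordinate-descent tolerance one tenth of that; maximum 200
  outer iterations, with a hard error (carrying λ and the iteration count)
  rather than a silent partial fit.
* An all-zero off-diagonal correlation matrix yields a degenerate
  single-point path λ = 0 with a warning.
* Constant variables are refused at classification time: zero variance
  cannot be correlated.
* Cohorts need ≥ 3 participants to correlate, and drop proportions that
  would leave ≤ p + 2 participants are skipped with a warning.
* Seeds: every stochastic routine takes an explicit integer seed, restores
  the caller's RNG state on exit, and is bit-reproducible given the seed.
* Test-suite problem sizes were chosen to keep the full suite around a
  minute on one core: recovery runs use 10 cohorts at n = 2000 with the
  default 100-λ path; bootstrap tests use 250 replicates at n = 2000 and
  100 at n = 60; the large-sample covariance check uses n = 50000 once.

## Known limitations

* Spearman-based input matrices estimate a monotone-association network;
  for strongly non-Gaussian data the partial correlations are approximations
  to the latent GGM quantities a polychoric approach would target.
* EBIC with γ = 0.5 is conservative at small n: at n = 60 and p = 18 the
  selected network is usually empty. That is reported honestly (CS = 0,
  uninterpretable) rather than smoothed over.
* The layer partition is taken as given; no community detection is
  performed, and bridge strength is the only bridge centrality implemented
  (no bridge betweenness/closeness/expected influence).
* Edge weights are conditional associations in a cross-sectional model; no
  causal or longitudinal claims follow from them.
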