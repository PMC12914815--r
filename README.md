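# mlbridge

Multilayer partial-correlation networks and bridge-strength centrality for
brain–behaviour cohort data.

## The problem

Mental-health symptoms, cognitive performance and regional brain structure
are usually analysed in separate statistical frameworks, which makes it hard
to say *which* variables transmit effects between domains. `mlbridge` puts
them in one framework: every variable is a node in a single network whose
nodes are partitioned into declared **layers** (for example
`mental_health`, `cognition` and `gmv` — regional gray-matter volume), and
edges are **regularized partial correlations** estimated with a Gaussian
graphical model. Nodes whose connections reach strongly *across* layers —
**bridge nodes** — are candidate targets for intervention, because change in
them is most likely to propagate between domains.

The package is aimed at researchers analysing cohort studies of this shape
(e.g. traumatic brain injury cohorts combining questionnaires,
neuropsychological tests and volumetry), and at methodologists who want a
fully scriptable, testable implementation with a synthetic-cohort generator
for power and recovery experiments.

## The model

For `p` nodes with correlation matrix `S`, the network is the
partial-correlation matrix implied by the penalized precision estimate
(graphical LASSO, diagonal unpenalized):

```
K̂ = argmax_K  log det K − tr(SK) − λ Σ_{i≠j} |K_ij|,     w_ij = −K̂_ij / √(K̂_ii K̂_jj)
```

λ is selected on a 100-point log-spaced path by the Extended Bayesian
Information Criterion, `EBIC = −2L + E log n + 4 E γ log p` with `γ = 0.5`
(E = number of nonzero edges). Before estimation, each node is residualized
on its covariates (age for all nodes; total intracranial volume and scanning
site for `gmv` nodes), and the correlation matrix is assembled per pair as
Pearson or Spearman depending on variable type and normality.

For a node `i` in layer `ℓ(i)`, **bridge strength** is
`b_i = Σ_{j : ℓ(j) ≠ ℓ(i)} |w_ij|`; nodes strictly above the 80th percentile
of the raw strengths are designated bridge nodes. Stability of the ranking is
quantified by a case-dropping bootstrap: the **CS coefficient** is the
largest fraction of participants that can be dropped while subsample bridge
strengths retain, with 95% probability, a correlation of at least 0.70 with
the full-sample values (CS ≥ 0.5 stable; 0.25–0.5 interpret with caution;
< 0.25 uninterpretable).

## Worked example

Generate a synthetic tri-layer cohort (4 mental-health + 6 cognition +
8 gray-matter-volume nodes, with four planted bridge nodes), residualize it
and fit:

```r
library(mlbridge)

model  <- make_multilayer_precision(
  layer_sizes  = c(4, 6, 8),
  bridge_nodes = c("INSOM", "SOM", "vIMM", "ProcS"),
  seed = 42)
cohort <- sample_cohort(model, n = 457, seed = 43)
cohort <- residualize(cohort)           # age for all; TIV + site for gmv nodes

net <- estimate_network(cohort)
net
#> Regularized partial-correlation network
#>   18 nodes (3 layers), n = 457
#>   edges: 43 / 153 (density 28.1%, low)
#>   selected lambda = 0.0920 (EBIC -847.9, gamma = 0.5)

designate_bridges(bridge_strength(net))
#> Bridge profile (80th percentile threshold = 0.2570)
#>  rank   node strength bridge
#>     1  INSOM   0.4580      *
#>     2  ProcS   0.3772      *
#>     3    SOM   0.3640      *
#>     4   vIMM   0.2971      *
#>     5 vDELAY   0.1970
#>     ...
#> Bridge nodes: INSOM, ProcS, SOM, vIMM

head(rank_interlayer_edges(net), 4)
#>    node_i node_j     weight       layer_i   layer_j
#> 7   INSOM vINTER -0.1892226 mental_health cognition
#> 19  ProcS   AMYG  0.1710792     cognition       gmv
#> 12  ProcS  dmPFC -0.1444242     cognition       gmv
#> 9   INSOM vDELAY -0.1234517 mental_health cognition
```

The fit found 43 of 153 possible edges; the four nodes above the
80th-percentile threshold are exactly the four whose between-layer
connectivity was planted in the generator, and the strongest interlayer
edges attach to them. Stability of the ranking:

```r
stab <- cs_coefficient(case_drop_bootstrap(cohort, n_boot = 250, seed = 1))
stab$cs; stab$band    # e.g. 0.4, "caution" at n = 457
```

The whole chain — residualize → estimate → bridge designation → stability →
serialized artifacts (weights CSV, edge-list TSV, GraphML, layout TSV, JSON
report) — is available as one call, `run_pipeline(pipeline_config(...))`,
or from the shell via the thin wrapper `inst/scripts/mlbridge.R`
(subcommands `simulate`, `preprocess`, `estimate`, `bridge`, `stability`,
`run`).

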