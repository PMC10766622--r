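# curvnet

Geometric network analysis of gene expression on a fixed interactome:
unsupervised sample clustering by optimal mass transport, and multi-scale
dynamic Ollivier-Ricci curvature analysis of cohort-specific weighted gene
networks, including bridge detection, persistence-based gene clustering,
and in-silico edge-perturbation and gene-knockout screens.

It is written for computational biologists who have (i) an interactome as
an edge list of gene symbols, (ii) a normalized expression matrix
(genes × samples), and optionally subtype labels, and who want to ask: which
samples belong together, which edges are communication bottlenecks between
functional modules, and which edges or genes would — if disrupted — most
change the coupling of a monitored gene pair.

## The core quantities

A sample's expression values become node weights of a random walk with
transition probabilities $P_{ij} = w_j / \sum_{k \in N_i} w_k$; its
stationary distribution ($\pi_i \propto w_i \sum_{j \in N_i} w_j$, closed
form) is the sample's network fingerprint, and samples are compared by the
Wasserstein-1 distance between fingerprints:

$$W_1(\mu, \nu) = \min_{\gamma \in \Gamma(\mu,\nu)} \sum_{ij} \gamma_{ij} d_{ij}.$$

For a cohort, edges carry interaction strengths
$\tilde w_{ij} = |\mathrm{cor}(x_i, x_j)|$ (outlier-desensitized), edge
lengths $w_{uv} = 1/\sqrt{\tilde w_{uv}}$, and the shortest-path metric
$d^w$. Ollivier-Ricci curvature compares neighborhood transport cost to
node distance,

$$\kappa(i,j) = 1 - \frac{W_1(\mu_i, \mu_j)}{d_{ij}},$$

and its dynamic version follows heat-diffused Dirac measures
$\eta_i(\tau) = \delta_i e^{-L\tau}$ across scales $\tau$: every edge starts
at $\kappa(0) = 0$ and mixes to $\kappa(\infty) = 1$, but edges bridging
communities lag or dip negative on the way. The first scale with
$\kappa \ge 0.75$ (the critical scale), the trajectory average over it, and
the persistence of component co-membership under curvature-ordered pruning
drive the downstream filtering, gene clustering and intervention rankings.

All Wasserstein distances are solved exactly by a transportation-simplex
routine written in C++ (entropic Sinkhorn fallback for very large
supports).

## Worked example

The bundled generator plants a two-community stochastic block model
(35 nodes, blocks of 17 and 18) joined by a single bridge edge, with unit
interaction strengths so curvature reflects topology alone:

```r
library(curvnet)

fx <- synth_fig1(seed = 7)
fx$wnet
#> weighted gene network: 35 nodes, 160 edges
#>   strength range: [1, 1]
#>   d_max (largest edge distance): 1

traj <- dynamic_curvature(fx$wnet)        # 41-point log scale grid
scales <- critical_scales(traj)           # critical value 0.75
signif(scales$tau_star, 4)
#> [1] 2.258

filt <- critical_filter(fx$wnet, scales)
filt$bridges
#>      [,1]  [,2]
#> [1,] "N00" "N34"
max(filt$membership)
#> [1] 2
```

The one edge with negative curvature at the characteristic scale
τ* ≈ 2.26 is exactly the planted bridge, and removing it recovers the two
planted communities. The bridge also has by far the smallest average
critical curvature, so it is the first edge pruned in gene clustering:

```r
acc <- average_critical_curvature(traj, scales)
round(sort(acc)[1:3], 4)
#> N00|N34 N32|N33 N25|N31
#>  0.0481  0.4337  0.4364

pers <- persistence_scores(fx$wnet, acc)
hierarchical_acc(pers$D, n_clusters = 2)  # gene dendrogram + flat labels
```

Interventions report the net curvature change Δ of monitored pairs; a
knockout far from the pair's neighborhood has exactly zero effect:

```r
ko <- knockout_gene(fx$wnet, "N10", matrix(c("N01", "N03"), ncol = 2))
ko$delta
#> N01|N03
#>       0
```

For sample clustering, `sample_distance_matrix()` + `cluster_samples()`
implement the Wasserstein workflow end to end; `synth_subtypes()` generates
a 60-node, 4-subtype benchmark on which the planted labels are recovered
with adjusted Rand index 1.

## Command line

A thin wrapper (`inst/cli/curvnet`) exposes the workflows as subcommands —
`synth`, `cluster-samples`, `build-weighted`, `dynamic-curvature`,
`hier-acc`, `perturb`, `knockout` — each writing TSV/GraphML/Newick
artifacts plus a JSON manifest of every effective parameter:

```sh
Rscript inst/cli/curvnet synth --preset subtypes --seed 7 --out demo/
Rscript inst/cli/curvnet cluster-samples --network demo/edges.tsv \
    --expression demo/expression.tsv --n-clusters 4 --out demo/clust/
```

## Package layout

- `R/network_io.R` — interactome/expression loading, LCC extraction, gene
  inclusion filter, writers
- `R/wasserstein.R`, `src/transport_simplex.cpp` — exact and entropic
  optimal transport
- `R/markov_clustering.R` — node-weighted walks, stationary distributions,
  sample distances, clustering
- `R/weighted_network.R` — desensitized correlations, strengths, weighted
  hop distances
- `R/curvature.R` — nodal measures, static and dynamic Ollivier-Ricci
  curvature, diffusion operator
- `R/multiscale.R` — critical scales, bridge filter, average critical
  curvature, persistence scores, hierarchical-acc
- `R/intervention.R` — edge perturbation, gene knockout, Δ ranking
- `R/synthetic.R` — SBM and expression generators
- `vignettes/curvnet-methods.Rmd` — model, assumptions, parameter and
  design rationale
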