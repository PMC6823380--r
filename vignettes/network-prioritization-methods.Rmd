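---
title: "Methods: network prioritization of TSG orthologs as longevity candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network prioritization of TSG orthologs as longevity candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longevnet)
```

## The model

`longevnet` formalizes a guilt-by-association screen over a curated
protein-protein interaction (PPI) network. The underlying assumptions are
the standard ones of network biology: (i) interacting proteins tend to share
function, so a gene embedded among aging genes is itself a plausible aging
gene; (ii) topological centrality (degree, betweenness) marks genes whose
perturbation propagates widely; and (iii) curated physical/genetic
interactions, though incomplete, sample the true interactome densely enough
for ranks — not absolute scores — to be meaningful. All downstream decisions
therefore consume *ranks*, never raw centralities.

The pipeline reconstructs two first-neighbour networks from the interaction
table — one around an aging seed list, one around a tumor-suppressor (TSG)
ortholog seed list — merges them, and classifies every merged-network node
into one of eight clusters by the Venn position (aging-only / intersection /
TSG-only) crossed with the seed annotation. The candidate pool is the TSG
connector clusters (4 and 6) minus genes with an already-reported aging
role. Candidates are ordered by

$$\mathrm{Rank}_{\min}(i) = \mathrm{Rank}_{de}(i) + \mathrm{Rank}_{be}(i),$$

the sum of the gene's competition ranks by degree and by betweenness on the
*merged* network. Competition ("min") ranking gives tied scores the smallest
applicable rank, so $\mathrm{Rank}_{\min} = 2$ is attainable only by a gene
that is first on both criteria.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| interaction class filter | none (load physical + genetic) | — | curated tables mix both classes; a `physical`-only switch is provided because analyses are often restricted to physical pairs |
| betweenness variant | unnormalized, fractional, endpoints excluded | — | rank-equivalent to the normalized variant within a connected component; only ranks are consumed |
| hub definition (`top_fraction`) | 0.1 | fraction of nodes | no universal hub definition exists; a degree quantile with inclusive ties is deterministic and scale-free |
| ranking scope | `pool` | — | ranks computed among the compared candidates; a `global` switch ranks over all merged nodes first (see Open choices) |
| RBH e-value cutoff | 1e-5 | e-value | stringent BlastP threshold conventional for orthology screens |
| MCL inflation | 1.5 | — | coarse clustering appropriate for ortholog groups; higher values fragment clusters |
| MCL numerics | prune 1e-5, tol 1e-6, ≤ 100 iterations | — | standard Markov-clustering practice; all configurable |
| enrichment FDR cutoff | 0.5 | q-value | deliberately permissive: the enrichment read-out is descriptive (which processes surround a candidate), not a discovery claim |
| neighbourhood radius | 2 | edges | "secondary connections" of a seed gene |
| Wang decay `w` | 0.8 | per is_a edge | the customary semantic-contribution decay; needs no information-content corpus |
| semantic-similarity threshold | 0.9 | similarity | only near-functional-equivalents of known aging genes pass |

## The synthetic study conditions

The generators in `synth_config()` emulate the real inputs at their
documented scale, and their defaults *are* the study conditions the tests
run under:

* a preferential-attachment network of 3000 genes with `attachment_m = 3`
  (≈ 9000 interactions — the scale of the curated worm interactome), giving
  the hub-heavy degree distribution the hub analyses rely on;
* a global lifespan-reduction-gene (LRG) rate of 0.35%, enriched to 5%
  among hub nodes;
* aging/TSG seed lists of 741 and 464 genes with
  `seed_overlap_fraction = 0.16` and `known_aging_fraction = 0.34`, chosen
  so that the connector pool and its curated subset sit at the documented
  scale (74 connector TSGs, 25 of them with a known aging role, leaving 49
  to rank);
* a layered GO DAG (depth 4, branching 3, occasional double parents) with
  leaf-level annotations at rate 0.08 and planted terms boosted 5× inside a
  target neighbourhood;
* planted ortholog clusters with within-cluster e-values log-uniform on
  [1e-180, 1e-20] and between-cluster background on [1e-4, 1] — above the
  1e-5 cutoff, so recovery is determined by the RBH + MCL machinery, not by
  luck.

**The hub stratum for LRG planting.** A 5% LRG rate among hubs and a 0.35%
global rate cannot coexist if "hubs" means the top 10% of nodes
(0.10 × 0.05 > 0.0035); the requested hub quota would exceed the global LRG
supply, and `gen_universe_and_network()` raises exactly that error. The hub
stratum is therefore a config field, `hub_top_fraction`, defaulting to 0.03:
small enough to be feasible, large enough (≈ 90–160 nodes at the default
scales) for the planted rate to be measurable. Labels are planted by
stratified sampling *after* graph construction, so they cannot alter the
topology.

**What passing tests do and do not show.** The generators produce clean
scale-free topology, uniform annotation noise, and perfectly separated
ortholog clusters. Real interactomes add study bias (well-studied genes have
more recorded interactions), annotation depth that correlates with study
bias, and similarity tables with paralog structure that pure reciprocal best
hits cannot resolve. Tests passing on synthetic data validate the
*machinery* — parsing, graph statistics, set algebra, ranking, the
statistics — not the biological claim that the top-ranked genes of any
particular real dataset modulate lifespan.

## Numerical choices and degenerate inputs

* **Betweenness** is delegated to igraph's Brandes implementation and is
  cross-checked in the test suite against a brute-force enumeration of all
  geodesics on hundreds of small random graphs.
* **Fisher's exact test** is the exact hypergeometric upper tail
  (`phyper`, computed in log space); the suite compares it against explicit
  binomial-coefficient summation for every consistent count grid up to
  N = 40.
* **Disconnected graphs**: all path statistics are per component; the mean
  path length averages only finite distances, and an edgeless network
  reports diameter 0 and `NA` mean path length.
* **MCL**: self-loops get the node's maximum incident weight before column
  normalization; a fully pruned column becomes an absorbing singleton;
  non-convergence within `max_iter` returns the current clustering with a
  warning. Nodes supported by several attractor systems go to the system
  containing the lexicographically smallest attractor.
* **Ties** are broken lexicographically by canonical symbol everywhere a
  total order is needed (candidate report, RBH best-hit selection), making
  every run byte-reproducible.
* **E-value 0** is capped at 1e-200 before the `-log10` edge weight.
* **Synonym chains** are resolved to their fixed point at load; cyclic
  chains and one alias claiming two canonical symbols are load-time errors.
* **Anomalous seed placements** (a TSG seed appearing only in the aging
  network, or vice versa) are not addressed by the eight-cluster scheme
  itself; they are assigned to the corresponding interactor cluster (2 or 7)
  and surfaced as machine-readable anomaly counts.

## Open design choices

* **Ranking scope.** "Rank the remaining candidates" can mean ranks within
  the candidate pool or global ranks restricted to the pool. Both orders
  agree on which scores are better, but competition ranks differ; the
  default is pool-scoped ranks (the comparison is among the candidates),
  and `scope = "global"` is available.
* **Interaction classes.** Both physical and genetic interactions load by
  default, with `class_filter = "physical"` as the restrictive mode;
  neither mode is asserted as canonical.
* **Semantic similarity measure.** Wang's topology-based measure with
  best-match-average aggregation was chosen because it is self-contained —
  no external information-content corpus is needed — and behaves sensibly
  on shallow synthetic DAGs. Resnik/Lin-style IC measures would need an
  annotation corpus and are out of scope.
* **GO slim mapping.** When a slim list is supplied, each term maps to its
  nearest slim ancestor (minimum is_a distance, ties to all). The slim set
  is always an explicit input.
* **Isolated seeds** (seed genes with no recorded interactions) are not
  nodes of any network and therefore belong to no cluster; they are counted
  in the reconstruction report instead.
* **Ortholog cluster shape.** Planted clusters hold one human gene plus one
  or two worm co-orthologs. A pure RBH graph cannot keep larger co-ortholog
  groups connected (best hits form a matching within a species), which is
  why full orthology pipelines add in-paralog edges; that machinery is
  intentionally out of scope, and the generator rejects
  `genes_per_cluster > 3`.

## Problem sizes used by the test suite

Chosen as the package's own balance of statistical power against runtime:
betweenness is verified on 200 random graphs of up to 15 nodes; Fisher
p-values on all count grids up to N = 40; MCL recovery on 50 seeded
configurations of 3–10 clusters; planted-term enrichment on 100 runs over
800-gene universes with 60-gene study sets; the hub-LRG rate on 50 networks
of 5000 genes; pipeline determinism on two identical full runs over a
300-gene fixture. The acceptance script runs the pipeline at the full
default scale (3000 genes).

## Known limitations

* The orthology stage is "OrthoMCL-lite": RBH + MCL on a supplied
  similarity table. It does not run BLAST, normalize between species pairs,
  or distinguish in-paralogs from orthologs within a cluster.
* Evidence codes in annotation files are ignored; annotations are treated
  as boolean.
* Hub-rate estimates on small networks are coarse: with a 0.35% global LRG
  rate, a few-hundred-node network contains only a handful of LRGs, and the
  measured hub fraction is dominated by integer effects.
* The eight-cluster partition is a deterministic reconstruction of a prose
  cluster scheme; the two anomaly classes above are this package's own
  policy, flagged in every report.
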