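---
title: "Methods: network construction, centrality screening and local enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, centrality screening and local enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis this package implements

Multi-herb preparations act through many compounds hitting many protein
targets at once, so their pharmacology is naturally studied as a set of
linked networks rather than a single drug–target pair. `netpharm`
reconstructs the three standard layers of such an analysis from scored
interaction tables:

1. **Compound → compound-target network.** A bipartite graph with one
   edge per retained chemical–protein interaction record.
2. **Herb → target network.** Each herb is linked to the distinct
   targets hit by any of its compounds; targets also present in the
   disease-target list are marked as overlap
   (`compound_disease_target`) nodes. Disease targets never hit by a
   compound do not appear in this layer — it describes what the formula
   reaches, not the disease itself.
3. **Seeded PPI network.** Starting from the union of compound targets
   and disease targets as seeds, the node set is every seed present in
   the protein–protein interaction table plus all of their first
   neighbors, and the edge set is the full induced subgraph on those
   nodes (neighbor–neighbor edges included). The expansion depth is
   exactly one shell: "other proteins" are, by definition, proteins
   with a direct connection to a seed. A star-of-seeds construction
   (dropping neighbor–neighbor edges) would misrepresent the density of
   real PPI neighborhoods and was deliberately not used.

Interaction tables are consumed as exported TSV files
(STITCH/STRING-style: two identifiers and a combined confidence
score). Live database queries are out of scope. Scores printed on the
0–1000 integer scale are auto-detected (any value above 1) and divided
by 1000; filtering is strictly greater-than the threshold, with 0.4
the conventional chemical–protein cutoff and 0.7 the high-confidence
protein–protein cutoff. Duplicate pairs keep the maximum score, which
is deterministic and order-independent; self-loops are removed.
Protein identifiers are uppercased before set operations because
exported tables freely mix protein names and gene symbols.

## Centrality indices and screening

Node importance is evaluated with three indices, computed from scratch
on the unweighted, undirected graph (edge scores are carried as
attributes only):

* **Degree** — the number of distinct neighbors.
* **Betweenness** — for each unordered pair $(s,t)$ a node $v \ne s,t$
  accumulates $\sigma_{st}(v)/\sigma_{st}$, the fraction of shortest
  $s$–$t$ paths through $v$. Computed with Brandes' accumulation
  algorithm (single BFS per source plus reverse-order dependency
  accumulation) and reported **unnormalized**, on the raw pair-count
  scale used by Cytoscape-style analyzers, so published cutoffs such
  as `betweenness >= 270.71207` can be applied directly.
* **Closeness** — component-scaled (Wasserman–Faust): for a node with
  $r$ reachable peers at total distance $D$ in an $n$-node graph,
  $c = \frac{r}{n-1}\cdot\frac{r}{D}$. This lies in $[0,1]$, equals
  the inverse mean distance on connected graphs, penalizes small
  components, and is 0 for isolated nodes. The two conventions
  (raw betweenness, unit-interval closeness) are the only pair under
  which cutoffs like 270.7 and 0.41 are mutually coherent.

`screenNodes()` retains the nodes at or above all three cutoffs
(inclusive `>=` comparisons). Cutoffs are either absolute values or
quantiles of the empirical per-index distributions; quantiles use
lower interpolation (type 1) so that even-sized samples are handled
deterministically and a complete graph — where all indices tie — is
retained in full by a median screen. `twoStageScreen()` repeats the
screen after recomputing all three indices on the stage-1 subnetwork.
Because published analyses rarely state how a fixed-size core (e.g. 40
nodes) was obtained from a screened set, both mechanisms are provided:
a re-thresholded second pass and a top-$k$-by-degree rule with
lexicographic tie-breaks; the pipeline default is top-$k$ ($k = 40$),
the only rule that reproduces a fixed-size core exactly.

Zero-retention screens raise an explicit error rather than returning
an empty network, since every downstream step would otherwise fail
less legibly.

## Over-representation statistics

Enrichment of a query gene set against GMT annotations is tested with
the hypergeometric upper tail: with $N$ background genes, $K$ in the
term, and $n$ annotated query genes of which $k$ are in the term,

$$P = \Pr(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

evaluated in log space for stability, alongside the fold enrichment
$(k/n)/(K/N)$ (undefined and reported as `NA` at $k=0$). An optional
EASE-style conservative variant (replace $k$ by $k-1$) is available
behind a flag and off by default. Terms with $k$ below `minHits`
(default 2) are excluded *before* Benjamini–Hochberg adjustment so the
number of tests $m$ reflects only terms that could plausibly be
reported. The background $N$ defaults to the union of all term members
and can be overridden when a wider universe (e.g. a genome) is
intended; published fold enrichments computed against proprietary
annotation universes are not reproducible under a different background
and should not be compared numerically across engines.

## What the synthetic generator emulates

`generateFixture()` produces a complete input bundle with known ground
truth, sized like a small formula study: 8 herbs with 5–12 compounds
each, 120 compound-target symbols (each hit by at least one compound,
via round-robin assignment plus random extras), 60 disease targets
sharing 8 symbols with the compound targets, and 30 annotation terms.
The PPI layer is grown by preferential attachment (600 nodes, 3 edges
per new node, attachment probability proportional to degree + 1),
giving the hub-dominated degree distribution that three-index
screening exploits and a closed-form edge count $m(n-m) = 1791$. The
ten highest-degree nodes are planted as compound-target hubs; the
remaining target symbols are scattered over low-degree nodes. One
annotation term is planted so that 80% of its 20 members come from the
compound∪disease target set — specifically the highest-degree target
symbols, i.e. exactly the symbols a centrality screen is designed to
keep — and the rest of the terms are uniform draws.

Scores are drawn on a 1/1000 grid (chemical–protein on [0.2, 1.0],
PPI on [0.5, 1.0]) so that both confidence cutoffs discard a
realistic fraction of records and the 0–1000 integer file dialect
round-trips the in-memory fixture byte-exactly. All randomness flows
from the single config seed, and the generator saves and restores the
caller's RNG state.

What the fixture does **not** emulate: real chemistry (compound ids
are synthetic tokens), pharmacophore-score thresholds upstream of the
target tables, annotation structure with term–term overlap hierarchies
(no GO graph), and the literature-curated compound lists of a real
formula. Passing tests therefore demonstrate algorithmic correctness
and pipeline integrity, not biological validity of any particular
database export.

## Numerical and design choices

* Threshold comparisons on scores are **strict** (`>`); screening
  comparisons on centralities are **inclusive** (`>=`). Both follow
  the conventions in which such cutoffs are customarily printed.
* Betweenness/closeness correctness is verified against exhaustive
  shortest-path enumeration oracles (recursive simple-path search with
  Floyd–Warshall distances) on hundreds of random connected graphs of
  up to 12 nodes, to within $10^{-9}$; the hypergeometric tail is
  verified against exact binomial-coefficient enumeration for every
  configuration with $N \le 25$ to within $10^{-12}$ relative error.
* Disconnected inputs are legal everywhere; closeness uses the
  component scaling above instead of erroring.
* All writers emit sorted nodes, edges and rows with fixed numeric
  formatting, so identical inputs yield byte-identical artifacts; the
  run manifest records md5 checksums and per-stage
  `input = output + dropped` record counts, making every silent filter
  visible.
* SIF cannot carry node attributes, so the SIF writer emits a sidecar
  node-attribute TSV; all three formats (SIF, GraphML, TSV) round-trip
  nodes, edges and roles exactly.
* Unmapped identifiers are dropped by default (with a logged count),
  matching the usual practice of deleting targets that cannot be
  related to a compound; `keep_raw` is available when downstream
  joining is preferred.

The test suite and the acceptance script run these analyses at the
default generator sizes (600-node PPI layer, 1,000 null-calibration
queries against 25 terms), which keeps the full suite in the
tens-of-seconds range on a single CPU while leaving every property
with comfortable statistical margin.

## Known limitations

* Enrichment treats terms independently: no ancestor propagation on
  the GO graph, no pathway topology, no gene-identifier translation.
* Only unweighted shortest-path centralities are provided; eigenvector,
  PageRank and stress centralities, and score-weighted paths, are out
  of scope.
* The quantile screen's lower-interpolation median is one of several
  defensible conventions; results on small networks can differ by one
  rank from interpolating definitions.
* Published node/edge counts and fold enrichments from any specific
  database snapshot depend on that snapshot's contents and the
  annotation engine's internal background; they cannot be reproduced
  from synthetic conditions and are not targets of the test suite.

## A worked run

```{r pipeline, eval = FALSE}
fx <- generateFixture(fixtureConfig(seed = 42))
files <- fixtureToFiles(fx, "fixture")
cfg <- validateConfig(list(
  herb_table = files[["herb_table"]],
  chem_table = files[["chem_table"]],
  ppi_table = files[["ppi_table"]],
  disease_targets = files[["disease_targets"]],
  gene_sets = files[["gene_sets"]],
  id_mapping = files[["id_mapping"]],
  out_dir = "run"))
res <- runPipeline(cfg)
networkSummary(res$networks$ppi)
head(res$enrichment$herb_targets)
```

The run directory then contains the three networks (SIF plus node
attributes), both centrality tables, the screened subnetwork and core,
two enrichment tables and the manifest.
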