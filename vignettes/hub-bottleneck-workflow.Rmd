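---
title: "From differential 2-DE spots to validated hub-bottleneck biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential 2-DE spots to validated hub-bottleneck biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppihub)
```

## The problem this package addresses

Comparative plasma proteomics by two-dimensional gel electrophoresis
(2-DE) produces a table of spot intensities across replicate gels and
conditions — for instance, patients who did and did not respond to
first-line pharmacotherapy for chronic immune thrombocytopenia (ITP).
Turning that table into a short, defensible list of candidate predictive
biomarkers requires a chain of standard but detail-laden steps:
differential-spot screening, protein-protein interaction (PPI) network
construction, topological prioritization, dense-module detection,
annotation enrichment, and an independent statistical validation of the
survivors in a third cohort. Each step has conventional cutoffs and each
is easy to get subtly wrong; `ppihub` implements the whole chain as
small, individually tested operations, plus a synthetic-data module that
generates every input with known ground truth so that the pipeline can
be exercised and audited entirely offline.

## The model and its stages

### 1. Differential spots

Each spot is screened by a classical one-way fixed-effects ANOVA across
condition groups and by its fold change. Densitometric noise is
multiplicative, so `spot_anova()` log-transforms intensities by default
(a raw-scale switch exists); `spot_stats()` first rescales each gel
(group × replicate) to a common total intensity so loading differences
do not masquerade as regulation. The retention rule in `filter_spots()`
is the conventional one: fold change ≥ 1.5 (non-strict) **and** p < 0.05
(strict). Fold change is always reported as a ratio ≥ 1 plus the
direction of the comparison group relative to the reference. Spots are
*not* merged by protein before filtering — distinct spots of one protein
(charge/size variants) are genuinely distinct observations — and
`dedupe_proteins()` collapses them only afterwards, in first-seen order.

### 2. Network construction

`read_network()` ingests TSV edge lists and the Cytoscape SIF dialect,
drops self-loops, collapses duplicate and reversed edges, and maps
identifiers through a user-supplied two-column table (no live database
lookups; e.g. UniProt entry names TRFE/VTDB to gene symbols TF/GC).
Graphs are undirected and unweighted; an optional score floor can filter
a TSV `score` column, but by default every edge is kept since typical
source exports have already been curated. `merge_networks()` is a plain
union of nodes, edges, and per-edge provenance tags — commutative,
associative, idempotent — which is exactly what "merging an HPRD network
with a STRING network" means operationally.

`scale_free_fit()` answers the "is this network scale-free" question the
way network-analysis tools conventionally do: a least-squares line on
(log k, log P(k)) over occupied degree bins, reporting the slope and the
Pearson correlation of the fitted points (its magnitude is the commonly
quoted "correlation rate"). Published correlation values cannot be
reproduced here because they depend on the original interaction-database
snapshots; the statistic itself is tested on exact power laws and on
preferential-attachment graphs.

### 3. Hub-bottleneck selection

Two topological criteria are intersected:

* **Hubs** — degree ≥ mean + 2·SD of the network's degree distribution
  (`hub_threshold()`, `select_hubs()`). The sample (n−1) SD is the
  default; the population variant is a switch, and an explicit integer
  override (a published realized cutoff such as 14) is accepted for
  replication runs.
* **Bottlenecks** — the top 10% of nodes by shortest-path betweenness
  centrality. `betweenness_centrality()` is a Brandes-style accumulation
  written in-package and verified against an exhaustive all-shortest-path
  enumeration oracle on dozens of small random graphs. Normalization is
  per connected component (divide by (n_c−1)(n_c−2)/2), matching the
  convention of the network-analysis tools that produce published
  centrality tables; components smaller than 3 get 0.

The top-10% count is `ceiling(fraction × N)` — with N = 110 this yields
11, matching the published table — and ties at the cut are broken by
higher degree, then lexicographic label, so selections are
deterministic. `consensus_candidates()` intersects hub-bottleneck sets
across networks and restricts to the differentially expressed query
proteins, since only input proteins can be biomarkers of the assay that
found them.

### 4. Module detection (MCODE-style)

`mcode_vertex_weights()` implements the published weighting: the weight
of a vertex is the highest k-core number of its closed neighborhood
times the density of that highest k-core — high for vertices embedded
in dense local neighborhoods, low for mere spokes of a star.
`mcode_find_complexes()` grows complexes greedily from the
highest-weight unvisited seed, admitting neighbors within
`node_score_cutoff` (default 0.2) of the seed weight, then applies the
2-core "haircut" and discards complexes with no 2-core; "fluff" is
available but off by default, mirroring the plugin defaults. Cluster
score is simple-graph density × size (`score_cluster()`), and
`filter_clusters()` applies the conventional strictly-greater-than-4
screen. Seed and tie order are fixed (weight, then degree, then label),
so results are reproducible; the original plugin's internal order is
unspecified, so node-level agreement with it is not promised —
planted-clique recovery and hand-traced fixtures are the tests instead.

### 5. Enrichment

`enrich()` is a local, auditable replacement for web-service
over-representation analysis: the one-sided hypergeometric tail
(Fisher), or by default the EASE score — the same tail with the overlap
reduced by one — because that is what DAVID-style servers report as
"p value". The background is the union of the collection's genes, the
only universe a GMT file can attest to; overlaps below 2 are suppressed,
matching the behavior of those servers. Published enrichment p-values
are deliberately *not* targets: they depend on the annotation-database
release, which is not shipped. Benjamini–Hochberg adjustment is offered
but off by default since the conventional screen is unadjusted p < 0.05.

### 6. Group validation

`anova_from_summary()` reconstructs the exact one-way ANOVA from
per-group (mean, SD, n) — pooled within-group mean square
Σ(nᵢ−1)sᵢ²/Σ(nᵢ−1) — so published summary tables are fully analyzable
without raw data; it agrees with `anova_from_raw()` to 1e−9 when
summaries are exact. `tukey_hsd()` forms all pairwise simultaneous
intervals `diff ± q(1−α, k, df) · sqrt(MSE/2 · (1/nᵢ + 1/nⱼ))`
(Tukey–Kramer unequal-n form) with studentized-range quantiles from R's
`qtukey`/`ptukey`; star categories are the smallest conventional level
at which zero leaves the interval.

A numerical honesty note: the published 95% CI half-widths for the ITP
example imply q ≈ 3.8 rather than the tabulated q(0.05, 3, 23) ≈ 3.54;
the origin (software version, df convention, or rounding) cannot be
recovered from the printed numbers. The CI *midpoints* equal the printed
mean differences to ≤ 5×10⁻⁴, so midpoints and the qualitative
significance pattern are what the acceptance tests assert; half-widths
are checked only structurally (containment, symmetry, monotone widening
as α decreases).

## The synthetic world

The generators produce data with exactly the structure the analysis
assumes — and nothing more:

* `gen_spot_table()` — log-normal intensities (multiplicative gel noise;
  the source study states no noise model, so the choice is ours) with a
  mean-preserving coefficient of variation, two conditions × n
  replicates, planted fold changes of known direction. Under a null
  table (planted FC = 1) the p-value screen passes at the nominal α
  within binomial error; that is what a green type-I test establishes,
  not anything about real gel artifacts (spot overlap, streaking,
  misalignment), which are *not* modeled.
* `gen_ppi_network()` — preferential attachment (chosen because the
  analyzed networks are asserted to be scale-free; the mechanism is our
  choice) plus an optional planted clique wired over randomly chosen
  existing nodes. Cliques of size 1–2 are rejected: a "module" below a
  triangle is meaningless.
* `gen_annotations()` — uniform random gene sets plus one term exactly
  equal to a designated gene set, so the minimum-p term is known.
* `gen_plasma_groups()` — Gaussian per-group draws truncated at zero by
  redrawing (concentrations are non-negative; redrawing keeps means
  nearly unbiased at realistic CVs, clipping would not).

All generators take an explicit seed, restore the caller's RNG state,
and are byte-reproducible. Defaults (e.g. triplicate gels, group sizes
8/8/10 in examples) mirror the conditions of the motivating study; spot
noise levels are free parameters since no variance information was
published for them.

One measured caveat: at the published TRFE group parameters
(7.75 ± 2.94 vs 3.84 ± 1.11 vs 10.25 ± 2.67, n = 8/8/10), the
respondent-vs-nonrespondent Tukey contrast has true power ≈ 0.79 — a
property of that design, which a 2000-replicate simulation confirms —
so the suite asserts the simulated detection rate against that computed
value, not against an aspirational 95%.

## Numerical and policy choices

* Boundary conventions: FC ≥ cutoff (non-strict), p < α (strict),
  hub degree ≥ threshold, module score > cutoff (strict). All switchable
  where a published analysis might have used the other convention.
* Bottleneck count `ceiling(0.10 × N)`; ties broken by degree then
  label.
* Betweenness normalization per component; graphs with < 3 nodes give
  all zeros by convention.
* The pipeline config is JSON (not YAML) because the supported R stack
  has no YAML parser; the content is the same flat declarative record,
  and `write_config()`/`read_config()` round-trip it.
* Reports are timestamp-free so identical config + seed gives
  byte-identical JSON.

## Known limitations

* No gel image processing, mass-spectrum handling, or identification
  scoring — spot tables and protein identifications are inputs.
* No live HPRD/STRING/DAVID clients; interaction sources and annotation
  collections are files you supply, so published network sizes and
  enrichment p-values that depend on database snapshots are out of
  reach by design.
* MCODE here is a faithful re-implementation of the published
  description, not a bit-for-bit port of the Java plugin.
* Betweenness is exact and O(V·E); fine for the hundreds-of-nodes
  networks this workflow sees, not tuned for graphs orders of magnitude
  larger.
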