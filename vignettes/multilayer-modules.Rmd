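---
title: "Multilayer module detection and confidence scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer module detection and confidence scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimodules)
```

## The multilayer model

A protein interactome is rarely one dataset. Literature-curated
interactions, orthology-transferred predictions and high-throughput
two-hybrid screens measure overlapping but distinct slices of the true
interactome, each with its own coverage and error profile. This package
treats these *interactome classes* as first-class objects
(`ppi_network` with a class label; `integrate_networks` forms their
union) and asks two questions: which dense modules does each class
support, and how much independent biological evidence — ontology
co-annotation, tissue co-expression, reference catalogs — does each
module accumulate?

The pipeline has five stages: simulate (or load) the inputs, detect
modules, annotate them with evidence variables, score them into
confidence tiers, and validate them against complex and pathway
catalogs. Each stage is an exported function; `run_pipeline()`
orchestrates them from a single seeded configuration.

## Detection: four resolutions of one network

Two deterministic, clique-anchored detectors bracket the resolution
spectrum:

- **Clique percolation** (`detect_cpm`). A k-clique community is the
  node union of a maximal set of k-cliques chained through shared
  (k−1)-subsets. Communities may overlap, which is biologically right:
  interface proteins sit in several complexes. We realize percolation
  through maximal cliques: every k-clique lies in a maximal clique of
  size ≥ k, and lifting preserves percolation adjacency, so components
  of the maximal-clique overlap graph (overlap ≥ k−1) give exactly the
  k-clique communities. The tests verify this equivalence against a
  literal brute-force enumeration of all k-cliques on a corpus of small
  random graphs. k = 2 is excluded (edges are not informative
  communities); k = 4 is the default working resolution.
- **Core mining** (`detect_mcode`). Vertices are weighted by the core
  number of their closed-neighborhood graph multiplied by the density
  of that neighborhood's highest-order core; modules grow breadth-first
  from the highest-weight unvisited seed, admitting neighbors whose
  weight is within `mcode_node_score_cutoff` (default 0.2) of the seed,
  to depth `mcode_max_depth` (default 100). The *haircut* step (default
  on) reduces each module to its 2-core, so every member keeps ≥ 2
  intra-module partners; *fluff* (default off) optionally adds dense
  boundary neighbors. The reported score is interactions per protein;
  `k_param` is the largest c with all intra-module degrees ≥ c.

Two partition methods stand between these extremes:

- **Greedy modularity maximization** (`detect_greedy`) merges from
  singletons, always joining the pair with the largest modularity gain.
- **Walktrap** (`detect_walktrap`) agglomerates by the t-step
  random-walk distance (default `steps = 4`, the algorithm's standard
  value).

Both delegate the agglomeration to igraph's reference implementations
and then scan *every* cut of the returned merge tree, selecting the
partition that maximizes our own `modularity_q`. The explicit scan
matters: the dendrogram cut igraph's `membership()` picks can miss the
true maximum by floating-point tolerance (on a 5-clique it returns a
two-block cut with Q = −0.08 rather than the trivial partition with
Q = 0). Scanning restores the defining contract — the partition of
maximal Q along the merge path — and makes the optimality tests against
exhaustive search over all set partitions (graphs ≤ 8 nodes) exact.

`modularity_q` computes the mixing matrix E with integer edge counts
and a single final division, so the identities Q(trivial partition) = 0
and ΣE = 1 hold exactly, not merely to rounding. Q = Tr E − Σᵢ(ΣⱼE)²
with e_ii = lᵢ/m and row sums dᵢ/2m, the standard degree-preserving
null convention.

Community selection across clique sizes
(`select_cfinder_communities`) follows a two-step reduction: forward,
for each k ≥ 4 keep at most `representative_subset_size` (default 5)
communities nearest the median size, discarding any above
`max_community_size` (default 200, the "too big clusters" guard);
backward, from the largest k down, keep a community only if it is not a
subset of one already selected. Communities at k = 3 are never
considered: at that resolution the giant component dominates and adds
no selective information.

## Annotation variables and confidence tiers

Seven quantities summarize a module (`module_variables`): n; n.ex (how
many members the expression compendium covers); ex.mean (pooled mean
expression over members × tissues); cor.mean (mean pairwise Spearman
correlation over all expressed member pairs, midranks for ties, pairs
with flat profiles dropped, `NA` below 2 expressed members); and
mf/bp/cc.mean, the mean co-annotation over *interacting* member pairs
per GO namespace.

Co-annotation of two proteins is the Jaccard similarity of their
ancestor graphs: the assigned terms of the namespace plus all is_a
ancestors, with the namespace root excluded — the root is shared by
every annotated protein and would floor every similarity, compressing
the informative range. Only is_a edges are traversed. Pairs lacking
annotation contribute nothing (they are dropped, not scored 0):
absence of annotation is missing evidence, not evidence of absence.
Two populations are deliberately different: co-annotation averages
over network edges inside the module (it measures agreement of
*interactions*), while cor.mean averages over all member pairs
(co-expression of a complex is a property of the whole set).

Confidence tiers (`assign_confidence`, thresholds inclusive,
default 0.5): **HIGH** requires all three GO means; **MEDIUM** requires
bp and cc plus a measurable cor.mean ≥ 0.5; **LOW** requires bp and cc
only. A module whose cor.mean cannot be measured can still be HIGH or
LOW but never MEDIUM — it cannot pass a criterion that cannot be
evaluated. The packaged fixture of printed annotation values (24 tiered
modules, 86 residual modules) is reproduced with zero mismatches, which
pins the inclusive-≥ convention: one fixture row sits exactly at
bp = 0.5 and is tiered Low.

`classify_permanence` reuses the 0.5 correlation threshold to split
permanent (constitutive, co-expressed) from transient
(condition-specific) modules; `crosstalk_score` reports the boundary
share of incident degree mass, 0 for a self-contained component and 1
for a module with no internal edge. Enrichment (`enrich`) is the
upper-tail hypergeometric test against any gene-set catalog with
Benjamini–Hochberg correction within the module's tested sets — the
paperwork behind calibration ranking (`calibration_rank`).

## Validation

`match_frequency` is |M∩C|/|C|; a complex is well matched at ≥ 0.5.
`module_pr` gives per-module tp/fp/fn precision and recall;
printed-value comparisons round half away from zero (0.875 → 0.88,
`round_half_up`). `class_pr` aggregates per class: every module is
assigned its best-frequency complex (ties: larger intersection, then
name), MM counts modules at or above the threshold, KC counts
complexes detected at nonzero frequency (configurable to the whole
catalog), and MC sums each module's mean qualifying frequency;
P′ = MM/PM, R′ = MC/KC. `protein_pr` pools member and catalog unions.
`fit_power_law` implements the discrete maximum-likelihood recipe with
Kolmogorov–Smirnov selection of x_min (Hurwitz zeta via partial sum
plus Euler–Maclaurin tail); the generator oracle `rpower_law` recovers
α = 2.5 within 0.01–0.02 median absolute error at n = 10⁴.

## What the synthetic generator emulates — and what it does not

`plant_spec()` encodes the study conditions: 8 planted modules of 6–12
proteins at intra-density 0.9 over a 300-node background of density
0.005; class edge retention 0.9 (LIT), 0.7 (ORTHO), 0.4 (HTP) with
spurious-edge rates 0.05/0.10/0.30 of the true edge count (curation
keeps most true edges and adds little noise; two-hybrid screens lose
most and add much); the integrated class is the union. Half the plants
are permanent. The annotation layer gives each plant a home leaf in
each of three complete ternary is_a trees of depth 4 (81 leaves per
namespace — deep enough that random leaf pairs share almost nothing
above the excluded root); members are annotated to it with probability
0.9, to a random leaf with 0.05, otherwise left unannotated, and
background proteins draw uniform leaves. Expression profiles over 50
tissues follow √ρ·latent + √(1−ρ)·noise with ρ = 0.8 (permanent) vs
0.1 (transient), shifted by +8 so pooled means land in the 8–12 range
of single-platform log-scale compendia (cosmetic realism only).
Catalogs are plants with 10% member dropout and 10% contamination;
pathways are unions of 1–3 plants.

Plants are sampled **disjointly**. A protein has exactly one expression
profile, so a protein shared by a permanent and a transient plant
cannot co-express perfectly with both; early experiments with shared
members showed within-plant correlation means collapsing toward 0.4
for 11-member permanent plants, destroying the very contrast the
generator exists to create. Disjoint plants keep the generator's
guarantees exact (ρ = 1 gives within-plant correlation exactly 1) while
the *detector* side still produces overlapping modules freely.
Deliberately not modeled: study bias toward hubs, curation error
modes, orthology-transfer mechanics, evidence-weighted edges. Passing
tests on this generator therefore demonstrate correctness of the
machinery and recoverability under controlled class biases — not
performance on real interactome data, whose biases are richer.

## Numerical choices and degenerate inputs

- Node iteration, seeding and module ordinals are deterministically
  ordered (sorted nodes; rank score descending, then lexicographic
  members), so module ids are reproducible run to run.
- All generators restore the caller's RNG state and are pure functions
  of (spec, seed); the pipeline writes byte-identical report bundles
  for identical configurations.
- Edgeless networks are rejected by the partition methods; graphs
  without a k-clique yield an empty (not an error) CPM result;
  singletons never form modules; a degenerate all-equal size sample is
  rejected by the power-law fitter.
- Unmeasurable quantities propagate as `NA` and are dropped from
  means; ratios with zero denominators are reported `NA` rather than
  0.

## Problem sizes in the test suite

The suite exercises: oracle equivalence of clique percolation on ~60
random graphs of 4–10 nodes (brute-force k-clique enumeration);
exhaustive modularity optimality on 8 structured graphs of ≤ 8 nodes
(all set partitions, Bell(8) = 4140); hypergeometric agreement with
explicit enumeration for universes ≤ 15; power-law recovery at n = 10⁴
over 20 seeds; and the full synthetic study at its default 300-node,
8-plant conditions. These sizes make the whole suite run in well under
a minute while keeping every oracle literal rather than approximate.

## Known limitations

- Real OBO ontologies use many relationship types; only is_a is
  traversed, by design.
- `KC` counts detected complexes by default; against very incomplete
  catalogs the whole-catalog option gives a more conservative recall′.
- The MEDIUM tier requires a measurable correlation mean; modules of
  mostly unprofiled proteins can only reach HIGH or LOW.
- Class-level precision′ on a handful of modules is granular;
  comparisons between classes are only meaningful over the pooled
  module population of a full pipeline run.
```{r session}
sessionInfo()
```
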