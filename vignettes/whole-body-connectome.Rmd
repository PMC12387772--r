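---
title: "Deriving and analysing a whole-body larval connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analysing a whole-body larval connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvanet)
```

## The data model

A whole-body EM reconstruction of a small segmented larva yields three
tables. *Skeletons* are rooted trees of 3D nodes in nanometres, one per
cell; complete cells are rooted on a soma-tagged node, while pieces that
could not be attached to any cell body are soma-less *fragments*.
*Connectors* are monadic chemical synapses: one presynaptic
(skeleton, node) endpoint onto one postsynaptic (skeleton, node) endpoint.
*Annotations* give each cell a unique name, a class (sensory neuron,
interneuron, motoneuron, effector, other non-neuronal, or fragment), an
optional cell-type label, a body region (head, segments 0–3, pygidium) and
a body side. Two conventions matter throughout:

* cell identity is the unique `cell_name`; skeleton ids are file-level
  plumbing;
* region and side membership come from annotations, never from
  coordinates, so no axis convention is imposed on the data.

`read_dataset()`/`write_dataset()` exchange this model as SWC plus two
TSVs and round-trip exactly; `validate_dataset()` reports (never throws)
violations of the structural invariants — one root per skeleton, acyclic
parenthood, resolvable connector endpoints, unique names, untyped
fragments — so broken exports can be audited.

## Connectome derivation

`build_connectome()` applies three rules, in order:

1. every synapse has weight one, and parallel synapses between the same
   ordered cell pair are summed into one directed edge;
2. every node whose total incident synapse count (incoming plus outgoing)
   is below `min_synapses` (default 3) is removed in a **single pass** —
   counts are taken on the full aggregated graph, then all low nodes are
   removed at once, with no cascade;
3. the graph is restricted to its largest *weakly* connected component.
   Weak connectivity is the right notion because the graph is strongly
   feed-forward (effectors never send synapses), so strong components
   would be degenerate.

Two details are worth stating precisely. First, ties in rule 3 are broken
by larger edge count, then by the lexicographically smallest member name,
making the selection deterministic; this matters for exactly
mirror-symmetric graphs, where a left-only and a right-only component can
tie. Second, the single-pass filter is *not* idempotent in general:
removing a weak node removes its edges, which can leave a surviving
neighbour below threshold on a re-derivation. We follow the single-pass
reading because the stated derivation protocol is one removal step
followed by component selection; an iterative, cascading variant
(`iterative = TRUE`) is exposed for users who want a fixed point, and the
test suite checks idempotence exactly where the semantics guarantee it.

Fragments are retained as graph nodes; the type-level graph
(`group_by_type()`) excludes them, sums synapse counts between cell types,
keeps within-type synapses as self-loops, and attaches
`display_weight = sqrt(weight)` for plotting only — every analysis uses
raw summed counts.

## Network analysis choices

**Leiden modules.** The directed graph is collapsed to an undirected one
(reciprocal weights summed) and partitioned with the Leiden algorithm
under the modularity objective. The resolution parameter (default 1.0,
classic modularity) controls how many modules are found, and the number
recovered genuinely varies with it; `resolution_sweep()` makes that
dependence visible rather than hiding it. Runs are seeded and bit-for-bit
reproducible.

**Centralities.** Weighted degree is the sum of incoming and outgoing
synapse counts. PageRank uses the canonical damping 0.85 on
synapse-weighted out-edges, with dangling nodes teleporting uniformly.
Betweenness is computed on the *unweighted* directed graph: synapse counts
are affinities, and treating them as distances would invert their meaning;
an inverse-weight-distance option exists for comparison. Authority is the
HITS authority score on the weighted adjacency. Ranks use the min-rank
convention so ties share the best rank.

**Flow tables.** `flow_table()` sums synapses between user-defined groups,
drops grouped connections below `min_weight` (default 11, i.e. only
connections with more than 10 synapses are kept) and flags connections
running against a stated group order. The pre-threshold totals are kept as
an attribute so flow is conserved and auditable.

## Left-right stereotypy

`pair_homologs()` pairs cell types with exactly one left and one right
member; midline, asymmetric and unbalanced types are listed with a reason
rather than silently dropped. For paired types, `side_matrices()` builds
two matrices over the same ordered type pairs: the left entry counts
synapses from the *left* member of the presynaptic type onto members of
the postsynaptic type on either side, the right entry mirror-wise.
`lr_correlation()` is the Pearson correlation of the flattened matrices,
zeros included, on raw counts — the most reproducible reading, since no
transform or support restriction is stated for this statistic in the
field; a square-root option is provided. A constant matrix makes the
correlation undefined and is reported as an error, not a number.
Morphological stereotypy uses `sholl_similarity()`: Sholl profiles of the
two skeletons on a shared radius grid, correlated. The grid stays strictly
inside the larger arbor extent so that trailing all-zero radii cannot
manufacture correlation between otherwise constant profiles.

## Pathways and segmental censuses

`classify_sensory_paths()` runs unweighted breadth-first search from every
sensory neuron to the effector set; a hop is one edge, so a direct synapse
onto an effector is 1 hop. Category labels are deliberately multi-label —
a sensory neuron with a direct effector contact may also be premotor — and
neurons with no directed path to any effector are an explicit output, not
an error. The search runs on the cell-level graph or on the type-level
graph; both are exposed because grouped and ungrouped analyses answer
slightly different questions. `segment_matrix()` and `head_trunk_census()`
are independent tallies of the same underlying quantity (synapses between
soma regions), and the test suite cross-checks them against each other.

## Morphometry

* **Cable length** sums Euclidean parent-child segment lengths in microns
  after a single-pass removal of terminal twigs shorter than
  `prune_below` = 2 µm (a twig is the tip-to-branch-point path; an
  unbranched skeleton has no twigs and is never pruned away). A
  single-node skeleton has length 0, not an error.
* **Smoothing** (`smooth_skeleton()`, σ = 6000 nm) replaces node
  coordinates by a Gaussian-weighted *local linear* regression against arc
  length within each unbranched segment, anchoring root, branch points and
  tips. Local linear (rather than a plain kernel average) is used because
  it reproduces straight segments exactly instead of contracting them near
  segment ends. Smoothing is for rendering and Sholl profiles only, never
  for synapse assignment or cable length.
* **Sholl profiles** count parent-child segments whose endpoint distances
  to the root straddle each sphere (nearer endpoint ≤ r, farther > r), so
  the crossing count near r → 0 equals the root's degree and is zero
  beyond the arbor extent. Sholl runs on smoothed, unpruned skeletons;
  cable length on unsmoothed, pruned ones — exactly that split.
* **Radial synapse density** histograms Euclidean soma-to-synapse-node
  distances in fixed 1000 nm bins ("radial" is read as distance from the
  soma, not geodesic along the arbor); class-level means are taken on a
  shared grid across cells.
* **Polarity** counts each cell's presynaptic and postsynaptic sites.
  Because synapses are monadic, total pre = total post = the connector
  count on every dataset — a conservation law the tests assert everywhere.

## The synthetic larva

The generator exists so that every stage above can be tested against
ground truth without the EM database. It emulates the *structure* of the
larva, not its numbers: six body regions; most cell types with exactly two
cells, one per side; classes SN/IN/MN/effector plus soma-less fragments;
monadic synapses biased in the SN → IN → MN → effector direction
(backward class transitions are damped by `class_order_bias`, default 5);
planted type-level connectivity modules; and mirror-symmetric left-right
wiring. Defaults were fixed once to give realistic study conditions:

* connection probabilities `p_within = 0.2`, `p_between = 0.02` on
  directed type pairs, with per-edge synapse counts
  `1 + NegBin(mu = 1.5, size = 1.5)` (mean 2.5, overdispersed, ≥ 1),
  calibrated so per-neuron median synapse counts land near 8 presynaptic
  and 6 postsynaptic sites, the published medians for this larva;
* `p_contralateral = 0.2`: a fifth of edges target the contralateral
  homolog, joining the two body halves into one connected graph (flips are
  mirrored exactly, so noise-free wiring stays perfectly symmetric);
* `fragment_fraction = 0.15` fragments, receiving and sending a small
  Poisson number of synapses, so filter and report code meet realistic
  nuisance structure.

Mirroring acts on the type-level edge list: the left-side list is sampled,
copied to the right side, and a `mirror_noise` fraction ε of the
right-side copies is resampled (new target type, weight and laterality).
At ε = 0 the left and right type matrices are identical by construction,
so `lr_correlation` is exactly 1; as ε grows the expected correlation
falls monotonically, which the tests verify as a trend over seeds. One
global seed drives everything; the three stages derive child seeds as
`(seed × 7919 + stage) mod (2³¹ − 1)` so each stage is independently
reproducible.

Two things the generator deliberately does **not** emulate: realistic
neurite geometry (arbors are a soma-rooted backbone with Poisson twigs)
and any developmental or physiological dynamics. Passing tests therefore
demonstrate correctness of the *analyses* under known ground truth, not
biological realism of the simulated larva.

A note on module-recovery testing: under the mirror construction, a
planted module's left and right halves are themselves denser internally
than across the midline, so cell-level community detection legitimately
splits them — recovering the planted *type* modules is not the right
target there. Module recovery is therefore benchmarked on
`planted_partition_graph()`, where connection probabilities act directly
on cell pairs (3 blocks of 20 cells, 0.4 within / 0.01 between by
default) and the planted blocks are the only structure. Leiden at
resolution 1.0 recovers them with adjusted Rand index ≥ 0.9 in at least
19 of 20 seeded runs.

## Numerical choices and degenerate inputs

* Exact mirror symmetry is reported as exactly 1: when the two side
  matrices are identical the correlation short-circuits to 1 rather than
  accumulating ~10⁻¹⁶ of floating-point noise.
* Sholl grids use a 10⁻⁹ relative tolerance when rounding the arbor
  extent to a whole number of steps, so coordinates that sit on a sphere
  boundary up to float error do not create phantom crossings.
* Degenerate inputs have defined behaviour: empty synapse tables, graphs
  emptied by the filter, constant matrices/profiles, skeletons without a
  soma (for radial density) and single-node skeletons (for similarity)
  raise informative errors; a single-node skeleton has cable length 0.
* SWC is written at 17 significant digits so write-read round trips are
  exact at double precision.

## Problem sizes in the test suite

The suite runs entirely on synthetic data built at test time: small body
plans (two to six types per class and one to six segments, up to ~140
cells), 100 random datasets of ≤ 60 cells for derivation-oracle
equivalence, 20-seed benchmarks for module recovery and for the
stereotypy noise trend, and 200 random fixtures of ≤ 50 nodes for
path-classification oracles. These sizes give each property enough random
instances to be meaningful while keeping the whole suite fast enough to
run habitually.

## Limitations

* The published whole-body statistics that require the EM database (the
  0.91 whole-body and 0.76 mushroom-body left-right correlations, the
  Table-1 path census) are procedure-reproduced here, not
  number-reproduced; the acceptance script recomputes only the ratios
  that printed counts determine analytically.
* Gap junctions are out of scope (none are annotated in this data model);
  synapses are strictly monadic.
* Betweenness weighting, Leiden resolution and the stereotypy transform
  are stated defaults with alternatives exposed — where the underlying
  protocol is silent, we chose the most reproducible reading and made the
  choice visible rather than definitive.
* Force-directed layout is out of scope; graphs export to GraphML/GEXF
  for external layout tools.
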