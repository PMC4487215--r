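---
title: "Detecting conserved protein complexes with unequally lenient network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved protein complexes with unequally lenient network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenalign)
```

## The problem

Protein complexes — groups of physically interacting proteins — are the
working units of the cell, and protein–protein interaction (PPI) networks
are believed to evolve at the level of these modules. Given PPI networks of
two species and sequence homology between their proteins, *local* network
alignment looks for pairs of small subnetworks, one per species, that are
joined by homology and plausibly descend from a common ancestral complex.
Two biological facts make this hard: gene duplication produces many-to-many
homology mappings, and interactions appear and disappear over evolutionary
time, so strictly identical topology across species is rare and a lenient
notion of "connected" is needed. Most methods apply the *same* leniency to
both networks; the method implemented here allows the two networks
*unequal* path-length bounds, `l` for network one and `r` for network two,
because PPI networks of different species differ in density and average
path length.

`lenalign` implements the full dividing-and-matching procedure: one network
is divided into candidate subnetworks (a known complex catalogue or the
bundled Markov clustering), cross-network mappings are propagated by an
unbalanced bi-random walk, conserved module pairs are grown under the
`l`/`r` bounds, and near-duplicate solutions are filtered. An evaluation
stack (overlap-score matching, precision/recall/F-measure, coverage rate,
Resnik GO similarity) and a synthetic benchmark generator complete the
package.

## Homology input and the seed matrix

Homology is consumed as bidirectional BLAST E-values; sequence handling is
out of scope. A cross-network pair `(a, b)` is a *real* homologous mapping
when both `E(a,b) < c` and `E(b,a) < c`, with cutoff `c = 1e-9` (strict, in
both directions; a missing direction fails). These pairs form the binary
seed matrix `A` (network-one proteins × network-two proteins). The
symmetric E-value mean `(E(a,b) + E(b,a))/2` is computed
(`sequence_similarity()`) but kept for diagnostics only — downstream stages
deliberately use the binary `A`, because the detection procedure reasons
about the *existence* of mappings, not their strength.

## The unbalanced bi-random walk

Direct homology misses mappings hidden by missing interactions or
unannotated proteins, so the seed matrix is propagated over both network
topologies. Let `P` be the row-normalised adjacency of network one
(`p(i,j) = 1/degree(i)` on edges, zero rows for isolated proteins) and `H`
the column-normalised adjacency of network two. The mapping matrix is

$$R_0 = A; \qquad
R_t = \alpha\,\frac{\lambda_p(t)\, P R_{t-1} + \lambda_h(t)\, R_{t-1} H}
                   {\lambda_p(t) + \lambda_h(t)} + (1-\alpha)\, A ,$$

for `t = 1 … max(l, r)`, with indicators `λp(t) = 1` iff `t ≤ l` and
`λh(t) = 1` iff `t ≤ r`. Left-multiplying by `P` takes one walk step in
network one; right-multiplying by `H` takes one step in network two; the
indicators let the two networks receive *unequal* numbers of steps. The
term `(1-α)A` re-anchors every iteration on the known mappings; `α = 0.5`
by default. Three properties follow and are asserted in the test suite:
with binary `A` every entry stays in `[0, 1]`; `R(i,j) > 0` only if some
seed pair lies within `l` steps of `i` and `r` steps of `j` (support
locality); and swapping the networks together with `(l, r)` transposes `R`.

Two deliberate non-features: there is no convergence test (the iteration
count is exactly `max(l, r)`, in contrast to run-to-convergence global
aligners), and `R` is not re-normalised between iterations — the update is
already a convex combination, and re-normalising would destroy the
`[0, 1]` seed-relative scale. Entries of `R` that are positive without a
seed entry are the *artificial* mappings (`artificial_mappings()`); any
positive mass counts by default (`threshold = 0`), configurable because no
canonical cutoff exists.

## Dividing the network

The partitioner is pluggable: any complex catalogue (known complexes or the
output of an external clustering tool, one complex per line) can be
supplied via `partition_from_catalogue()`, which intersects each complex
with the network and preserves catalogue order. As the only built-in
partitioner the package bundles a compact Markov clustering
(`mcl_partition()`): column-stochastic adjacency with unit self-loops,
alternating expansion (matrix squaring) and inflation (entrywise power,
default exponent 2, then column renormalisation) until the matrix changes
by less than `1e-6` or 100 rounds, clusters read from the attractor
structure. Singleton clusters are retained — the growth step handles them
trivially. Overlapping clusterings (e.g. clique percolation) are out of
scope but their output files are accepted through the catalogue reader.

## Growing conserved module pairs

For each subnetwork the detection proceeds in four steps
(`grow_modules()`, `refine_module_two()`, `attach_isolated()`,
`filter_overlaps()`, composed by `align_networks()`):

**Step 1 — admission.** Starting from the lexicographically smallest
subnetwork member, members within path length `l` of the current node
(paths through the full network) are admitted into ModuleOne when the walk
matrix gives the two of them a shared homolog and either (a) some shared
homolog is a real homolog (per `A`) of one of them, or (b) two different
shared homologs are really matched to two distinct subnetwork members
outside the current node-and-neighbour set. Only seed-supported homologs
enter ModuleTwo — artificial mappings may *witness* shared ancestry but
never contribute members. The admission condition depends only on the
subnetwork and the matrices, so evaluation order cannot change the result;
chaining it breadth-first from the smallest member keeps ModuleOne
internally connected under the depth-`l` relation, which the tests assert.
A subnetwork yielding no admissible pair degenerates to its smallest
seed-linked member, giving later steps a chance to extend or discard it.

**Step 2 — refining ModuleTwo.** Many-to-many homology inflates ModuleTwo,
so each of its proteins is weighted by the sum of its walk scores to
ModuleOne, and connected components of ModuleTwo are formed under depth-`r`
connectivity in network two (paths may traverse proteins outside the
module — a conserved pair may be bridged by an unmapped protein).
Components of two or more proteins mark their seed counterparts in
ModuleOne as covered; a singleton whose counterparts are all covered is
redundant and removed, and of several singletons competing for an
uncovered counterpart only the heaviest survives (ties to the smallest
ID, for determinism).

**Step 3 — attaching isolated members.** Subnetwork members that Step 1
missed (e.g. isolated within the subnetwork's reach) are appended when
their real homolog is already in ModuleTwo, or reaches ModuleTwo within
`r` steps — in which case the homolog joins ModuleTwo too. Finally, since
conserved complexes consist of homologous proteins, members of either
module with no seed link into the other module are discarded (iterated to
a fixed point, as each removal can orphan others).

The whole procedure then re-runs with the roles of the networks reversed
(subnetworks of network two, `l`/`r` swapped, matrices transposed), and
solutions are reported in a fixed orientation.

**Step 4 — overlap filtering.** Redundant solutions arise from overlapping
subnetworks and shared homologs. With the overlap score
`OS(B, C) = |B∩C|² / (|B||C|)`, a solution is removed when another
*retained* solution has a strictly larger network-one complex with
`OS > t` (`t = 0.8`). Processing order is decreasing network-one size,
then decreasing network-two size, then lexicographic membership. Both
inequalities are strict: equal-sized near-duplicates survive (and exact
duplicates collapse later in `distinct_complexes()`), and `OS = 0.8`
exactly does not trigger removal.

## Evaluation

Predictions are matched to a known catalogue at `OS ≥ 0.2`. The report
counts predicted complexes (PC), matched predictions (MPC = TP), known
complexes matched at least once (MKC — counted once however many
predictions hit them), and perfect set-identical matches (PM); precision
is `MPC/PC`, recall `MKC/known_total`, F their harmonic mean, and the
coverage rate sums each known complex's best single-prediction
intersection over the catalogue's total protein count. The recall
denominator `known_total` is an explicit, logged argument (default: the
catalogue size) because published evaluations sometimes restrict the
catalogue in unstated ways; making it explicit keeps reported recalls
auditable.

Functional relevance uses Resnik similarity over the Gene Ontology
(biological process by default): the information content
`IC(t) = −ln p(t)` with `p(t)` the fraction of annotated proteins whose
upward-closed annotation contains `t` (descendant-closed counts, natural
log — the standard annotation-based corpus IC), term similarity the
maximum IC over common ancestors, protein similarity the maximum over
annotation term pairs, with unannotated proteins flagged and scored 0.
Per solution the package averages pairwise similarity within each module,
across modules only, and over all pairs (unordered, no self-pairs);
solution-level averages are combined unweighted across solutions, and
single-protein modules are excluded from within-module means. For
cross-network pairs the network-one corpus's IC is used; the two species'
corpora differ, some convention is required, and this one is symmetric in
practice when both annotation sets derive from the same GO release.

## The synthetic benchmark

Real evaluations of this method family need curated interactomes, BLAST
runs and complex catalogues; none of that is required to validate the
machinery. `generate_synthetic()` plants `n` dense connected modules
(spanning path plus Bernoulli(0.9) extra edges) in network one, mirrors
each into network two with a fraction of edges rewired within the module,
links mirrored proteins with strong bidirectional E-values (1e-50), drops
a fraction of those links, duplicates a fraction of network-two module
proteins with identical edges and links (many-to-many mappings), and adds
Erdős–Rényi background (100 extra proteins per side, edge probability
0.01 — a sparse periphery, roughly the density of curated interactomes).
The defaults — 10 complexes of 4–8 proteins, 10% dropout, 10% rewiring,
10% duplication — are the package's benchmark conditions throughout; the
generator is fully deterministic given its seed and restores the caller's
RNG state.

What the generator does *not* emulate: scale-free degree structure,
correlated false-positive interactions, sequence-level evolution, and
complexes sharing proteins. Passing the benchmark therefore demonstrates
that the machinery behaves as specified under modular structure with
realistic noise types — not that any particular biological interactome
would yield the published biological findings.

In the noise-free limit every planted pair is an exactly mirrored module
and the pipeline must recover all of them with overlap score 1 on both
sides; under the default noise the tests require at least 90% recovery at
`OS ≥ 0.2`. Both properties are exercised in the test suite and recomputed
by `scripts/acceptance.R`.

## Numerical and degeneracy choices

* Path lengths count edges; depth bounds are `≤`, and `l = r = 2`
  (defaults) reproduces the common "path of length at most 2" leniency.
* Isolated proteins give zero transition rows/columns rather than errors;
  empty seed tables give all-zero `R`; `l = r = 0` returns `R = A`.
* All tie-breaks (start node, singleton competition, filter order) are
  lexicographic, making every run reproducible; two runs with the same
  configuration produce byte-identical outputs.
* MCL prunes entries below `1e-8` after inflation to preserve sparsity;
  convergence is the max absolute entry change below `1e-6`.
* Problem sizes used in validation: walk equivalence on 100 random
  instances of ≤10 nodes per side over all `(l, r) ∈ {0..3}²`;
  connectivity against a Floyd–Warshall oracle on 50 random 12-node
  graphs; the benchmark pipeline on ~160-protein networks. The full
  benchmark runs in well under a second, so these sizes probe correctness,
  not performance; the sparse-matrix contract is what carries the method
  to interactome scale.

## Known limitations

* Step 1's growth is seeded at one member per subnetwork; a subnetwork
  whose admissible pairs form several far-apart regions contributes only
  the region reachable from the start (the reversed pass and Step 3
  mitigate this). This is inherent to emitting one solution per
  subnetwork.
* ModuleTwo may legitimately end up with several depth-`r` components
  when distinct multi-protein components each cover part of ModuleOne;
  the filter keeps them all, as the refinement rule prescribes.
* The walk's artificial-mapping threshold (any positive mass) is
  permissive; on very dense networks a stricter threshold may be wanted.
* Only two-network alignment is supported; multi-species extension and
  alignment-graph methods are out of scope.

## A worked run

```{r example}
bench <- generate_synthetic(synth_params(seed = 1))
A <- build_seed_matrix(bench$homology, bench$net1, bench$net2)
R <- bi_random_walk(transition_matrix(bench$net1, "row"),
                    transition_matrix(bench$net2, "column"), A)
subs <- partition_from_catalogue(bench$catalogue, bench$net1)
res <- align_networks(bench$net1, bench$net2, subs, NULL, R, A)
glance(res)
match_stats(distinct_complexes(res, "one"), bench$catalogue)
recovery_rate(res, bench$truth)
```
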