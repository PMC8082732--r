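---
title: "Computing DCJ-indel distances for natural genomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing DCJ-indel distances for natural genomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjindel)
```

## The model

A genome is a set of chromosomes, each a sequence of oriented marker
occurrences, linear or circular. A DCJ cuts two positions and rejoins the
four open ends differently; indels insert or delete contiguous marker
segments. Under the maximal matches model a marker may only be deleted
where it is over-represented (`ΔΦ(m) = Φ_A(m) − Φ_B(m) > 0` for deletions
from *A*) and only inserted where under-represented. The DCJ-indel
distance is the minimum number of DCJs plus indels sorting *A* into *B*.

The package computes this distance exactly for *natural* genomes —
arbitrary multiplicities, arbitrary content, mixed chromosome
topologies — by reducing it to an optimal consistent cycle decomposition
of a capped multi-relational diagram, found by an integer linear program.
For singular genomes (every common marker occurs once in each genome) the
closed form over the relational diagram is used and doubles as the main
internal oracle.

## Runs, indel potential, transitions

Within a component of the diagram, maximal stretches of same-genome indel
edges form *runs*; `Λ(C)` counts them. DCJs within a component can merge
and accumulate runs so that a component with `Λ` runs can be resolved with
`λ(Λ) = ⌈(Λ+1)/2⌉` indels (`0` for `Λ = 0`): the *indel potential*. The
ILP does not count runs directly; it counts *transitions* — indel-free
stretches flanked by indel edges of opposite genomes — because transitions
localize at single edges. For cycles `ℵ = 0` if `Λ ≤ 1` and `ℵ = Λ`
otherwise, which gives the identity `λ = ℵ/2 + r` with `r = [Λ ≥ 1]` that
the ILP objective exploits; the suite asserts it analytically for
`Λ = 0..50`.

## The recombination groups and the greedy deduction

For linear singular genomes, DCJs across two path components
(*recombinations*) can beat sorting components separately. The path types
that matter are classified by endpoint genomes and run structure: `W`
(AA-path, even runs), `W̄`/`W̲` (AA-path, odd runs starting in *A*/*B*),
`M`, `M̄`, `M̲` (the BB analogues), `Z` and `N` (AB-paths with even runs
read from *A*, starting in *A* or *B*). The total deduction is obtained
greedily over chained recombination groups in six parts with
`δ = 2P + 3Q + 2T + S + 2M + N`.

The full group table used here is:

| part | groups (sources consumed) | deduction each |
|------|---------------------------|----------------|
| P | `W M` | 2 |
| Q | `W W M̄ M̲`, `M M W̄ W̲` | 3 |
| T | `W Z M̄`, `W N M̲`, `W W M̄`, `W W M̲`, `M N W̄`, `M Z W̲`, `M M W̄`, `M M W̲` | 2 |
| S | `Z N`, `W̄ M̄`, `W̲ M̲`, `W M̄`, `W M̲`, `W̄ M`, `W̲ M`, `W Z`, `W N`, `M Z`, `M N`, `W W`, `M M` | 1 |
| M | `Z Z W̲ M̄`, `N N W̄ M̲` | 2 |
| N | `Z W̲ M̄`, `N W̄ M̲`, `Z Z W̲`, `Z Z M̄`, `N N W̄`, `N N M̲` | 1 |

This table was derived by exhaustive exploration of the elementary
recombination operations (each consuming two source paths and producing
resultants with a known DCJ cost and indel-cost change) and is verified in
the test suite against a brute-force optimizer over those operations, on
every type-count vector with entries up to three and on thousands of
random larger vectors. Within each part the groups are exclusive once the
earlier parts have been applied; the three-source groups that feed a
resultant back into a second deducting operation (`W Z M̄` and its
mirrors) must precede the `W W M̄`-style subgroups of Q, which the table
order encodes. Linear singleton chromosomes enter the classification as
AA-/BB-paths with a single run.

## Matchings, capping and the ILP

With duplicates, the multi-relational diagram carries an extremity edge
between every pair of same-marker, same-end occurrence extremities, and an
indel edge on every occurrence of an over-represented marker. A maximal
*sibling set* (extremity edges chosen in head/tail pairs, no two incident)
is exactly a maximal matching of occurrences; the decomposition it induces
reproduces the relational diagram of the matched singular genomes. One
subtlety: an indel edge enters the induced decomposition only for
*unmatched* occurrences. A matched occurrence that forms a
single-occurrence linear chromosome has two degree-one telomere
extremities, so a purely degree-based completion rule would also admit its
indel edge and merge two components into one with a lower weight; the
package therefore keys the completion on matchedness, which the
randomized capping tests confirmed to be the semantics that keeps the two
construction routes identical.

Linear chromosome ends are removed by *capping*: `p* = max(κ_A, κ_B)` cap
pairs (4`p*` vertices) close every telomere, `a* = |κ_A − κ_B|` artificial
adjacencies pair the surplus caps on the side with fewer linear
chromosomes, and the complete bipartite set of cap extremity edges lets
the solver choose how paths are linked. Every consistent decomposition of
the capped diagram is a cycle decomposition, and for each fixed matching
the best capping recovers the uncapped weight up to the `p*` extra cycles
the caps close — the identity holds as
`max_P w(Q[S,P]) = w(D[S]) + p*`, equivalently as equality of the
distances `n* − w(D[S]) = n* + p* − max_P w(Q[S,P])`; the weight-level
form without the `p*` offset does not hold whenever linear chromosomes are
present, which the enumeration tests make explicit.

The ILP has binary edge-selection variables (adjacency and artificial
edges are fixed to one and folded into the rows), cycle labels
`0 ≤ y_i ≤ i` equalized along selected edges and zeroed through selected
indel edges, counters `z_i = 1` only if `y_i = i` (so `Σz` counts
indel-free cycles), run labels `r ∈ {0,1}` pinned to 0/1 at selected
A-/B-indel edges, transition variables on A-adjacencies, and singleton
variables per circular chromosome whose occurrences all carry indel edges.
The objective maximizes `Σz − ½Σt − Σs`; the distance is
`n* + p* − objective`.

Two modelling choices deserve a note:

* **Transition placement.** Label changes are prohibited on all edges
  except A-adjacencies that share a vertex with an A-indel edge, so every
  transition is observed immediately next to the A-run it borders and
  only those edges carry transition variables. Cap-adjacent adjacencies
  are *not* exempt: when an exclusive marker sits at a chromosome end its
  telomere vertex carries both the cap adjacency and an indel edge, and
  that adjacency must be allowed to host the label change — freezing it
  would make such instances infeasible.
* **Circular singletons.** The singleton constraint is instantiated only
  for circular chromosomes in which *every* occurrence carries an indel
  edge; other circular chromosomes can never decompose into a singleton,
  and giving them the constraint would force phantom singleton counts.

Cap vertices carry free run labels (they are indel-free), and label
equality propagates across selected cap edges, so runs merge correctly
through capped chromosome ends.

The MIP is written in CPLEX LP format and solved by the GLPK standalone
solver (`glpsol`), single-threaded and deterministic; proven optimality is
reported as status `optimal`, a time-limited run with an incumbent as
`feasible_gap` with primal/dual distance bounds. Matchings of markers that
are singular in both genomes are forced by the degree constraints, so the
number of genuinely free binaries scales with the duplicate occurrences
and the number of telomeres, not with genome size.

## Oracles

Three independent routes validate the implementation:

* a breadth-first search over genome states under all DCJ operations
  (adjacency rewiring both ways, telomere joins, adjacency splits), the
  ground truth for canonical instances up to five markers;
* exhaustive enumeration of maximal matchings, each scored by the
  singular closed form, for natural instances within a guard on the
  matching-space size;
* exhaustive enumeration of capping sets, for the capping identity above.

The keystone test asserts BFS = closed form = ILP on 200 random canonical
instances, closed form = ILP on 200 random singular instances with
exclusive markers and mixed topologies, and matching enumeration = ILP on
100 random natural instances with at most 8 occurrences per genome and 3
copies per marker.

## The simulator

The generator evolves a root genome of fresh singular markers along a
weighted rooted tree (default: two leaves). Per edge, event counts are
Poisson: DCJs with mean equal to the edge weight, duplications, deletions
and insertions with mean weight × rate (defaults 0.4, 0.2 and 0.1).
Events apply in the order DCJs, duplications, deletions, insertions. DCJ
cut sites are drawn uniformly over adjacencies and telomeres with both
rejoinings equiprobable; segment lengths are Zipf-distributed (shape 4
for indels, 6 for duplications; the sampler truncates the unbounded
support at 10⁴, beyond which the mass is below 10⁻¹⁰ for these shapes),
and locations are uniform over the genome. Insertions mint globally fresh
markers; duplications copy a segment to a uniformly drawn target
position; deletions are truncated so a chromosome never empties. Every
event is logged with enough detail that replaying the log on the parent
genome reproduces the child exactly, which the suite asserts, along with
bit-identical reproducibility from the seed.

What the simulator does *not* emulate: sequence-level mutation, rate
heterogeneity beyond edge weights, biased rearrangement breakpoints, or
whole-chromosome gains and losses. Passing the simulated suites therefore
demonstrates correctness of the distance computation under the model's
own generative assumptions, not robustness to marker-inference noise in
real data.

## Problem sizes and numerical choices

The validation suites run at desk scale: oracle agreement uses genomes of
up to ten markers (the BFS state space grows super-exponentially), the
capping enumeration caps `p*` at two (capping sets grow as `(2p*)!`), and
the simulated benchmark uses a root genome of 200 occurrences with
duplication rate 0.4 and 10 expected DCJs per branch, solved to proven
optimality. Distances are integers throughout; the ILP objective is
half-integral because of the transition term, and the decoded distance is
rounded from `n* + p* − objective` only to absorb solver floating-point
noise. Ties among co-optimal matchings or cappings are resolved
arbitrarily by the solver: only the distance is contractual, the witness
decomposition is informational. Circular chromosomes are stored in a
canonical rotation so genome equality, state deduplication in the BFS and
file round-trips are well defined.

## Known limitations

* GLPK's branch-and-bound is markedly weaker than commercial solvers;
  instances with thousands of duplicate occurrences or many linear
  chromosomes will hit time limits that stronger MIP backends would not.
  The model text is solver-agnostic (LP format) should another backend be
  available.
* The recombination-cost enumerator rebuilds the full diagram per
  candidate DCJ; it is a verification device for small path
  constellations, not an optimizer.
* `sibling_sets()`, `capping_sets()` and `bfs_dcj_distance()` are oracles
  with explicit combinatorial guards; they refuse rather than attempt
  large instances.
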