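---
title: "Potential-theory link prediction: model, predictors, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-theory link prediction: model, predictors, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potentialnet)
```

## The model

potentialnet studies link formation in directed networks — food webs, neural
wiring diagrams, citation and follower graphs — under a *potential theory*:
every directed arc is assumed to correspond to the decrease of exactly one
unit of an integer node potential. A digraph is **potential-definable** when
its nodes admit potentials $p$ with

$$p_i = p_j + 1 \quad \text{for every arc } i \to j,$$

in which case the potential value reads as a node's level in a local
hierarchy (directed paths are strictly hierarchical and definable; any graph
containing a reciprocal arc pair, or a directed cycle, is not; feed-forward
loops show that acyclicity is necessary but not sufficient). Potentials are
determined only up to an additive constant per weakly connected component,
so `assign_potentials()` reports the canonical representative with minimum 0
in each component; a disconnected graph is definable exactly when all of its
components are, since the unit-drop rule never couples components.

`assign_potentials()` labels nodes by breadth-first traversal of the
underlying undirected graph, stepping $-1$ along an arc and $+1$ against it,
and checking every non-tree edge. It is linear in nodes plus arcs. When the
graph is not definable it returns a certificate: the first conflicting arc
together with the BFS tree path joining its endpoints, whose implied
potential difference differs from the required 1. Equivalently, a graph is
definable iff every undirected cycle traverses equal numbers of forward and
backward arcs — a characterisation the test suite checks against a
cycle-basis oracle.

## The subgraph catalog

The theory becomes predictive when combined with two classical local
mechanisms. *Clustering* favours short loops in the undirected sense, which
restricts attention to subgraphs of orders 3 and 4 that embed a loop;
reciprocal pairs are not counted as loops. To avoid double counting, only
**minimal** loop-embedded subgraphs are kept: those containing no proper
loop-embedded subgraph, where "subgraph" is the *generalized* notion — any
node subset with any subset of the arcs among those nodes, not only induced
subgraphs. *Homophily*, read topologically, prefers patterns whose nodes
span fewer potential levels.

`enumerate_minimal_loop_embedded(order)` realises this definition by brute
force: all digraphs on `order` labeled nodes without self-loops or
reciprocal pairs are generated ($3^{\binom{n}{2}}$ of them), the
loop-embedded ones kept, minimality enforced, and isomorphs collapsed via a
canonical form (the minimum adjacency bit-string over all node
permutations — at most 24 permutations at these orders, so exact and cheap).
Minimality is decided by the equivalent fast test "the graph is cyclic, no
node is isolated, and deleting any single arc breaks all undirected cycles";
the test suite re-verifies the catalog against the literal exhaustive
node-subset/arc-subset search, and against an independent oracle: the
catalog must equal the reciprocal-free orientations of the full cycle on
`order` nodes up to isomorphism.

The catalog comprises six patterns, in the package's canonical role
labelings:

| name | arcs | definable | potential levels |
|------|------|-----------|------------------|
| 3-FFL | 1→2, 2→3, 1→3 | no | — |
| 3-Loop | 1→2, 2→3, 3→1 | no | — |
| Bi-fan | 1→3, 1→4, 2→3, 2→4 | yes | 2 |
| Bi-parallel | 1→2, 1→3, 2→4, 3→4 | yes | 3 |
| 4-Loop | 1→2, 2→3, 3→4, 4→1 | no | — |
| 4-FFL | 1→2, 2→3, 3→4, 1→4 | no | — |

Only Bi-fan and Bi-parallel are potential-definable, and Bi-fan is the more
homogeneous of the two (two potential levels against three), which singles
it out as the structure the combined mechanisms favour most.

## The twelve predictors

Removing one arc from each pattern, up to the pattern's automorphisms,
yields twelve predictor specifications S1–S12 (`derive_predictors()`),
grouped by parent as 3-FFL: S1–S3, 3-Loop: S4, Bi-fan: S5, Bi-parallel:
S6–S7, 4-Loop: S8, 4-FFL: S9–S12. Within a parent, the removed-arc orbit
representatives are ordered lexicographically by role pair in the labelings
above; this within-parent labeling convention is a package choice (the
original figure's drawing order is not text-recoverable), and any consistent
bijection gives identical results because predictors are evaluated
individually and by parent groupings.

The score of a non-observed candidate arc $(x, y)$ under predictor $S_k$ is
the number of occurrences of $S_k$'s parent pattern that adding $x \to y$
would create *with the candidate in the removed-arc role*. An occurrence is
an injective map of pattern roles to distinct nodes with every pattern arc
present; extra arcs among the image nodes — including reciprocal partners —
are ignored, per the generalized subgraph definition (induced-subgraph
counting is deliberately not used, and a reverse arc $y \to x$ in the
training data does not affect the candidate's score). For every one of the
twelve predictors the automorphism subgroup fixing the removed arc is
trivial — asserted when the catalog is built — so occurrence counting
reduces to counting distinct assignments of the one or two free roles.

Two implementations are provided. `score_link()` enumerates all injective
free-role tuples; it is the reference oracle. `score_link_fast()` propagates
constraints over adjacency lists (each free role's admissible nodes are
intersections of in/out neighbour lists of already-bound roles), with cost
bounded by the product of at most two adjacency-list sizes; the suite checks
equality of the two on hundreds of random digraphs. `hybrid_score()` sums
members of a grouping, e.g. `"3-FFL"` = S1+S2+S3 = the total number of
3-FFLs created.

## Evaluation protocol

`split_arcs()` partitions the observed arcs into a training set and a probe
(testing) set; the training fraction defaults to 0.9 and the probe size is
round-half-up of $(1-f)\,M$, documented because $M$ is rarely divisible
by 10. Nodes isolated by the split remain in the training graph, keeping the
candidate universe intact. Accuracy is the AUC: the probability that a
randomly chosen missing (probe) link outscores a randomly chosen nonexistent
link (an ordered pair never linked in the full network), ties counting one
half:

$$\mathrm{AUC} = \frac{n' + 0.5\,n''}{n}.$$

`auc_exact()` evaluates this over *all* probe-by-nonexistent pairs with
midrank-style counting in exact arithmetic; `auc_sampled()` draws $n$
independent comparisons. `run_experiment()` repeats the whole pipeline over
independent partitions (the reference protocol is 50) with seeds
`base_seed + 1 .. base_seed + repetitions`, and reports means and standard
deviations per predictor set. If all scores were i.i.d. draws from one
distribution the AUC would be about 0.5, so the excess over 0.5 measures
performance beyond chance.

Numerical and protocol choices that were genuinely open:

* **Exact vs sampled AUC.** The comparison count of the original protocol is
  unstated; the package uses the exact AUC whenever
  $|\text{probe}| \times |\text{nonexistent}| \le 10^7$ (default
  `exact_budget`) and otherwise $10^5$ sampled comparisons, recording which
  path was taken in the per-repetition output.
* **Nonexistent universe.** The universal candidate set is quadratic in the
  node count, so for larger graphs `run_experiment()` uniformly samples the
  nonexistent links (default cap $10 \times |\text{probe}|$ once the
  universe exceeds 20,000; `"all"` forces enumeration). The choice is
  explicit and logged per repetition.
* **Normalization at load time.** Self-loops are dropped with a warning (no
  catalog pattern contains one; food-web cannibalism loops are thus
  excluded) and duplicate arcs collapse — the method is purely topological,
  so weights in input files are ignored. Pajek `*Edges` lines expand to
  reciprocal arc pairs, the only faithful reading of an undirected line in a
  directed container.
* **Determinism.** Every random step takes an explicit seed and restores the
  caller's RNG state; identical inputs give bit-identical outputs. Arc
  tables and node sets are kept in locale-independent radix order, and
  equal-sized weak components are tie-broken toward the lexicographically
  smallest member label.

## Synthetic data

The generators emulate the regime the method targets — sparse directed
networks at food-web scale, tens to hundreds of nodes with hundreds to a
few thousand arcs (e.g. 69 nodes / 916 arcs for a typical wet-season food
web) — while letting structure be planted exactly:

* `random_digraph(n, m)` draws exactly `m` arcs uniformly (without
  replacement; exact counts keep test assertions crisp), optionally
  excluding reciprocal pairs.
* `layered_dag(n, layers)` places arcs only from layer $\ell+1$ to $\ell$,
  so every arc drops one level and the graph is potential-definable by
  construction, recovering its layer indices up to translation.
* `planted_bifan_graph(sources, sinks, p)` is a one-way bipartite graph with
  independent arc inclusion; its expected Bi-fan count has the closed form
  $\binom{s}{2}\binom{t}{2}p^4$, attached as metadata. Being one-way
  bipartite it contains no directed triangle, which makes it a sharp
  discriminator: S5 (Bi-fan completion) recovers held-out arcs well above
  chance while S4 (3-Loop completion) is forced to score every candidate 0
  and lands exactly at AUC 0.5.

What these generators do *not* emulate: degree heterogeneity of real food
webs (hub predators), reciprocity-rich social media graphs, community
structure, and any node attributes. Passing tests on synthetic data
therefore validate the machinery — enumeration, counting, the protocol —
not the empirical claim that Bi-fan completion predicts links best on real
networks, which requires the real datasets the command-line interface can
process but the package does not ship.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is informative: definability oracles
on graphs of up to 8 nodes (where exhaustive labeling search over potentials
$\{0,\dots,7\}$ is conclusive, the spread within a component being at most
$n-1$); fast-vs-brute scoring equality on 100 random digraphs of 10–30
nodes at densities 0.05–0.4; the random-score AUC baseline on 50-node,
300-arc graphs with 10,000 sampled comparisons over 20 seeds; planted
Bi-fan recovery at $30 \times 30$, $p = 0.3$ over 10 exact-AUC splits; and
the 50-partition reproducibility check on a 200-node, 1500-arc graph.

## Known limitations

* Pattern enumeration is implemented for orders 2–4 only; order 5 and up is
  out of the combinatorial scope of the catalog.
* `structural_summary()` computes the effective diameter by exact all-pairs
  BFS, appropriate for the small and medium graphs targeted here, not for
  web-scale networks where probabilistic counting would be required.
* Scores are integer counts; no weighting, probabilistic calibration, or
  similarity-index predictors beyond the twelve subgraph predictors.
* `potential_level_count()` is only defined for definable graphs; there is
  no maximum-definable-subgraph relaxation.
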