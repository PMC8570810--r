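---
title: "Target controllability of directed interaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target controllability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netctrl)
```

## The model

A directed interaction network over nodes $V$ ($n = |V|$) carries linear
dynamics $\dot x = A x + B u$: the structured matrix $A$ has $A_{ij}$
generically nonzero iff the edge $j \to i$ exists (this orientation is fixed
package-wide), and $B$ has one unit column $e_s$ per input node $s \in I$.
A target set $T$ is *generically controllable* from $I$ when the rows of the
Kalman matrix $[B, AB, \dots, A^{n-1}B]$ indexed by $T$ have rank $|T|$ for
almost every assignment of nonzero weights to the edges. The biological
reading: $T$ collects disease-essential proteins, $I$ the proteins where an
intervention (ideally a drug) injects a signal, and the paths from $I$ to
$T$ are the routes along which influence propagates.

### The path-compatibility (layer) condition

All solutions in this package are sets of *control paths*: one directed walk
per target, from its input $u_0$ through edges to the target $u_m$, with
$m \le L$ (the path-length cap). Within a path, node $u_i$ sits at
*backward layer* $m - i$; the target is at layer 0, the input at layer $m$.
A path set is accepted iff no node is occupied by two distinct paths at the
same backward layer. Intuitively, layers are time-reversed steps of signal
propagation: a node cannot relay two different signals in the same step, but
one input node *can* drive several targets if its paths have pairwise
distinct lengths (time-multiplexing of a single input signal). The condition
is sufficient for generic controllability; the package treats it as the
constructive certificate and verifies it independently with the rank oracle
(below). Repeated nodes within one walk are allowed: the condition is
layer-based, not simple-path-based, and walks arise naturally from the
backward construction (e.g. around cycles).

Targets may act as their own inputs (a length-0 path, occupying the target
at layer 0 only). Because whether that is biologically meaningful depends on
the application, `control_problem(allow_self_inputs = FALSE)` forbids any
path whose input equals its target; with the flag off, a problem can be
genuinely uncontrollable (e.g. a target with in-degree 0), which both
solvers report as a status rather than an error.

## Greedy layer matching

`greedy_control()` maintains one chain per target, initialized at the target
(layer 0). At layer $d = 1, \dots, L$ every active chain with current node
$v$ proposes the predecessors $\{u : (u, v) \in E\}$; a maximum bipartite
matching between chains and candidate nodes (Kuhn augmentation with
preference-ordered adjacency) decides which chains extend, so at most one
chain acquires any node at layer $d$ — preserving the layer condition by
construction. Unmatched chains terminate and designate their current node as
an input at its current layer. Candidates are ranked: (1) nodes already
designated as inputs by terminated chains — reuse shrinks $|I|$; (2)
preferred sources; (3) higher out-degree (hubs are more likely to serve
later chains); (4) a random tie-break from the repeat's RNG stream. A
defensive occupancy check additionally blocks a candidate already held at
the same layer by another chain; with synchronous extension this cannot
trigger, but it guards the invariant against future refactoring.

`repeats` (default 10) independent restarts draw distinct tie-break streams
from per-repeat sub-seeds; solutions are deduplicated by input set and
ranked by the lexicographic objective $(|I|, -|I \cap S|)$, then by input
ids for determinism. The optional `p_stop` (default 0) terminates a chain
early, with that probability, when it currently sits on a preferred source —
a way to trade path length for drug-targetable inputs; it is off by default
so the default run is driven purely by the matching.

Per-target, at most one new input arises, so $|I| \le |T|$ always. Greedy is
a heuristic: on the bundled `cycle` fixture it returns 2 inputs where 1
suffices, which is the gap the genetic algorithm closes.

## Genetic algorithm

`ga_control()` encodes a candidate solution as one gene per target: the
chosen input node, constrained to `ancestors_within(target, L)` (backward
BFS; each ancestor is annotated with *all* layers $\le L$ at which it can
occur on a walk to the target — around a cycle these form a parity pattern,
not a single distance). Decoding builds a shortest walk per gene (ties
broken by node-id order), counts layer conflicts, and runs one repair pass
re-routing conflicting paths via the gene's next-shortest feasible layer.
Fitness is the lexicographic triple (conflicts, $|I|$, $-|I \cap S|$);
infeasible chromosomes stay in the population graded by conflict count —
killing them would flatten the search space. Evolution uses tournament
selection (size 3), uniform per-gene crossover, per-gene mutation by
resampling from the ancestor pool, and elitism. Half the initial population
is seeded from randomized greedy passes, so the GA starts at least as good
as a greedy run and searches for strictly better assignments (e.g.
trading a non-preferred input for a preferred one, or exploiting
time-multiplexed single inputs the synchronous greedy cannot reach).

Defaults: population 100, elite fraction 0.1, mutation 0.05, tournament 3,
at most 200 generations, stop after 50 stagnant generations. These are this
package's own declared values, chosen as round numbers in the ranges
standard for small combinatorial GAs; the stagnation rule dominates in
practice on desk-scale problems. Two pure-speed measures that do not change
semantics: decode results are memoized (converged populations re-evaluate
few distinct chromosomes), and the run stops early when a provably optimal
solution is found ($|I| = 1$ with a preferred input, or $|I| = 1$ when no
preferred set was given). All feasible solutions encountered are archived,
deduplicated by input set, and returned ranked as in `greedy_control()`.

## The generic-rank oracle

`target_generic_rank()` is the package's independent ground truth, used in
tests and exposed via `verify_solutions()`. Genericity is sampled: each draw
assigns the edges independent uniform nonzero weights modulo the prime
$p = 2^{31} - 1$ and computes the rank of the target rows of the Kalman
matrix by Gaussian elimination over $\mathbb{F}_p$. Exact modular
arithmetic removes the floating-point rank-threshold ambiguity entirely; by
Schwartz–Zippel a draw underestimates the generic rank with probability at
most $n^2 / p$ (about $10^{-7}$ at $n = 20$), and the maximum over 3 draws
(default) is reported, so false negatives are negligible and false positives
impossible. Since intermediate products $a b$ with $a, b < 2^{31}$ exceed
the exactly representable double range, modular multiplication splits one
factor into 16-bit halves, keeping every intermediate below $2^{48}$.
`brute_force_minimum_inputs()` wraps the oracle in an exhaustive
increasing-size subset sweep, guarded to networks with $\le 12$ nodes.

When `allow_self_inputs = FALSE`, the brute-force candidate pool simply
excludes target nodes — a conservative reading consistent with the path
semantics (no input equal to its own target).

## Subnetwork generation

`generate_network()` implements three extraction rules around a seed set:
all edges touching a seed (`neighbors`), only seed-to-seed edges
(`direct`), and `gap` with $k \in 0..4$ intermediaries: keep edge $(u, v)$
iff $d_{out}(u) + 1 + d_{in}(v) \le k + 1$, where $d_{out}$/$d_{in}$ are
minimum BFS distances from/to the seed set (computed via igraph). The
sandwich rule makes the intended semantics — "on a directed seed-to-seed
walk with at most $k$ intermediaries" — cheap and gives two free choices we
adopt deliberately: the walk may start and end at the *same* seed (cycles
through one seed qualify), and $k = 0$ coincides exactly with `direct`.
Seeds never touched by a kept edge are dropped from the result (the node set
is exactly the kept endpoints); seeds absent from the universe warn rather
than fail, since curated seed lists routinely contain identifiers outside a
given interactome. These choices give the algebra the tests assert: `direct`
$\subseteq$ `neighbors`, `gap` monotone in $k$, `gap(0)` $=$ `direct`, and
idempotence of regeneration.

Identifiers are opaque, case-sensitive strings throughout; no HGNC/UniProt
cross-mapping is attempted — users map upstream, and unknown ids in target
or source lists are dropped with a warning (or rejected with
`strict = TRUE`).

## Synthetic data

`random_digraph()` provides Erdős–Rényi digraphs (each ordered pair an edge
with probability $p$) and a preferential-attachment model: an edgeless core
of $\max(2, \mathrm{param})$ nodes, then each new node sends `param`
directed edges to distinct existing nodes with probability proportional to
in-degree + 1, giving exactly $\mathrm{param} \cdot (n - \max(2,
\mathrm{param}))$ edges and heavy-tailed in-degrees. This emulates the
hub-dominated degree structure of protein-interaction networks well enough
to exercise the algorithms; it does not reproduce the motif composition,
reciprocity, or annotation biases of curated interactomes, so passing tests
demonstrate algorithmic correctness, not biological performance.
`toy_fixture()` bundles the five hand-checkable instances (`chain`, `star`,
`diamond`, `unequal`, `cycle`) whose optima are known in closed form and
re-verified by the oracle.

## Verification studies and problem sizes

The test suite asserts, among others: every solution emitted by either
solver on 100 random Erdős–Rényi problems ($n = 20$, $p = 0.1$, $|T| = 5$,
$|S| = 3$) passes both the layer check and the rank oracle; on 50 tiny
instances ($n \le 7$, $|T| \le 3$) the exhaustive minimum never exceeds the
greedy input count and the GA matches it on at least 40; the generation
algebra holds on 30 random universes; identical seeds yield bit-identical
JSON; and a 20,000-edge preferential-attachment analysis with 50 targets
completes in seconds. These sizes were chosen so the whole suite runs
comfortably on a laptop while still exercising every code path;
`scripts/acceptance.R` recomputes the same quantities from scratch for any
`--seed`.

## Numerical and design notes

* All randomness flows through per-purpose sub-seeds derived from one user
  seed (`withr::with_seed`); repeat runs are bit-identical, and no global
  RNG state leaks.
* Ties are broken deterministically everywhere randomness is not explicitly
  requested: node-id order in walk construction and solution ranking,
  preference rank in matching.
* The objective never weighs path lengths or edge signs;
  activation/inhibition annotations in SIF input are parsed and discarded,
  as the structural-controllability semantics is sign-blind.
* Known limitations: greedy extension is synchronous, so it cannot
  time-multiplex one input over equal-layer alternatives reachable only by
  delaying a chain (the GA covers much of this gap); the layer condition is
  sufficient but not necessary, so both solvers can report more inputs than
  the generic minimum; and exhaustive verification is capped at 12 nodes by
  design.
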