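# netctrl

Structural target controllability of directed interaction networks, with a
focus on biomedicine: given a directed protein–protein interaction network
and a set of *target* proteins (e.g. disease-specific survivability-essential
genes), find a small set of *input* (source) nodes — preferably
drug-targetable ones — from which external signals can steer the state of
every target, and report the explicit control path from each input to its
target.

## The problem and the model

The network carries linear dynamics **ẋ = A x + B u**, where the structured
state matrix *A* has *A*<sub>ij</sub> generically nonzero iff the edge
*j → i* exists, and *B* has one unit column per input node. A target set *T*
is *structurally controllable* from inputs *I* when, for almost every choice
of nonzero edge weights, the rows of the Kalman controllability matrix
[*B, AB, A²B, …, A*<sup>n−1</sup>*B*] indexed by *T* have full rank |*T*|.

Because too few essential proteins are themselves drug targetable, the
practical question is to control them *through* upstream drug-targetable
proteins. `netctrl` searches for input sets that minimize the objective
(|*I*|, −|*I* ∩ *S*|) lexicographically, where *S* is a user-supplied set of
preferred (drug-targetable) sources: fewest inputs first, then as many
preferred ones as possible.

Two search algorithms are provided, both certified by construction and by an
independent rank test:

* **Greedy layer matching** (`greedy_control()`): grows one control path per
  target backwards, layer by layer; a maximum bipartite matching between
  chains and candidate predecessor nodes keeps paths node-disjoint within
  each backward layer — the *path-compatibility condition* (no node occupied
  by two paths at the same backward distance from their targets), which is
  sufficient for generic target controllability. Randomized restarts explore
  alternatives; candidate preference favours input reuse, then preferred
  sources, then high out-degree.
* **Genetic algorithm** (`ga_control()`): evolves per-target input
  assignments (decode to shortest walks, repair conflicts, score by
  conflicts / |*I*| / preferred coverage) with tournament selection, uniform
  crossover, mutation and elitism.

Every solution can be verified independently with the exact generic-rank
oracle (`target_generic_rank()`), computed over the field of integers modulo
a large prime — no floating-point rank thresholds; on tiny networks
`brute_force_minimum_inputs()` gives the exhaustive optimum.

Subnetworks around seed proteins are extracted from a full interactome with
`generate_network()` (all interactions touching seeds, only seed–seed
interactions, or interactions on seed-to-seed walks with at most *k*
intermediaries, *k* ≤ 4).

## Worked example

A toy growth-signalling cascade; the targets are three downstream effectors
and the receptor EGFR and kinase MEK are marked drug-targetable:

```r
library(netctrl)

edges <- tibble::tribble(~from, ~to,
  "EGFR","RAS",  "RAS","RAF",  "RAF","MEK",  "MEK","ERK",
  "EGFR","PI3K", "PI3K","AKT", "AKT","MTOR", "MTOR","S6K",
  "ERK","MYC",   "AKT","MYC")
net <- network(edges)
problem <- control_problem(net, targets = c("MYC", "S6K", "ERK"),
                           preferred_sources = c("EGFR", "MEK"))

sols <- greedy_control(problem, seed = 1)
sols
#> <ctrl_solution_set> 2 solution(s) from 'greedy'
#> # A tibble: 2 × 4
#>   solution n_inputs n_preferred inputs
#>      <int>    <int>       <int> <chr>
#> 1        1        2           1 EGFR*, PI3K
#> 2        2        2           1 EGFR*, RAS

tidy(sols$solutions[[1]])
#> # A tibble: 3 × 5
#>   target input length input_is_preferred path
#>   <chr>  <chr>  <int> <lgl>              <chr>
#> 1 ERK    EGFR       4 TRUE               EGFR -> RAS -> RAF -> MEK -> ERK
#> 2 MYC    EGFR       3 TRUE               EGFR -> PI3K -> AKT -> MYC
#> 3 S6K    PI3K       3 FALSE              PI3K -> AKT -> MTOR -> S6K
```

Two inputs steer all three targets; EGFR (drug-targetable, starred) starts
two paths of different lengths — allowed, because the layer condition only
forbids a node occurring in two paths at the *same* backward distance. The
genetic algorithm searches more broadly and finds the fully drug-targetable
pair:

```r
glance(ga_control(problem, seed = 1))[1, ]
#> # A tibble: 1 × 4
#>   solution n_inputs n_preferred inputs
#>      <int>    <int>       <int> <chr>
#> 1        1        2           2 EGFR*, MEK*

verify_solutions(net, sols)
#> # A tibble: 2 × 5
#>   solution n_inputs compatible  rank controllable
#>      <int>    <int> <lgl>      <int> <lgl>
#> 1        1        2 TRUE           3 TRUE
#> 2        2        2 TRUE           3 TRUE
```

`rank = 3 = |T|` confirms generic controllability of both solutions
independently of how they were constructed.

A command-line interface wrapping the same functions (subcommands
`generate`, `analyze greedy|ga`, `verify`, `simulate`; TSV/SIF edge lists,
plain-text node sets, versioned JSON solutions) is installed at
`inst/cli/netctrl`; see its header for usage.

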