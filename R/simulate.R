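#' Built-in toy controllability instances
#'
#' Small named instances with hand-checkable optima, used throughout the
#' documentation and tests:
#'
#' * `"chain"` — `a -> b -> c`, targets `{b, c}`; one input (`a`) suffices
#'   because it feeds the two targets at different backward layers.
#' * `"star"` — `a -> b`, `a -> c`, targets `{b, c}`; two inputs are
#'   needed (both paths from `a` would occupy it at layer 1).
#' * `"diamond"` — `u -> x -> t1`, `u -> y -> t2`, targets `{t1, t2}`;
#'   two inputs are needed.
#' * `"unequal"` — `u -> t1`, `u -> x -> t2`, targets `{t1, t2}`; the
#'   single input `u` works because the two path lengths differ.
#' * `"cycle"` — `a -> b -> a`, targets `{a, b}`.
#'
#' @param name one of `"chain"`, `"star"`, `"diamond"`, `"unequal"`,
#'   `"cycle"`.
#' @param max_path_length path-length cap for the bundled problem.
#' @return a list with elements `network` (a [network()]) and `problem`
#'   (a [control_problem()] with no preferred sources).
#' @examples
#' toy_fixture("chain")$network
#' @export
toy_fixture <- function(name = c("chain", "star", "diamond", "unequal", "cycle"),
                        max_path_length = 10L) {
  name <- match.arg(name)
  fx <- switch(name,
    chain = list(from = c("a", "b"), to = c("b", "c"), targets = c("b", "c")),
    star = list(from = c("a", "a"), to = c("b", "c"), targets = c("b", "c")),
    diamond = list(
      from = c("u", "x", "u", "y"), to = c("x", "t1", "y", "t2"),
      targets = c("t1", "t2")
    ),
    unequal = list(
      from = c("u", "u", "x"), to = c("t1", "x", "t2"),
      targets = c("t1", "t2")
    ),
    cycle = list(from = c("a", "b"), to = c("b", "a"), targets = c("a", "b"))
  )
  net <- network(data.frame(from = fx$from, to = fx$to))
  list(
    network = net,
    problem = control_problem(net, fx$targets,
      max_path_length = max_path_length
    )
  )
}

#' Random directed networks for simulation studies
#'
#' Two generators:
#'
#' * `model = "er"` — Erdős–Rényi style: every ordered pair of distinct
#'   nodes is an edge independently with probability `param`.
#' * `model = "pa"` — preferential attachment: starting from a small
#'   edgeless core of `max(2, param)` nodes, each new node sends `param`
#'   directed edges to distinct existing nodes sampled with probability
#'   proportional to in-degree + 1. The result has exactly
#'   `param * (n - max(2, param))` edges. This gives heavy-tailed
#'   in-degrees as a crude stand-in for protein-interaction topologies; no
#'   claim is made of matching any curated interactome.
#'
#' Both are fully deterministic for a fixed `seed`.
#'
#' @param n number of nodes, at least 2.
#' @param model `"er"` or `"pa"`.
#' @param param edge probability in `[0, 1]` (`er`) or out-edges per new
#'   node, a positive integer (`pa`).
#' @param seed integer seed.
#' @return a [network()] object; node identifiers are zero-padded
#'   (`"v01"`, ...), so lexicographic and numeric order agree.
#' @examples
#' random_digraph(10, "er", 0.2, seed = 1)
#' @export
random_digraph <- function(n, model = c("er", "pa"), param, seed = 1L) {
  n <- assert_count(n, "n", min = 2L)
  model <- match.arg(model)
  ids <- sprintf(paste0("v%0", nchar(as.character(n)), "d"), seq_len(n))
  withr::with_seed(seed, {
    if (model == "er") {
      stopifnot(param >= 0, param <= 1)
      pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      pairs <- pairs[pairs$from != pairs$to, ]
      pairs <- pairs[order(pairs$from, pairs$to), ]
      keep <- stats::runif(nrow(pairs)) < param
      network(
        data.frame(from = ids[pairs$from[keep]], to = ids[pairs$to[keep]]),
        nodes = ids
      )
    } else {
      param <- assert_count(param, "param", min = 1L)
      core <- max(2L, param)
      if (n <= core) rlang::abort("`n` must exceed the core size max(2, param)")
      from <- to <- integer(0)
      indeg <- rep(0L, n)
      for (v in seq(core + 1L, n)) {
        existing <- seq_len(v - 1L)
        tgt <- sample(existing, param, prob = indeg[existing] + 1)
        from <- c(from, rep(v, param))
        to <- c(to, tgt)
        indeg[tgt] <- indeg[tgt] + 1L
      }
      network(data.frame(from = ids[from], to = ids[to]), nodes = ids)
    }
  })
}

#' Sample a random controllability problem on a network
#'
#' Draws `n_targets` targets uniformly without replacement, then
#' `n_preferred` preferred sources from the remaining nodes.
#'
#' @param network a [network()] object.
#' @param n_targets number of targets, `1..n_nodes(network)`.
#' @param n_preferred number of preferred sources drawn from the non-target
#'   nodes. Default 0.
#' @param max_path_length path-length cap for the problem. Default 10.
#' @param seed integer seed; fixed seed gives an identical problem.
#' @return a [control_problem()] object.
#' @examples
#' sample_problem(random_digraph(10, "er", 0.3, seed = 1), 3, seed = 2)
#' @export
sample_problem <- function(network, n_targets, n_preferred = 0L,
                           max_path_length = 10L, seed = 1L) {
  stopifnot(inherits(network, "ctrl_network"))
  n_targets <- assert_count(n_targets, "n_targets")
  if (n_targets > n_nodes(network)) {
    rlang::abort("`n_targets` exceeds the number of nodes")
  }
  stopifnot(n_preferred >= 0, n_preferred <= n_nodes(network) - n_targets)
  withr::with_seed(seed, {
    targets <- sample(network$nodes, n_targets)
    rest <- setdiff(network$nodes, targets)
    pref <- if (n_preferred > 0) sample(rest, n_preferred) else character()
    control_problem(network, targets, pref, max_path_length = max_path_length)
  })
}
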