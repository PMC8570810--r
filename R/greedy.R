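#' Greedy target controllability analysis
#'
#' Finds a small set of input nodes controlling all targets by backward,
#' layer-by-layer extension of one control path (chain) per target. Each
#' chain starts at its target (backward layer 0). At layer
#' \eqn{d = 1, \dots, L} every still-active chain proposes its current
#' node's predecessors as candidate extensions; a maximum bipartite
#' matching between chains and candidates decides which chains extend (so
#' chains stay node-disjoint within each layer, preserving the
#' path-compatibility condition by construction). Unmatched chains
#' terminate and designate their current node as a control input at its
#' current layer.
#'
#' Candidate predecessors are preferred in this order: (1) nodes already
#' designated as inputs by terminated chains (reusing an input shrinks
#' \eqn{|I|}), (2) preferred sources, (3) higher out-degree, (4) a random
#' tie-break from the repeat's RNG stream. `repeats` independent randomized
#' restarts are run; distinct solutions (by input set) are returned sorted
#' by the objective: fewest inputs first, then most preferred inputs, then
#' lexicographic input ids.
#'
#' @param problem a [control_problem()] object.
#' @param repeats number of independent randomized restarts. Default 10.
#' @param max_solutions maximum number of distinct solutions returned.
#'   Default 10.
#' @param p_stop probability of terminating a chain early when its current
#'   node is a preferred source, even if extendable; 0 (the default)
#'   disables early stopping and makes each repeat's search fully driven by
#'   the matching.
#' @param seed integer seed controlling all randomization; identical
#'   `problem` + parameters + `seed` give identical output.
#' @return a `ctrl_solution_set`: ranked list of [control_solution()]
#'   objects with `$status` `"ok"`, or `"uncontrollable"` when no valid
#'   solution exists under the constraints (possible only when
#'   `allow_self_inputs = FALSE`).
#' @examples
#' fx <- toy_fixture("chain")
#' greedy_control(fx$problem, seed = 1)
#' @export
greedy_control <- function(problem, repeats = 10L, max_solutions = 10L,
                           p_stop = 0, seed = 1L) {
  stopifnot(inherits(problem, "ctrl_problem"))
  repeats <- assert_count(repeats, "repeats")
  max_solutions <- assert_count(max_solutions, "max_solutions")
  stopifnot(p_stop >= 0, p_stop <= 1)

  seeds <- derive_seeds(seed, repeats)
  sols <- list()
  for (r in seq_len(repeats)) {
    s <- withr::with_seed(seeds[r], greedy_once(problem, p_stop))
    if (!is.null(s)) sols[[length(sols) + 1L]] <- s
  }
  sols <- dedup_solutions(sols)
  sols <- sols[solution_order(sols)]
  sols <- utils::head(sols, max_solutions)
  out <- new_solution_set(
    sols,
    algorithm = "greedy",
    params = list(
      repeats = repeats, max_solutions = max_solutions,
      p_stop = p_stop, seed = seed,
      max_path_length = problem$max_path_length
    )
  )
  out$status <- if (length(sols)) "ok" else "uncontrollable"
  out
}

# One randomized greedy pass; uses the current RNG state. Returns a
# ctrl_solution, or NULL when self-inputs are forbidden and some chain was
# forced into one.
greedy_once <- function(problem, p_stop = 0) {
  net <- problem$network
  L <- problem$max_path_length
  targets <- problem$targets
  nt <- length(targets)
  t_idx <- node_index(net, targets)
  pref_idx <- node_index(net, problem$preferred_sources)
  is_pref <- logical(n_nodes(net))
  is_pref[pref_idx] <- TRUE
  outdeg <- lengths(net$succ)

  # chain state: reversed paths (target first), current node, active flag
  paths_rev <- lapply(t_idx, function(i) i)
  current <- t_idx
  active <- rep(TRUE, nt)
  input_nodes <- integer() # nodes already designated as inputs
  failed <- FALSE
  # occupancy keys node * (L + 1) + layer, for the defensive blocking check
  occ <- t_idx * (L + 1L)

  terminate <- function(c_id, layer) {
    u <- current[c_id]
    active[c_id] <<- FALSE
    input_nodes <<- union(input_nodes, u)
    if (!problem$allow_self_inputs && u == t_idx[c_id] &&
        net$nodes[u] == targets[c_id]) {
      failed <<- TRUE
    }
  }

  for (d in seq_len(L)) {
    act <- which(active)
    if (length(act) == 0) break

    if (p_stop > 0) {
      for (c_id in act) {
        if (is_pref[current[c_id]] && stats::runif(1) < p_stop) {
          terminate(c_id, d - 1L)
        }
      }
      act <- which(active)
      if (length(act) == 0) break
    }

    # candidate pairs (chain, predecessor) for layer d
    cand <- lapply(act, function(c_id) net$pred[[current[c_id]]])
    lens <- lengths(cand)
    pair_l <- rep(act, lens)
    pair_u <- unlist(cand, use.names = FALSE)
    if (length(pair_u)) {
      blocked <- (pair_u * (L + 1L) + d) %in% occ
      pair_l <- pair_l[!blocked]
      pair_u <- pair_u[!blocked]
    }
    if (length(pair_u) == 0) {
      for (c_id in act) terminate(c_id, d - 1L)
      break
    }
    rank_key <- order(
      -(pair_u %in% input_nodes), # reuse existing inputs first
      -is_pref[pair_u], # then preferred sources
      -outdeg[pair_u], # then high out-degree
      stats::runif(length(pair_u)) # random tie-break
    )
    pref_rank <- integer(length(pair_u))
    pref_rank[rank_key] <- seq_along(pair_u)

    m <- kuhn_match(
      li = match(pair_l, act), ri = pair_u,
      nl = length(act), nr = n_nodes(net), pref = pref_rank
    )
    matched_chain <- act[m[, 1]]
    matched_node <- m[, 2]
    for (j in seq_along(matched_chain)) {
      c_id <- matched_chain[j]
      u <- matched_node[j]
      paths_rev[[c_id]] <- c(paths_rev[[c_id]], u)
      current[c_id] <- u
      occ <- c(occ, u * (L + 1L) + d)
    }
    for (c_id in setdiff(act, matched_chain)) terminate(c_id, d - 1L)
  }
  for (c_id in which(active)) terminate(c_id, L)
  if (failed) {
    return(NULL)
  }

  paths <- lapply(paths_rev, function(p) net$nodes[rev(p)])
  names(paths) <- targets
  control_solution(problem, paths)
}
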