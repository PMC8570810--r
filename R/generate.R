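#' Build a subnetwork around seed nodes
#'
#' Extracts, from a full interaction universe, the subnetwork relevant to a
#' set of seed proteins. Three families of generation rules are available:
#'
#' * `"neighbors"` — keep every edge with at least one endpoint in the
#'   seed set (all interactions containing a seed).
#' * `"direct"` — keep only edges with both endpoints in the seed set.
#' * `"gap"` — keep an edge \eqn{(u, v)} when it lies on a directed walk
#'   \eqn{s \rightsquigarrow u \to v \rightsquigarrow s'} between seeds
#'   \eqn{s, s'} with at most `k` intermediary (non-seed) nodes, i.e. total
#'   edge length at most `k + 1`. `gap` with `k = 0` coincides with
#'   `direct`. The walk may start and end at the same seed.
#'
#' The gap rule is evaluated with the distance sandwich: with
#' \eqn{d_{out}(x)} the minimum distance from any seed to \eqn{x} and
#' \eqn{d_{in}(x)} the minimum distance from \eqn{x} to any seed, the edge
#' \eqn{(u,v)} is kept iff \eqn{d_{out}(u) + 1 + d_{in}(v) \le k + 1}.
#'
#' The result's node set consists of the endpoints of kept edges; seeds
#' incident to no kept edge are dropped. Seeds absent from the universe are
#' reported with a warning, not an error.
#'
#' @param interactions a [network()] object: the full interaction universe.
#' @param seeds nonempty character vector of seed node identifiers.
#' @param mode one of `"neighbors"`, `"direct"`, `"gap"`.
#' @param k number of intermediary nodes allowed, integer 0..4; used only
#'   when `mode = "gap"`.
#' @return a [network()] object.
#' @examples
#' u <- network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
#' generate_network(u, seeds = c("a", "c"), mode = "gap", k = 1)
#' @export
generate_network <- function(interactions, seeds,
                             mode = c("neighbors", "direct", "gap"), k = 1L) {
  stopifnot(inherits(interactions, "ctrl_network"))
  mode <- match.arg(mode)
  seeds <- unique(clean_ids(seeds, "seed identifier"))
  if (length(seeds) == 0) rlang::abort("the seed set is empty")

  missing <- setdiff(seeds, interactions$nodes)
  if (length(missing)) {
    rlang::warn(sprintf(
      "%d seed(s) not found in the interaction universe: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
  }
  seed_idx <- node_index(interactions, setdiff(seeds, missing))
  em <- interactions$edges
  keep <- switch(mode,
    neighbors = em[, 1] %in% seed_idx | em[, 2] %in% seed_idx,
    direct = em[, 1] %in% seed_idx & em[, 2] %in% seed_idx,
    gap = gap_keep(interactions, seed_idx, k)
  )
  subnetwork_from_edges(interactions, em[keep, , drop = FALSE])
}

gap_keep <- function(interactions, seed_idx, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k > 4 || k != as.integer(k)) {
    rlang::abort("`k` must be an integer between 0 and 4")
  }
  em <- interactions$edges
  if (length(seed_idx) == 0 || nrow(em) == 0) {
    return(rep(FALSE, nrow(em)))
  }
  g <- as_igraph(interactions)
  # d_out[x]: min unweighted distance seed -> x; d_in[x]: min distance x -> seed
  d_out <- suppressWarnings(
    apply(igraph::distances(g, v = seed_idx, mode = "out"), 2, min)
  )
  d_in <- suppressWarnings(
    apply(igraph::distances(g, v = seed_idx, mode = "in"), 2, min)
  )
  d_out[seed_idx] <- 0
  d_in[seed_idx] <- 0
  d_out[em[, 1]] + 1 + d_in[em[, 2]] <= k + 1
}

# Restrict a network to a subset of its edge matrix; nodes are the kept
# endpoints only.
subnetwork_from_edges <- function(interactions, em) {
  used <- sort(unique(as.vector(em)))
  nodes <- interactions$nodes[used]
  em2 <- cbind(match(em[, 1], used), match(em[, 2], used))
  if (nrow(em2) > 1) em2 <- em2[order(em2[, 1], em2[, 2]), , drop = FALSE]
  new_network(nodes, em2)
}

#' Union of interaction networks
#'
#' Combines the edge sets of several networks (e.g. several interaction
#' databases) into one universe; duplicate edges collapse.
#'
#' @param ... [network()] objects.
#' @return a [network()] object.
#' @export
network_union <- function(...) {
  nets <- list(...)
  stopifnot(length(nets) > 0, all(vapply(nets, inherits, logical(1), "ctrl_network")))
  edges <- dplyr::bind_rows(lapply(nets, as_tibble))
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  network(edges, nodes = nodes)
}
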