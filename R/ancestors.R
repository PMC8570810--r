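#' Ancestors of a target within a path-length cap
#'
#' Backward breadth-first exploration from a target: which nodes can reach
#' it by a directed walk of at most `max_path_length` edges, and at which
#' backward layers they can sit on such a walk. A node may be feasible at
#' several layers (e.g. around a cycle: on `a -> b -> a` with target `a`,
#' node `a` occurs at layers 0 and 2, node `b` at layers 1 and 3).
#'
#' @param network a [network()] object.
#' @param target a single node identifier.
#' @param max_path_length maximum walk length \eqn{L \ge 0}.
#' @return a tibble with columns `node`, `min_layer` (shortest walk
#'   length to the target) and `layers` (list column of all feasible
#'   layers `<= max_path_length`), ordered by `min_layer` then `node`.
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "a")))
#' ancestors_within(net, "a", 3)
#' @export
ancestors_within <- function(network, target, max_path_length) {
  stopifnot(inherits(network, "ctrl_network"), length(target) == 1)
  t_idx <- node_index(network, target)
  if (is.na(t_idx)) rlang::abort(sprintf("target '%s' is not in the network", target))
  L <- assert_count(max_path_length, "max_path_length", min = 0L)

  layer_sets <- backward_layers(network, t_idx, L)
  feas <- feasible_layers(layer_sets, n_nodes(network))
  nodes <- which(lengths(feas) > 0)
  out <- tibble::tibble(
    node = network$nodes[nodes],
    min_layer = vapply(feas[nodes], min, integer(1)),
    layers = feas[nodes]
  )
  dplyr::arrange(out, .data$min_layer, .data$node)
}

# layer_sets[[d + 1]]: sorted node indices occurring at backward layer d on
# some walk to the target (P_0 = {target}, P_d = predecessors of P_{d-1}).
backward_layers <- function(network, t_idx, L) {
  sets <- vector("list", L + 1L)
  sets[[1]] <- t_idx
  if (L >= 1) {
    for (d in seq_len(L)) {
      prev <- sets[[d]]
      nxt <- unlist(network$pred[prev], use.names = FALSE)
      sets[[d + 1L]] <- if (is.null(nxt)) integer() else sort(unique(nxt))
    }
  }
  sets
}

# Invert layer sets: per node, the integer vector of feasible layers.
feasible_layers <- function(layer_sets, n) {
  feas <- rep(list(integer()), n)
  for (d in seq_along(layer_sets)) {
    for (u in layer_sets[[d]]) feas[[u]] <- c(feas[[u]], d - 1L)
  }
  feas
}
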