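#' Directed interaction network
#'
#' A `ctrl_network` stores a directed graph over opaque, case-sensitive node
#' identifiers. It is the state space of the linear dynamics
#' \eqn{\dot x = A x + B u} on which all controllability computations run:
#' the structured state matrix \eqn{A} has \eqn{A_{ij}} generically nonzero
#' if and only if the edge \eqn{j \to i} is present.
#'
#' Edges are a set: parallel duplicates collapse; self-loops are kept.
#' Isolated nodes are allowed (pass them via `nodes`).
#'
#' @param edges a data frame whose first two columns are the source and
#'   target identifier of one directed edge per row (extra columns, e.g. a
#'   SIF relation, are ignored), or a two-column character matrix.
#' @param nodes optional character vector of node identifiers; the union of
#'   edge endpoints and `nodes` becomes the node set.
#' @return an object of class `ctrl_network`.
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net
#' dplyr::as_tibble(net)
#' @export
network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    from <- character()
    to <- character()
  } else if (is.matrix(edges)) {
    stopifnot(ncol(edges) >= 2)
    from <- clean_ids(edges[, 1])
    to <- clean_ids(edges[, 2])
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2) rlang::abort("`edges` needs at least two columns (from, to)")
    from <- clean_ids(edges[[1]])
    to <- clean_ids(edges[[2]])
  }
  nodes <- sort(unique(c(from, to, if (!is.null(nodes)) clean_ids(nodes))))
  em <- cbind(match(from, nodes), match(to, nodes))
  em <- unique(em)
  if (nrow(em) > 1) em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  new_network(nodes, em)
}

# Low-level constructor: `nodes` a sorted unique character vector, `em` an
# integer edge matrix (from, to) already deduplicated.
new_network <- function(nodes, em) {
  storage.mode(em) <- "integer"
  n <- length(nodes)
  pred <- succ <- rep(list(integer()), n)
  if (nrow(em) > 0) {
    succ_split <- split(em[, 2], factor(em[, 1], levels = seq_len(n)))
    pred_split <- split(em[, 1], factor(em[, 2], levels = seq_len(n)))
    succ <- lapply(succ_split, function(v) sort(unname(v)))
    pred <- lapply(pred_split, function(v) sort(unname(v)))
  }
  structure(
    list(nodes = nodes, edges = em, pred = pred, succ = succ),
    class = "ctrl_network"
  )
}

#' @export
print.ctrl_network <- function(x, ...) {
  cat(sprintf(
    "<ctrl_network> %d nodes, %d directed edges\n",
    n_nodes(x), n_edges(x)
  ))
  if (n_edges(x) > 0) {
    show <- utils::head(as_tibble(x), 5)
    cat(paste0("  ", show$from, " -> ", show$to, collapse = "\n"), "\n")
    if (n_edges(x) > 5) cat(sprintf("  ... %d more\n", n_edges(x) - 5L))
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param network a [network()] object.
#' @return an integer.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Edge list of a network as a tibble
#'
#' @param x a [network()] object.
#' @param ... unused.
#' @return a tibble with character columns `from` and `to`, one row per
#'   directed edge.
#' @method as_tibble ctrl_network
#' @export
as_tibble.ctrl_network <- function(x, ...) {
  tibble::tibble(
    from = x$nodes[x$edges[, 1]],
    to = x$nodes[x$edges[, 2]]
  )
}

#' Convert to an igraph object
#'
#' @param network a [network()] object.
#' @return an [igraph::graph] with the same nodes and directed edges.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as_tibble(network),
    directed = TRUE,
    vertices = network$nodes
  )
}

#' Node degrees
#'
#' In- and out-degree of every node, counting each distinct directed edge
#' once (a self-loop contributes to both).
#'
#' @param network a [network()] object.
#' @return a tibble with columns `node`, `in_degree`, `out_degree`.
#' @export
node_degrees <- function(network) {
  tibble::tibble(
    node = network$nodes,
    in_degree = unname(lengths(network$pred)),
    out_degree = unname(lengths(network$succ))
  )
}

# Map identifiers to integer node indices; unknown ids give NA.
node_index <- function(network, ids) match(ids, network$nodes)

has_node <- function(network, ids) ids %in% network$nodes
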