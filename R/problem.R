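#' Define a target controllability problem
#'
#' Bundles a directed network with the set of target nodes \eqn{T} that must
#' be steered, an optional set of preferred source nodes \eqn{S} (typically
#' drug-targetable proteins, favoured as control inputs), and the cap
#' \eqn{L} on control-path length (layers of backward extension from each
#' target).
#'
#' Identifiers in `targets` or `preferred_sources` that do not occur in the
#' network are dropped with a warning (or rejected when `strict = TRUE`);
#' the dropped ids are kept on the object and reported by
#' [validate_problem()].
#'
#' @param network a [network()] object.
#' @param targets character vector of target node identifiers (nonempty
#'   after dropping unknowns).
#' @param preferred_sources character vector of preferred source
#'   identifiers; may be empty.
#' @param max_path_length positive integer \eqn{L}: maximum number of edges
#'   in a control path. Default 10.
#' @param allow_self_inputs may a target serve as its own control input
#'   (a path of length 0)? Default `TRUE`. When `FALSE`, no control path
#'   may have its input equal to its target.
#' @param strict error (instead of warn and drop) on unknown identifiers.
#' @return an object of class `ctrl_problem`.
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' control_problem(net, targets = c("b", "c"))
#' @export
control_problem <- function(network, targets, preferred_sources = character(),
                            max_path_length = 10L, allow_self_inputs = TRUE,
                            strict = FALSE) {
  stopifnot(inherits(network, "ctrl_network"))
  targets <- unique(clean_ids(targets, "target identifier"))
  preferred_sources <- if (length(preferred_sources)) {
    unique(clean_ids(preferred_sources, "source identifier"))
  } else {
    character()
  }
  L <- assert_count(max_path_length, "max_path_length", min = 1L)

  unknown_targets <- setdiff(targets, network$nodes)
  unknown_sources <- setdiff(preferred_sources, network$nodes)
  if (length(unknown_targets) || length(unknown_sources)) {
    msg <- sprintf(
      "identifiers not in the network: %s",
      paste(c(unknown_targets, unknown_sources), collapse = ", ")
    )
    if (strict) rlang::abort(msg) else rlang::warn(paste(msg, "(dropped)"))
  }
  targets <- setdiff(targets, unknown_targets)
  preferred_sources <- setdiff(preferred_sources, unknown_sources)
  if (length(targets) == 0) {
    rlang::abort("the target set is empty (after dropping unknown identifiers)")
  }

  structure(
    list(
      network = network,
      targets = sort(targets),
      preferred_sources = sort(preferred_sources),
      max_path_length = L,
      allow_self_inputs = isTRUE(allow_self_inputs),
      unknown_targets = unknown_targets,
      unknown_sources = unknown_sources
    ),
    class = "ctrl_problem"
  )
}

#' @export
print.ctrl_problem <- function(x, ...) {
  cat(sprintf(
    "<ctrl_problem> %d nodes, %d edges | %d targets, %d preferred sources, L = %d\n",
    n_nodes(x$network), n_edges(x$network),
    length(x$targets), length(x$preferred_sources), x$max_path_length
  ))
  invisible(x)
}

#' Validate a controllability problem
#'
#' Checks that every identifier resolves in the network and flags targets
#' that cannot be reached from anywhere: a target with in-degree 0 can only
#' be controlled by placing an input on the target itself.
#'
#' @param problem a [control_problem()] object.
#' @return a tibble with columns `check` (one of `"unknown_target"`,
#'   `"unknown_source"`, `"only_self_controllable"`), `node`, and `message`.
#'   Zero rows means the problem is clean.
#' @examples
#' net <- network(data.frame(from = c("a", "a"), to = c("b", "c")))
#' validate_problem(control_problem(net, targets = "a"))
#' @export
validate_problem <- function(problem) {
  stopifnot(inherits(problem, "ctrl_problem"))
  net <- problem$network
  report <- list(
    tibble::tibble(
      check = "unknown_target", node = problem$unknown_targets,
      message = sprintf("target '%s' is not in the network", problem$unknown_targets)
    ),
    tibble::tibble(
      check = "unknown_source", node = problem$unknown_sources,
      message = sprintf("preferred source '%s' is not in the network", problem$unknown_sources)
    )
  )
  t_idx <- node_index(net, problem$targets)
  indeg <- lengths(net$pred)[t_idx]
  lonely <- problem$targets[indeg == 0]
  report <- c(report, list(tibble::tibble(
    check = "only_self_controllable", node = lonely,
    message = sprintf(
      "target '%s' has in-degree 0, only self-controllable", lonely
    )
  )))
  dplyr::arrange(dplyr::bind_rows(report), .data$check, .data$node)
}
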