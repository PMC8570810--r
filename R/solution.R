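#' Control solutions and path compatibility
#'
#' A control solution assigns to every target exactly one control path: a
#' directed walk from an input node \eqn{u_0} to the target
#' \eqn{u_m = t}, every consecutive pair being an edge and \eqn{m \le L}.
#' The *backward layer* of \eqn{u_i} within its path is \eqn{m - i}: the
#' target sits at layer 0, the input at layer \eqn{m}.
#'
#' A set of paths is a valid solution when it satisfies the
#' *path-compatibility (layer) condition*: no node is occupied by two
#' different paths at the same backward layer. A single input node may
#' start several paths only if their lengths all differ. This condition is
#' sufficient for generic target controllability and is what
#' [target_generic_rank()] verifies independently.
#'
#' @param problem a [control_problem()] object.
#' @param paths a named list, one element per target (names are the target
#'   ids), each a character vector of node identifiers from the input to
#'   the target.
#' @return an object of class `ctrl_solution` with elements `paths`,
#'   `inputs`, `preferred_inputs` and `objective` (the pair
#'   \eqn{(|I|, -|I \cap S|)}, compared lexicographically, smaller better).
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' pr <- control_problem(net, targets = c("b", "c"))
#' sol <- control_solution(pr, list(b = c("a", "b"), c = c("a", "b", "c")))
#' check_path_compatibility(sol)
#' @export
control_solution <- function(problem, paths) {
  stopifnot(inherits(problem, "ctrl_problem"))
  net <- problem$network
  if (!setequal(names(paths), problem$targets) ||
      length(paths) != length(problem$targets)) {
    rlang::abort("`paths` must have exactly one element per target")
  }
  paths <- paths[sort(names(paths))]
  for (tgt in names(paths)) {
    p <- paths[[tgt]]
    if (p[length(p)] != tgt) {
      rlang::abort(sprintf("path for target '%s' does not end at it", tgt))
    }
    if (length(p) - 1L > problem$max_path_length) {
      rlang::abort(sprintf(
        "path for target '%s' has length %d > L = %d",
        tgt, length(p) - 1L, problem$max_path_length
      ))
    }
    validate_walk(net, p)
    if (!problem$allow_self_inputs && p[1] == tgt) {
      rlang::abort(sprintf(
        "target '%s' is its own input but self-inputs are forbidden", tgt
      ))
    }
  }
  inputs <- sort(unique(vapply(paths, function(p) p[1], character(1))))
  preferred <- intersect(inputs, problem$preferred_sources)
  structure(
    list(
      paths = paths,
      inputs = inputs,
      preferred_inputs = preferred,
      objective = c(n_inputs = length(inputs), n_preferred = length(preferred)),
      targets = sort(names(paths)),
      preferred_sources = problem$preferred_sources
    ),
    class = "ctrl_solution"
  )
}

# Hard error naming the offending step if `p` is not a walk in `net`.
validate_walk <- function(net, p) {
  idx <- node_index(net, p)
  if (anyNA(idx)) {
    rlang::abort(sprintf(
      "path node '%s' is not in the network", p[which(is.na(idx))[1]]
    ))
  }
  if (length(idx) > 1) {
    for (i in seq_len(length(idx) - 1L)) {
      if (!(idx[i + 1L] %in% net$succ[[idx[i]]])) {
        rlang::abort(sprintf(
          "path step %s -> %s is not an edge of the network", p[i], p[i + 1L]
        ))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.ctrl_solution <- function(x, ...) {
  cat(sprintf(
    "<ctrl_solution> %d inputs (%d preferred) controlling %d targets\n",
    length(x$inputs), length(x$preferred_inputs), length(x$paths)
  ))
  for (tgt in names(x$paths)) {
    cat("  ", paste(x$paths[[tgt]], collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

# Occupancy table: one row per (path, node, layer).
path_occupancy <- function(paths) {
  occ <- lapply(names(paths), function(tgt) {
    p <- paths[[tgt]]
    m <- length(p) - 1L
    tibble::tibble(target = tgt, node = p, layer = m - seq_along(p) + 1L)
  })
  dplyr::bind_rows(occ)
}

#' Check the path-compatibility (layer) condition
#'
#' Enumerates every violation of the layer condition (see
#' [control_solution()]): pairs of distinct paths that occupy the same node
#' at the same backward layer.
#'
#' @param solution a [control_solution()] object.
#' @return a tibble with columns `node`, `layer`, `path1`, `path2` (the
#'   target ids naming the two conflicting paths), ordered by node id then
#'   layer. Zero rows means the solution is compatible.
#' @export
check_path_compatibility <- function(solution) {
  stopifnot(inherits(solution, "ctrl_solution"))
  occ <- path_occupancy(solution$paths)
  key <- paste(occ$node, occ$layer, sep = "\x1f")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) == 0) {
    return(tibble::tibble(
      node = character(), layer = integer(),
      path1 = character(), path2 = character()
    ))
  }
  out <- purrr::map_dfr(dup_keys, function(k) {
    sub <- occ[key == k, ]
    cmb <- utils::combn(sort(sub$target), 2)
    tibble::tibble(
      node = sub$node[1], layer = sub$layer[1],
      path1 = cmb[1, ], path2 = cmb[2, ]
    )
  })
  dplyr::arrange(out, .data$node, .data$layer, .data$path1, .data$path2)
}

# Lexicographic objective order: |I| ascending, |I n S| descending, then
# input ids; returns an ordering permutation for a list of solutions.
solution_order <- function(solutions) {
  n_in <- vapply(solutions, function(s) length(s$inputs), integer(1))
  n_pref <- vapply(solutions, function(s) length(s$preferred_inputs), integer(1))
  key <- vapply(solutions, function(s) paste(s$inputs, collapse = "\x1f"), character(1))
  order(n_in, -n_pref, key)
}

# Deduplicate solutions by input set, keeping first occurrence.
dedup_solutions <- function(solutions) {
  key <- vapply(solutions, function(s) paste(s$inputs, collapse = "\x1f"), character(1))
  solutions[!duplicated(key)]
}

# Container for a ranked list of solutions plus run metadata.
new_solution_set <- function(solutions, algorithm, params) {
  structure(
    list(solutions = solutions, algorithm = algorithm, params = params),
    class = "ctrl_solution_set"
  )
}

#' @export
print.ctrl_solution_set <- function(x, ...) {
  cat(sprintf(
    "<ctrl_solution_set> %d solution(s) from '%s'\n",
    length(x$solutions), x$algorithm
  ))
  if (length(x$solutions)) print(glance(x))
  invisible(x)
}

#' @export
length.ctrl_solution_set <- function(x) length(x$solutions)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a control solution into one row per path
#'
#' @param x a [control_solution()] or solution set returned by
#'   [greedy_control()] / [ga_control()].
#' @param ... unused.
#' @return a tibble with columns `target`, `input`, `length`,
#'   `input_is_preferred` and `path` (nodes collapsed with `" -> "`); for a
#'   solution set, an extra leading `solution` index column.
#' @method tidy ctrl_solution
#' @export
tidy.ctrl_solution <- function(x, ...) {
  inputs <- unname(vapply(x$paths, function(p) p[1], character(1)))
  tibble::tibble(
    target = names(x$paths),
    input = inputs,
    length = unname(lengths(x$paths)) - 1L,
    input_is_preferred = inputs %in% x$preferred_sources,
    path = unname(vapply(x$paths, paste, character(1), collapse = " -> "))
  )
}

#' @rdname tidy.ctrl_solution
#' @method tidy ctrl_solution_set
#' @export
tidy.ctrl_solution_set <- function(x, ...) {
  purrr::imap_dfr(
    x$solutions,
    function(s, i) dplyr::mutate(tidy(s), solution = i, .before = 1)
  )
}

#' Summarise solutions: one row per solution
#'
#' @param x a [control_solution()] or a solution set.
#' @param ... unused.
#' @return a tibble with columns `n_inputs`, `n_preferred`, `inputs`
#'   (comma-collapsed ids, preferred ones marked with `*`); for a solution
#'   set, a leading `solution` index column.
#' @method glance ctrl_solution
#' @export
glance.ctrl_solution <- function(x, ...) {
  marked <- ifelse(x$inputs %in% x$preferred_inputs,
    paste0(x$inputs, "*"), x$inputs
  )
  tibble::tibble(
    n_inputs = length(x$inputs),
    n_preferred = length(x$preferred_inputs),
    inputs = paste(marked, collapse = ", ")
  )
}

#' @rdname glance.ctrl_solution
#' @method glance ctrl_solution_set
#' @export
glance.ctrl_solution_set <- function(x, ...) {
  purrr::imap_dfr(
    x$solutions,
    function(s, i) dplyr::mutate(glance(s), solution = i, .before = 1)
  )
}
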