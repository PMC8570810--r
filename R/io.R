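#' Read and write directed networks
#'
#' Two plain-text formats are supported. Orientation is always "first
#' column is the edge source, last the edge target".
#'
#' * `"tsv"` — one directed edge per line, two tab-separated identifier
#'   columns. Lines starting with `#` and blank lines are skipped;
#'   duplicate edges collapse.
#' * `"sif"` — simple interaction format: `source relation target ...`,
#'   whitespace-delimited; the relation column is ignored for the control
#'   semantics (activation/inhibition signs carry no meaning here); lines
#'   with several targets yield one edge per target.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`; default guessed from the file
#'   extension, falling back to `"tsv"`.
#' @param undirected_as_bidirectional also add the reverse of every edge
#'   (for sources that record undirected interactions). Default `FALSE`.
#' @return `read_network()`: a [network()] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("a\tb", "b\tc"), f)
#' read_network(f)
#' @export
read_network <- function(path, format = NULL, undirected_as_bidirectional = FALSE) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  format <- format %||%
    (if (tolower(tools::file_ext(path)) == "sif") "sif" else "tsv")
  format <- match.arg(format, c("tsv", "sif"))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    rlang::abort(sprintf("no edges found in %s (empty network)", path))
  }
  from <- character(length(keep))
  to_list <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    fields <- strsplit(trimws(lines[ln]), if (format == "tsv") "\t" else "[ \t]+")[[1]]
    min_fields <- if (format == "tsv") 2L else 3L
    if (length(fields) < min_fields || any(trimws(fields) == "")) {
      rlang::abort(sprintf(
        "malformed %s line %d in %s: '%s'", format, ln, path, lines[ln]
      ))
    }
    from[j] <- fields[1]
    to_list[[j]] <- if (format == "tsv") fields[2] else fields[-(1:2)]
  }
  lens <- lengths(to_list)
  edges <- data.frame(
    from = rep(from, lens),
    to = unlist(to_list, use.names = FALSE)
  )
  if (undirected_as_bidirectional) {
    edges <- rbind(edges, data.frame(from = edges$to, to = edges$from))
  }
  network(edges)
}

#' @rdname read_network
#' @param network a [network()] object to write.
#' @param relation relation label used in the `sif` output column.
#' @return `write_network()`: the path, invisibly.
#' @export
write_network <- function(network, path, format = NULL, relation = "interacts") {
  stopifnot(inherits(network, "ctrl_network"))
  format <- format %||%
    (if (tolower(tools::file_ext(path)) == "sif") "sif" else "tsv")
  format <- match.arg(format, c("tsv", "sif"))
  ed <- as_tibble(network)
  lines <- if (format == "tsv") {
    paste(ed$from, ed$to, sep = "\t")
  } else {
    paste(ed$from, relation, ed$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write node-identifier sets
#'
#' One identifier per line; surrounding whitespace is trimmed, blank lines
#' and lines starting with `#` are skipped, duplicates collapse.
#'
#' @param path file path.
#' @return `read_node_set()`: a character vector (an error if empty).
#' @examples
#' f <- tempfile()
#' writeLines(c("b", "", "# note", "c", "b"), f)
#' read_node_set(f)
#' @export
read_node_set <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[!grepl("^(#|$)", lines)])
  if (length(ids) == 0) {
    rlang::abort(sprintf("no identifiers found in %s", path))
  }
  ids
}

#' @rdname read_node_set
#' @param ids character vector of identifiers to write.
#' @return `write_node_set()`: the path, invisibly.
#' @export
write_node_set <- function(ids, path) {
  writeLines(clean_ids(ids), path)
  invisible(path)
}

SOLUTION_SCHEMA_VERSION <- "1.0"

#' Write and read control solutions as JSON
#'
#' Serializes a solution set to a versioned JSON document carrying the run
#' metadata (algorithm, parameters, seed, objective definition) and, per
#' solution, the input nodes with their preferred (drug-targetable) flag,
#' one control path per target, and the objective values. Reading back
#' against the same problem reproduces the solution set exactly.
#'
#' @param solutions a `ctrl_solution_set` from [greedy_control()] or
#'   [ga_control()].
#' @param path output file path.
#' @return `write_solutions()`: the path, invisibly.
#' @export
write_solutions <- function(solutions, path) {
  stopifnot(inherits(solutions, "ctrl_solution_set"))
  doc <- list(
    schema_version = SOLUTION_SCHEMA_VERSION,
    algorithm = solutions$algorithm,
    status = solutions$status %||% "ok",
    objective = "minimize (n_inputs, -n_preferred_inputs) lexicographically",
    parameters = solutions$params,
    solutions = lapply(solutions$solutions, function(s) {
      list(
        inputs = lapply(s$inputs, function(id) {
          list(id = id, is_preferred = id %in% s$preferred_inputs)
        }),
        paths = lapply(names(s$paths), function(tgt) {
          list(target = tgt, input = s$paths[[tgt]][1], nodes = I(s$paths[[tgt]]))
        }),
        objective = list(
          n_inputs = length(s$inputs),
          n_preferred = length(s$preferred_inputs)
        )
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solutions
#' @param problem the [control_problem()] the solutions belong to; used to
#'   re-validate paths on read.
#' @return `read_solutions()`: a `ctrl_solution_set`.
#' @export
read_solutions <- function(path, problem) {
  stopifnot(inherits(problem, "ctrl_problem"))
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema_version, SOLUTION_SCHEMA_VERSION)) {
    rlang::abort(sprintf(
      "unsupported solution schema version '%s'", doc$schema_version %||% "?"
    ))
  }
  sols <- lapply(doc$solutions, function(s) {
    paths <- stats::setNames(
      lapply(s$paths, function(p) unlist(p$nodes)),
      vapply(s$paths, `[[`, character(1), "target")
    )
    control_solution(problem, paths)
  })
  out <- new_solution_set(sols, algorithm = doc$algorithm, params = doc$parameters)
  out$status <- doc$status %||% "ok"
  out
}
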