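# Shared test utilities: random instances and independent re-implementations
# used as oracles against the package's own code paths.

# A random Erdos-Renyi control problem; all randomness is seed-derived.
random_instance <- function(seed, n = 20, p = 0.1, n_targets = 5, n_preferred = 3,
                            L = 10) {
  net <- random_digraph(n, "er", p, seed = seed)
  sample_problem(net, n_targets, n_preferred, max_path_length = L, seed = seed + 1L)
}

# Brute-force layer-condition check, independent of check_path_compatibility:
# enumerate all (path, node, layer) triples with nested loops and compare
# every pair of paths directly.
naive_compatible <- function(paths) {
  occ <- list()
  for (tgt in names(paths)) {
    p <- paths[[tgt]]
    m <- length(p) - 1L
    for (i in seq_along(p)) {
      occ[[length(occ) + 1L]] <- list(tgt = tgt, node = p[i], layer = m - i + 1L)
    }
  }
  if (length(occ) < 2) {
    return(TRUE)
  }
  for (i in seq_len(length(occ) - 1L)) {
    for (j in seq(i + 1L, length(occ))) {
      if (occ[[i]]$tgt != occ[[j]]$tgt &&
          occ[[i]]$node == occ[[j]]$node &&
          occ[[i]]$layer == occ[[j]]$layer) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Independent maximum-matching cardinality via igraph's bipartite matching.
igraph_matching_size <- function(left, right, pairs) {
  if (nrow(pairs) == 0) {
    return(0L)
  }
  lv <- paste0("L_", unique(left))
  rv <- paste0("R_", unique(right))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("L_", pairs[[1]]), to = paste0("R_", pairs[[2]])),
    directed = FALSE,
    vertices = data.frame(name = c(lv, rv), type = c(rep(FALSE, length(lv)),
                                                     rep(TRUE, length(rv))))
  )
  igraph::max_bipartite_match(g)$matching_size
}

expect_valid_solution_set <- function(sols, problem, check_rank = TRUE) {
  expect_s3_class(sols, "ctrl_solution_set")
  for (s in sols$solutions) {
    expect_identical(sort(names(s$paths)), problem$targets)
    expect_equal(nrow(check_path_compatibility(s)), 0)
    expect_lte(length(s$inputs), length(problem$targets))
    if (check_rank) {
      expect_identical(
        target_generic_rank(problem$network, s$inputs, problem$targets),
        length(problem$targets)
      )
    }
  }
}
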