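universe <- function() {
  network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
}

test_that("neighbors mode keeps edges touching any seed", {
  out <- generate_network(universe(), seeds = c("a", "c"), mode = "neighbors")
  expect_identical(as_tibble(out)$from, c("a", "b", "c"))
  expect_identical(as_tibble(out)$to, c("b", "c", "d"))
})

test_that("direct mode keeps only seed-to-seed edges", {
  out <- generate_network(universe(), seeds = c("a", "c"), mode = "direct")
  expect_identical(n_edges(out), 0L)
  out2 <- generate_network(universe(), seeds = c("b", "c"), mode = "direct")
  expect_identical(as_tibble(out2), tibble::tibble(from = "b", to = "c"))
})

test_that("gap mode keeps edges on short seed-to-seed walks", {
  out <- generate_network(universe(), seeds = c("a", "c"), mode = "gap", k = 1)
  expect_identical(as_tibble(out)$from, c("a", "b"))
  expect_identical(as_tibble(out)$to, c("b", "c"))
  # k = 0 means no intermediaries: identical to direct
  g0 <- generate_network(universe(), seeds = c("a", "c"), mode = "gap", k = 0)
  d <- generate_network(universe(), seeds = c("a", "c"), mode = "direct")
  expect_identical(as_tibble(g0), as_tibble(d))
})

test_that("a cycle through a single seed qualifies as a seed-to-seed walk", {
  u <- network(data.frame(from = c("s", "x"), to = c("x", "s")))
  out <- generate_network(u, seeds = "s", mode = "gap", k = 1)
  expect_identical(n_edges(out), 2L)
})

test_that("absent seeds warn, empty seed set and bad k error", {
  expect_warning(
    out <- generate_network(universe(), seeds = c("a", "nope"), mode = "neighbors"),
    "nope"
  )
  expect_identical(n_edges(out), 1L)
  expect_error(generate_network(universe(), seeds = character(), mode = "direct"), "empty")
  expect_error(generate_network(universe(), seeds = "a", mode = "gap", k = 5), "0 and 4")
  expect_error(generate_network(universe(), seeds = "a", mode = "gap", k = -1), "0 and 4")
})

test_that("generation algebra holds on random universes", {
  for (seed in 1:30) {
    u <- random_digraph(25, "er", 0.08, seed = seed)
    seeds <- withr::with_seed(seed, sample(u$nodes, 5))
    nb <- generate_network(u, seeds, mode = "neighbors")
    di <- generate_network(u, seeds, mode = "direct")
    # direct edges are a subset of neighbors edges
    expect_true(nrow(dplyr::anti_join(as_tibble(di), as_tibble(nb),
      by = c("from", "to")
    )) == 0)
    # gap(0) coincides with direct exactly
    g_prev <- generate_network(u, seeds, mode = "gap", k = 0)
    expect_identical(as_tibble(g_prev), as_tibble(di))
    # gap(k) is monotone in k
    for (k in 1:4) {
      g_k <- generate_network(u, seeds, mode = "gap", k = k)
      expect_true(nrow(dplyr::anti_join(as_tibble(g_prev), as_tibble(g_k),
        by = c("from", "to")
      )) == 0)
      g_prev <- g_k
    }
    # idempotence: regenerating from the result changes nothing
    for (mode in c("neighbors", "direct")) {
      g1 <- generate_network(u, seeds, mode = mode)
      if (n_edges(g1) > 0) {
        g2 <- suppressWarnings(generate_network(g1, seeds, mode = mode))
        expect_identical(as_tibble(g2), as_tibble(g1))
      }
    }
    g1 <- generate_network(u, seeds, mode = "gap", k = 2)
    if (n_edges(g1) > 0) {
      g2 <- suppressWarnings(generate_network(g1, seeds, mode = "gap", k = 2))
      expect_identical(as_tibble(g2), as_tibble(g1))
    }
  }
})
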