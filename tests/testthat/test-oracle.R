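test_that("modular arithmetic primitives are exact near the word boundary", {
  p <- 2147483647
  # (p-1)^2 = 1 mod p, and agreement with native products in the exact range
  expect_identical(netctrl:::mulmod(p - 1, p - 1, p), 1)
  expect_identical(netctrl:::mulmod(0, p - 1, p), 0)
  a <- c(12345, 7, 99991)
  b <- c(54321, 13, 12343)
  expect_identical(netctrl:::mulmod(a, b, p), (a * b) %% p)
  # Fermat: a^(p-1) = 1 mod p for prime p
  expect_identical(netctrl:::powmod(1234567, p - 1, p), 1)
  expect_identical(netctrl:::powmod(2, 10, 1009), 1024 %% 1009)
})

test_that("modular rank matches known ranks on structured matrices", {
  p <- 2147483647
  expect_identical(netctrl:::mod_rank(diag(3), p), 3L)
  M <- rbind(c(1, 2, 3), c(2, 4, 6), c(0, 1, 1)) # row 2 = 2 * row 1
  expect_identical(netctrl:::mod_rank(M, p), 2L)
  expect_identical(netctrl:::mod_rank(matrix(0, 2, 4), p), 0L)
})

test_that("generic rank separates the chain and star instances", {
  ch <- toy_fixture("chain")
  expect_identical(target_generic_rank(ch$network, "a", c("b", "c")), 2L)
  st <- toy_fixture("star")
  expect_identical(target_generic_rank(st$network, "a", c("b", "c")), 1L)
  # an input placed on the target itself always contributes rank 1
  expect_identical(target_generic_rank(ch$network, "b", "b"), 1L)
  # unequal-length branches: a single input column controls both targets
  un <- toy_fixture("unequal")
  expect_identical(target_generic_rank(un$network, "u", c("t1", "t2")), 2L)
  # diamond: u alone reaches both targets at the same distance, rank 1
  di <- toy_fixture("diamond")
  expect_identical(target_generic_rank(di$network, "u", c("t1", "t2")), 1L)
})

test_that("rank with inputs everywhere is always |targets|", {
  for (seed in 1:10) {
    net <- random_digraph(8, "er", 0.2, seed = seed)
    targets <- withr::with_seed(seed, sample(net$nodes, 3))
    expect_identical(
      target_generic_rank(net, net$nodes, targets), 3L
    )
  }
})

test_that("rank is monotone in the input set", {
  for (seed in 1:15) {
    net <- random_digraph(9, "er", 0.2, seed = seed)
    sets <- withr::with_seed(seed, {
      targets <- sample(net$nodes, 3)
      small <- sample(net$nodes, 2)
      big <- union(small, sample(net$nodes, 3))
      list(targets = targets, small = small, big = big)
    })
    expect_lte(
      target_generic_rank(net, sets$small, sets$targets),
      target_generic_rank(net, sets$big, sets$targets)
    )
  }
})

test_that("draw count does not change the verdict", {
  for (seed in 1:10) {
    net <- random_digraph(8, "er", 0.25, seed = seed)
    io <- withr::with_seed(seed, list(
      inputs = sample(net$nodes, 2), targets = sample(net$nodes, 3)
    ))
    expect_identical(
      target_generic_rank(net, io$inputs, io$targets, draws = 3, seed = seed),
      target_generic_rank(net, io$inputs, io$targets, draws = 6, seed = seed)
    )
  }
})

test_that("brute force finds the known minima on the toys", {
  ch <- toy_fixture("chain")
  bf <- brute_force_minimum_inputs(ch$network, c("b", "c"))
  expect_identical(bf$size, 1L)
  expect_identical(bf$inputs, "a")

  st <- toy_fixture("star")
  bf2 <- brute_force_minimum_inputs(st$network, c("b", "c"))
  expect_identical(bf2$size, 2L)
  expect_identical(bf2$inputs, c("a", "b")) # first size-2 witness in lex order

  di <- toy_fixture("diamond")
  bf3 <- brute_force_minimum_inputs(di$network, c("t1", "t2"))
  expect_identical(bf3$size, 2L)
})

test_that("brute force respects its guards and restriction options", {
  expect_error(
    brute_force_minimum_inputs(random_digraph(13, "er", 0.1, 1), "v01"),
    "12 nodes"
  )
  st <- toy_fixture("star")
  # excluding targets from the pool leaves only a, insufficient for rank 2
  out <- brute_force_minimum_inputs(st$network, c("b", "c"),
    allow_self_inputs = FALSE
  )
  expect_identical(out$size, Inf)
  expect_identical(out$inputs, character())
  out2 <- brute_force_minimum_inputs(st$network, c("b", "c"),
    restrict_to = c("a", "c")
  )
  expect_identical(out2$inputs, c("a", "c"))
})

test_that("prime guard rejects moduli smaller than n^2", {
  net <- random_digraph(10, "er", 0.2, seed = 1)
  expect_error(target_generic_rank(net, "v01", "v02", prime = 97), "prime")
})

test_that("verify_solutions confirms greedy output end to end", {
  pr <- random_instance(3, n = 10, p = 0.2, n_targets = 3)
  v <- verify_solutions(pr$network, greedy_control(pr, seed = 3))
  expect_true(all(v$compatible))
  expect_true(all(v$controllable))
})
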