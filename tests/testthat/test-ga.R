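test_that("decoding builds shortest walks and detects conflicts", {
  ch <- toy_fixture("chain")
  d <- decode_chromosome(ch$problem, c(b = "a", c = "a"))
  expect_identical(d$conflicts, 0L)
  expect_identical(d$solution$inputs, "a")

  # star: both walks would place a at layer 1 and no alternative layer exists
  st <- toy_fixture("star")
  d2 <- decode_chromosome(st$problem, c(b = "a", c = "a"))
  expect_null(d2$solution)
  expect_identical(d2$conflicts, 1L)

  # each target mapped to itself: layer-0 occupancies never collide
  d3 <- decode_chromosome(st$problem, c(b = "b", c = "c"))
  expect_identical(d3$conflicts, 0L)
  expect_identical(d3$solution$inputs, c("b", "c"))

  expect_error(
    decode_chromosome(ch$problem, c(b = "c", c = "c")),
    "not an ancestor"
  )
})

test_that("repair re-routes via an alternative feasible layer", {
  # d reaches t1 directly and t2 both directly and through x; assigning d to
  # both targets conflicts at layer 1 until one path re-routes via layer 2
  net <- network(data.frame(
    from = c("d", "d", "d", "x"),
    to = c("t1", "t2", "x", "t2")
  ))
  pr <- control_problem(net, targets = c("t1", "t2"))
  d <- decode_chromosome(pr, c(t1 = "d", t2 = "d"))
  expect_identical(d$conflicts, 0L)
  expect_identical(d$solution$inputs, "d")
  lens <- sort(unname(lengths(d$solution$paths)) - 1L)
  expect_identical(lens, c(1L, 2L))
})

test_that("ga finds the brute-force optimum on the toy instances", {
  ch <- toy_fixture("chain")
  sols <- ga_control(ch$problem, population_size = 30, max_generations = 30,
                     stagnation_limit = 10, seed = 1)
  expect_identical(sols$solutions[[1]]$inputs, "a")

  st <- toy_fixture("star")
  sols2 <- ga_control(st$problem, population_size = 30, max_generations = 30,
                      stagnation_limit = 10, seed = 1)
  expect_identical(length(sols2$solutions[[1]]$inputs), 2L)

  cy <- toy_fixture("cycle")
  sols3 <- ga_control(cy$problem, population_size = 30, max_generations = 30,
                      stagnation_limit = 10, seed = 1)
  expect_identical(length(sols3$solutions[[1]]$inputs), 1L)
})

test_that("ga results are reproducible and valid", {
  for (seed in 1:5) {
    pr <- random_instance(seed, n = 12, p = 0.2, n_targets = 3, n_preferred = 2)
    a <- ga_control(pr, population_size = 30, max_generations = 40,
                    stagnation_limit = 15, seed = 99)
    b <- ga_control(pr, population_size = 30, max_generations = 40,
                    stagnation_limit = 15, seed = 99)
    expect_identical(
      lapply(a$solutions, `[[`, "paths"),
      lapply(b$solutions, `[[`, "paths")
    )
    expect_identical(a$trajectory, b$trajectory)
    expect_valid_solution_set(a, pr)
  }
})

test_that("best fitness never worsens across generations (elitism)", {
  for (seed in 1:5) {
    pr <- random_instance(seed, n = 15, p = 0.15, n_targets = 4, n_preferred = 0)
    tr <- ga_control(pr, population_size = 20, max_generations = 40,
                     stagnation_limit = 40, seed = seed)$trajectory
    key <- tr$conflicts * 1e6 + tr$n_inputs * 1e3 - tr$n_preferred
    expect_true(all(diff(key) <= 0))
  }
})

test_that("ga matches the exhaustive minimum on tiny instances", {
  for (seed in 1:8) {
    pr <- random_instance(seed, n = 6, p = 0.3, n_targets = 2, n_preferred = 0,
                          L = 6)
    bf <- brute_force_minimum_inputs(pr$network, pr$targets)
    sols <- ga_control(pr, population_size = 30, max_generations = 40,
                       stagnation_limit = 15, seed = seed)
    expect_gte(length(sols$solutions[[1]]$inputs), bf$size)
  }
})

test_that("ga reports uncontrollable when no assignment exists", {
  net <- network(data.frame(from = "a", to = "b"))
  pr <- control_problem(net, targets = "a", allow_self_inputs = FALSE)
  out <- ga_control(pr, population_size = 10, max_generations = 5, seed = 1)
  expect_identical(out$status, "uncontrollable")
})
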