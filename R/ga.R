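#' Genetic-algorithm target controllability analysis
#'
#' Population search over per-target input assignments. A chromosome maps
#' every target to a chosen input node among its ancestors within the
#' path-length cap \eqn{L}; decoding builds one shortest walk per target
#' and scores the assignment by the lexicographic fitness
#' (path-compatibility conflicts ascending, then \eqn{|I|} ascending, then
#' \eqn{|I \cap S|} descending). Infeasible chromosomes stay in the
#' population, graded by conflict count, which keeps the search space
#' smooth. Half the initial population is random, half is seeded from
#' randomized greedy passes. Evolution uses tournament selection, uniform
#' per-gene crossover, per-gene mutation (resampling from the target's
#' ancestors) and elitism; search stops at `max_generations`, after
#' `stagnation_limit` generations without improvement, or as soon as a
#' provably optimal solution (a single input that is preferred, or a
#' single input when no preferred sources were given) is found.
#'
#' @param problem a [control_problem()] object.
#' @param population_size number of chromosomes, at least 4. Default 100.
#' @param elite_fraction fraction of the population copied unchanged each
#'   generation; in (0, 1). Default 0.1.
#' @param mutation_rate per-gene mutation probability. Default 0.05.
#' @param tournament_size tournament size for parent selection. Default 3.
#' @param max_generations generation cap. Default 200.
#' @param stagnation_limit stop after this many generations without
#'   fitness improvement. Default 50.
#' @param max_solutions maximum number of distinct solutions returned.
#'   Default 10.
#' @param seed integer seed; identical seed gives identical results.
#' @return a `ctrl_solution_set` (see [greedy_control()]) with an extra
#'   `$trajectory` tibble (best fitness per generation) and `$status`
#'   `"ok"` or `"uncontrollable"`.
#' @examples
#' fx <- toy_fixture("star")
#' ga_control(fx$problem, population_size = 20, max_generations = 20, seed = 1)
#' @export
ga_control <- function(problem, population_size = 100L, elite_fraction = 0.1,
                       mutation_rate = 0.05, tournament_size = 3L,
                       max_generations = 200L, stagnation_limit = 50L,
                       max_solutions = 10L, seed = 1L) {
  stopifnot(inherits(problem, "ctrl_problem"))
  population_size <- assert_count(population_size, "population_size", min = 4L)
  stopifnot(elite_fraction > 0, elite_fraction < 1)
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  tournament_size <- assert_count(tournament_size, "tournament_size", min = 2L)
  max_generations <- assert_count(max_generations, "max_generations")
  stagnation_limit <- assert_count(stagnation_limit, "stagnation_limit")
  max_solutions <- assert_count(max_solutions, "max_solutions")

  params <- list(
    population_size = population_size, elite_fraction = elite_fraction,
    mutation_rate = mutation_rate, tournament_size = tournament_size,
    max_generations = max_generations, stagnation_limit = stagnation_limit,
    max_solutions = max_solutions, seed = seed,
    max_path_length = problem$max_path_length
  )
  res <- withr::with_seed(seed, ga_run(problem, params))
  out <- new_solution_set(res$solutions, algorithm = "ga", params = params)
  out$status <- res$status
  out$trajectory <- res$trajectory
  out
}

# Per-target gene pools and layer structures used by decoding.
ga_context <- function(problem) {
  net <- problem$network
  L <- problem$max_path_length
  t_idx <- node_index(net, problem$targets)
  ctx <- lapply(t_idx, function(ti) {
    ls <- backward_layers(net, ti, L)
    feas <- feasible_layers(ls, n_nodes(net))
    pool <- which(lengths(feas) > 0)
    if (!problem$allow_self_inputs) pool <- setdiff(pool, ti)
    list(target = ti, layer_sets = ls, feas = feas, pool = pool)
  })
  names(ctx) <- problem$targets
  ctx
}

# Shortest walk of exactly `d` edges from node `g` to the target of `ctx_t`,
# as an integer node vector input..target; ties broken by smallest node id.
walk_from_layer <- function(net, ctx_t, g, d) {
  path <- integer(d + 1L)
  path[1] <- g
  cur <- g
  if (d >= 1) {
    for (step in seq_len(d)) {
      lay <- d - step # layer the next node must be able to occupy
      nxt <- intersect(net$succ[[cur]], ctx_t$layer_sets[[lay + 1L]])
      cur <- nxt[1] # sorted: smallest node id wins ties
      path[step + 1L] <- cur
    }
  }
  path
}

#' Decode a chromosome into a control solution
#'
#' Builds, per target, a shortest walk from the assigned gene node to the
#' target (ties broken by node-id order), counts path-compatibility
#' conflicts, and attempts one repair pass re-routing conflicting paths via
#' the next-shortest feasible layer. Returns a valid solution when no
#' conflicts remain, otherwise the residual conflict count.
#'
#' @param problem a [control_problem()] object.
#' @param genes named character vector mapping every target to its chosen
#'   input node; each gene must be an ancestor of its target within the
#'   path-length cap.
#' @return a list with elements `solution` (a [control_solution()] or
#'   `NULL`) and `conflicts` (integer, 0 when feasible).
#' @examples
#' fx <- toy_fixture("chain")
#' decode_chromosome(fx$problem, c(b = "a", c = "a"))
#' @export
decode_chromosome <- function(problem, genes) {
  stopifnot(inherits(problem, "ctrl_problem"))
  if (!setequal(names(genes), problem$targets)) {
    rlang::abort("`genes` must name exactly the problem's targets")
  }
  ctx <- ga_context(problem)
  g_idx <- node_index(problem$network, genes[problem$targets])
  for (i in seq_along(ctx)) {
    if (is.na(g_idx[i]) || length(ctx[[i]]$feas[[g_idx[i]]]) == 0) {
      rlang::abort(sprintf(
        "gene '%s' is not an ancestor of target '%s' within L = %d",
        genes[problem$targets][i], problem$targets[i], problem$max_path_length
      ))
    }
  }
  dec <- ga_decode(problem, ctx, g_idx)
  if (dec$conflicts == 0L) {
    list(solution = ga_build_solution(problem, dec$paths), conflicts = 0L)
  } else {
    list(solution = NULL, conflicts = dec$conflicts)
  }
}

# Number of conflicting (node, layer) pair occurrences across integer paths.
count_conflicts <- function(paths, L) {
  keys <- unlist(lapply(paths, function(p) {
    m <- length(p) - 1L
    p * (L + 2L) + (m - seq_along(p) + 1L)
  }), use.names = FALSE)
  cnt <- table(keys)
  sum(choose(cnt[cnt > 1], 2))
}

# Core decoder: integer gene vector -> list(paths, conflicts, inputs).
# One repair pass: conflicting paths (in target order) try their gene's
# next-shortest feasible layers.
ga_decode <- function(problem, ctx, g_idx) {
  net <- problem$network
  L <- problem$max_path_length
  nt <- length(ctx)
  layer_of <- integer(nt)
  paths <- vector("list", nt)
  for (i in seq_len(nt)) {
    d <- ctx[[i]]$feas[[g_idx[i]]][1]
    layer_of[i] <- d
    paths[[i]] <- walk_from_layer(net, ctx[[i]], g_idx[i], d)
  }
  conf <- count_conflicts(paths, L)
  if (conf > 0L) {
    for (i in seq_len(nt)) {
      if (!path_in_conflict(paths, i, L)) next
      alts <- setdiff(ctx[[i]]$feas[[g_idx[i]]], layer_of[i])
      for (d2 in alts) {
        cand <- paths
        cand[[i]] <- walk_from_layer(net, ctx[[i]], g_idx[i], d2)
        c2 <- count_conflicts(cand, L)
        if (c2 < conf) {
          paths <- cand
          layer_of[i] <- d2
          conf <- c2
          break
        }
      }
      if (conf == 0L) break
    }
  }
  inputs <- sort(unique(g_idx))
  list(paths = paths, conflicts = as.integer(conf), inputs = inputs)
}

path_in_conflict <- function(paths, i, L) {
  key_i <- {
    p <- paths[[i]]
    m <- length(p) - 1L
    p * (L + 2L) + (m - seq_along(p) + 1L)
  }
  others <- unlist(lapply(paths[-i], function(p) {
    m <- length(p) - 1L
    p * (L + 2L) + (m - seq_along(p) + 1L)
  }), use.names = FALSE)
  any(key_i %in% others)
}

ga_build_solution <- function(problem, int_paths) {
  net <- problem$network
  paths <- lapply(int_paths, function(p) net$nodes[p])
  names(paths) <- problem$targets
  control_solution(problem, paths)
}

# Lexicographic fitness: conflicts asc, |I| asc, |I n S| desc.
ga_fitness <- function(dec, pref_idx) {
  c(
    dec$conflicts,
    length(dec$inputs),
    -sum(dec$inputs %in% pref_idx)
  )
}

fitness_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

ga_run <- function(problem, params) {
  net <- problem$network
  L <- problem$max_path_length
  ctx <- ga_context(problem)
  nt <- length(ctx)
  pref_idx <- node_index(net, problem$preferred_sources)

  pools <- lapply(ctx, `[[`, "pool")
  if (any(lengths(pools) == 0)) {
    return(list(
      solutions = list(), status = "uncontrollable",
      trajectory = tibble::tibble(generation = integer(), conflicts = integer(),
                                  n_inputs = integer(), n_preferred = integer())
    ))
  }

  pop_size <- params$population_size
  rand_gene <- function(i) {
    pool <- pools[[i]]
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  random_chrom <- function() vapply(seq_len(nt), rand_gene, integer(1))

  # seed half the population from randomized greedy passes
  n_seeded <- pop_size %/% 2L
  pop <- vector("list", pop_size)
  filled <- 0L
  for (r in seq_len(n_seeded)) {
    gs <- greedy_once(problem)
    if (is.null(gs)) break
    g <- node_index(net, vapply(gs$paths[problem$targets], `[`, character(1), 1))
    ok <- vapply(seq_len(nt), function(i) g[i] %in% pools[[i]], logical(1))
    if (all(ok)) {
      filled <- filled + 1L
      pop[[filled]] <- g
    }
  }
  for (j in seq(filled + 1L, pop_size)) pop[[j]] <- random_chrom()

  # memoized decode: converged populations re-evaluate few chromosomes
  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- paste(chrom, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    dec <- ga_decode(problem, ctx, chrom)
    val <- list(fitness = ga_fitness(dec, pref_idx), dec = dec)
    cache[[key]] <- val
    val
  }

  archive <- new.env(parent = emptyenv()) # input-set key -> ctrl_solution
  record <- function(dec) {
    if (dec$conflicts != 0L) {
      return(invisible())
    }
    key <- paste(dec$inputs, collapse = ",")
    if (is.null(archive[[key]])) {
      archive[[key]] <- ga_build_solution(problem, dec$paths)
    }
  }

  n_elite <- max(1L, ceiling(params$elite_fraction * pop_size))
  best_fit <- NULL
  stagnant <- 0L
  traj <- vector("list", params$max_generations)

  for (gen in seq_len(params$max_generations)) {
    keys <- vapply(pop, paste, character(1), collapse = ",")
    evals <- lapply(pop, evaluate)
    fits <- t(vapply(evals, `[[`, numeric(3), "fitness"))
    for (e in evals) record(e$dec)

    ord <- order(fits[, 1], fits[, 2], fits[, 3], keys)
    gen_best <- fits[ord[1], ]
    traj[[gen]] <- gen_best
    if (is.null(best_fit) || fitness_less(gen_best, best_fit)) {
      best_fit <- gen_best
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    optimal <- best_fit[1] == 0 && best_fit[2] == 1 &&
      (length(pref_idx) == 0 || best_fit[3] == -1)
    if (optimal || stagnant >= params$stagnation_limit ||
        gen == params$max_generations) {
      break
    }

    elite <- pop[ord[seq_len(n_elite)]]
    n_child <- pop_size - n_elite
    rank_of <- integer(pop_size)
    rank_of[ord] <- seq_len(pop_size)
    sel <- matrix(
      sample.int(pop_size, 2L * n_child * params$tournament_size, replace = TRUE),
      nrow = 2L * n_child
    )
    cross_r <- matrix(stats::runif(n_child * nt), n_child)
    mut_r <- matrix(stats::runif(n_child * nt), n_child)
    children <- vector("list", n_child)
    for (cidx in seq_len(n_child)) {
      i1 <- sel[2L * cidx - 1L, ]
      i2 <- sel[2L * cidx, ]
      p1 <- pop[[i1[which.min(rank_of[i1])]]]
      p2 <- pop[[i2[which.min(rank_of[i2])]]]
      child <- p1
      swap <- cross_r[cidx, ] >= 0.5
      child[swap] <- p2[swap]
      for (i in which(mut_r[cidx, ] < params$mutation_rate)) {
        child[i] <- rand_gene(i)
      }
      children[[cidx]] <- child
    }
    pop <- c(elite, children)
  }

  sols <- lapply(sort(ls(archive)), function(k) archive[[k]])
  sols <- sols[solution_order(sols)]
  sols <- utils::head(sols, params$max_solutions)

  traj <- traj[!vapply(traj, is.null, logical(1))]
  trajectory <- tibble::tibble(
    generation = seq_along(traj),
    conflicts = vapply(traj, `[`, numeric(1), 1),
    n_inputs = vapply(traj, `[`, numeric(1), 2),
    n_preferred = -vapply(traj, `[`, numeric(1), 3)
  )
  list(
    solutions = sols,
    status = if (length(sols)) "ok" else "uncontrollable",
    trajectory = trajectory
  )
}
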