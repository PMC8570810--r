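#' Generic-rank (Kalman) verification of target controllability
#'
#' Independent ground truth for the path-based algorithms. The network
#' carries linear dynamics \eqn{\dot x = A x + B u} where the structured
#' state matrix has \eqn{A_{ij}} generically nonzero iff the edge
#' \eqn{j \to i} exists, and \eqn{B} holds one unit column per input node.
#' The target set \eqn{T} is generically controllable iff the rows of the
#' Kalman controllability matrix
#' \eqn{[B, AB, A^2B, \dots, A^{n-1}B]} indexed by \eqn{T} have full rank
#' \eqn{|T|} for almost every assignment of nonzero edge weights.
#'
#' Genericity is tested by exact arithmetic over the field of integers
#' modulo a large prime: each draw assigns independent uniform nonzero
#' weights to the edges and computes the rank of the target rows mod `p`.
#' The maximum rank across draws is returned; a draw underestimates the
#' generic rank with probability at most \eqn{n^2 / p} (Schwartz–Zippel),
#' so false negatives are vanishingly rare and are further suppressed by
#' taking several draws. There are no false positives.
#'
#' @param network a [network()] object.
#' @param inputs nonempty character vector of input node identifiers
#'   (columns of \eqn{B}).
#' @param targets character vector of target node identifiers.
#' @param prime modulus for the exact arithmetic; must be prime and exceed
#'   `n_nodes(network)^2`. Default \eqn{2^{31} - 1}.
#' @param draws number of independent random weight assignments. Default 3.
#' @param seed integer seed for the weight draws.
#' @return `target_generic_rank()`: the integer generic rank of the target
#'   rows (controllable iff it equals `length(targets)`).
#'   `is_controllable()`: a logical.
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' target_generic_rank(net, inputs = "a", targets = c("b", "c"))
#' @export
target_generic_rank <- function(network, inputs, targets,
                                prime = 2147483647, draws = 3L, seed = 1L) {
  stopifnot(inherits(network, "ctrl_network"))
  inputs <- unique(clean_ids(inputs, "input identifier"))
  targets <- unique(clean_ids(targets, "target identifier"))
  i_idx <- node_index(network, inputs)
  t_idx <- node_index(network, targets)
  if (length(i_idx) == 0) rlang::abort("`inputs` must be nonempty")
  if (anyNA(i_idx) || anyNA(t_idx)) {
    rlang::abort("all inputs and targets must be nodes of the network")
  }
  draws <- assert_count(draws, "draws")
  if (prime <= n_nodes(network)^2) {
    rlang::abort("`prime` must exceed n_nodes(network)^2")
  }

  n <- n_nodes(network)
  m <- length(i_idx)
  nt <- length(t_idx)
  em <- network$edges
  # incoming edge rows grouped by head node, aligned with their tails
  in_edges <- split(seq_len(nrow(em)), factor(em[, 2], levels = seq_len(n)))

  best <- 0L
  seeds <- derive_seeds(seed, draws)
  for (dr in seq_len(draws)) {
    w <- withr::with_seed(
      seeds[dr],
      if (nrow(em)) sample.int(prime - 1L, nrow(em), replace = TRUE) else numeric()
    )
    K <- matrix(0, nt, n * m)
    Y <- matrix(0, n, m)
    Y[cbind(i_idx, seq_len(m))] <- 1
    for (k in seq_len(n)) {
      K[, ((k - 1L) * m + 1L):(k * m)] <- Y[t_idx, , drop = FALSE]
      if (k < n) Y <- mod_matvec(Y, em, in_edges, w, prime, n, m)
    }
    r <- mod_rank(K, prime)
    best <- max(best, r)
    if (best == nt) break
  }
  as.integer(best)
}

#' @rdname target_generic_rank
#' @export
is_controllable <- function(network, inputs, targets,
                            prime = 2147483647, draws = 3L, seed = 1L) {
  target_generic_rank(network, inputs, targets, prime, draws, seed) ==
    length(unique(clean_ids(targets)))
}

#' Verify a solution set against the rank oracle
#'
#' Convenience wrapper: checks that every solution's input set achieves
#' generic rank `|T|` on its targets, and that every solution passes
#' [check_path_compatibility()].
#'
#' @param network a [network()] object.
#' @param solutions a `ctrl_solution_set` from [greedy_control()] or
#'   [ga_control()].
#' @param ... passed on to [target_generic_rank()].
#' @return a tibble with one row per solution: `solution`, `n_inputs`,
#'   `compatible` (logical), `rank`, `controllable` (logical).
#' @export
verify_solutions <- function(network, solutions, ...) {
  stopifnot(inherits(solutions, "ctrl_solution_set"))
  purrr::imap_dfr(solutions$solutions, function(s, i) {
    tibble::tibble(
      solution = i,
      n_inputs = length(s$inputs),
      compatible = nrow(check_path_compatibility(s)) == 0,
      rank = target_generic_rank(network, s$inputs, s$targets, ...),
      controllable = .data$rank == length(s$targets)
    )
  })
}

#' Exhaustive minimum input set on tiny networks
#'
#' Enumerates candidate input subsets in increasing size (lexicographic
#' within each size) and returns the first whose generic rank equals
#' \eqn{|T|}. A combinatorial guard restricts use to networks with at most
#' 12 nodes. Serves as the brute-force oracle against which the greedy and
#' genetic searches are benchmarked.
#'
#' @param network a [network()] object with at most 12 nodes.
#' @param targets character vector of target identifiers.
#' @param allow_self_inputs when `FALSE`, target nodes are excluded from
#'   the candidate input pool.
#' @param restrict_to optional character vector restricting the candidate
#'   input pool.
#' @inheritParams target_generic_rank
#' @return a list with `size` (integer, or `Inf` when no subset up to all
#'   candidates achieves full target rank) and `inputs` (character vector
#'   witness, empty when `size` is `Inf`).
#' @examples
#' net <- network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' brute_force_minimum_inputs(net, targets = c("b", "c"))
#' @export
brute_force_minimum_inputs <- function(network, targets,
                                       allow_self_inputs = TRUE,
                                       restrict_to = NULL,
                                       prime = 2147483647, draws = 3L,
                                       seed = 1L) {
  stopifnot(inherits(network, "ctrl_network"))
  if (n_nodes(network) > 12) {
    rlang::abort("brute-force search is limited to networks with <= 12 nodes")
  }
  targets <- unique(clean_ids(targets))
  pool <- sort(restrict_to %||% network$nodes)
  pool <- intersect(pool, network$nodes)
  if (!allow_self_inputs) pool <- setdiff(pool, targets)
  nt <- length(targets)
  for (size in seq_along(pool)) {
    combos <- utils::combn(pool, size, simplify = FALSE)
    for (cand in combos) {
      r <- target_generic_rank(network, cand, targets, prime, draws, seed)
      if (r == nt) {
        return(list(size = size, inputs = cand))
      }
    }
  }
  list(size = Inf, inputs = character())
}

# --- exact arithmetic mod p (p < 2^31), representable in doubles ---------

# (a * b) mod p, exact for 0 <= a, b < 2^31 via a 16-bit split of `a`:
# every intermediate stays below 2^48 < 2^53.
mulmod <- function(a, b, p) {
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * b) %% p) * 65536 + a0 * b) %% p
}

# a^e mod p by binary exponentiation (scalar).
powmod <- function(a, e, p) {
  r <- 1
  a <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- mulmod(r, a, p)
    a <- mulmod(a, a, p)
    e <- e %/% 2
  }
  r
}

# Sparse structured product A %*% Y mod p: row i of the result sums
# w[e] * Y[tail(e), ] over incoming edges e of node i.
mod_matvec <- function(Y, em, in_edges, w, p, n, m) {
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    es <- in_edges[[i]]
    if (length(es)) {
      acc <- numeric(m)
      for (e in es) {
        acc <- (acc + mulmod(w[e], Y[em[e, 1], ], p)) %% p
      }
      out[i, ] <- acc
    }
  }
  out
}

# Rank of a matrix over GF(p) by Gaussian elimination.
mod_rank <- function(M, p) {
  M <- M %% p
  nr <- nrow(M)
  nc <- ncol(M)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(M[row:nr, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    inv <- powmod(M[row, col], p - 2, p)
    M[row, ] <- mulmod(M[row, ], inv, p)
    below <- which(M[, col] != 0)
    below <- below[below > row]
    for (r2 in below) {
      M[r2, ] <- (M[r2, ] - mulmod(M[r2, col], M[row, ], p)) %% p
    }
    row <- row + 1L
  }
  row - 1L
}
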