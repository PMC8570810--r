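#' Maximum bipartite matching with ordered augmentation
#'
#' Computes a maximum-cardinality matching between two vertex classes,
#' augmenting in a caller-supplied preference order: left vertices are
#' processed in order of their best-ranked pair, and each augmenting-path
#' search tries right candidates in pair-preference order. Among maximum
#' matchings the result therefore *greedily* respects the preference; it is
#' not guaranteed to be the globally preference-optimal maximum matching.
#'
#' This is the per-layer subroutine of [greedy_control()]: chains are the
#' left class, candidate predecessor nodes the right class, and the
#' preference encodes input reuse, preferred sources and degree.
#'
#' @param allowed a data frame whose first two columns list the allowed
#'   (left, right) pairs.
#' @param preference optional numeric vector, one value per row of
#'   `allowed`; smaller values are tried first. Defaults to row order.
#' @return a tibble with columns `left` and `right`, one row per matched
#'   pair; left- and right-unique, of maximum cardinality.
#' @examples
#' pairs <- data.frame(left = c(1, 1, 2), right = c("a", "b", "a"))
#' max_bipartite_matching(pairs)
#' @export
max_bipartite_matching <- function(allowed, preference = NULL) {
  allowed <- as.data.frame(allowed)
  if (nrow(allowed) == 0) {
    return(tibble::tibble(left = character(), right = character()))
  }
  stopifnot(ncol(allowed) >= 2)
  lf <- as.character(allowed[[1]])
  rt <- as.character(allowed[[2]])
  preference <- preference %||% seq_along(lf)
  stopifnot(length(preference) == length(lf))

  lv <- unique(lf)
  rv <- unique(rt)
  m <- kuhn_match(
    li = match(lf, lv), ri = match(rt, rv),
    nl = length(lv), nr = length(rv), pref = preference
  )
  tibble::tibble(left = lv[m[, 1]], right = rv[m[, 2]])
}

# Integer-index Kuhn augmenting-path matching. `li`, `ri`: pair endpoints;
# `pref`: numeric rank per pair (smaller first). Returns a 2-column matrix
# of matched (left, right) indices.
kuhn_match <- function(li, ri, nl, nr, pref) {
  ord <- order(pref)
  li <- li[ord]
  ri <- ri[ord]
  # adjacency per left vertex, already in preference order
  adj <- split(ri, factor(li, levels = seq_len(nl)))
  best <- match(seq_len(nl), li) # rank of each left vertex's best pair
  match_r <- integer(nr) # right -> left, 0 free
  visited <- logical(nr)

  augment <- function(l) {
    for (r in adj[[l]]) {
      if (!visited[r]) {
        visited[r] <<- TRUE
        if (match_r[r] == 0L || augment(match_r[r])) {
          match_r[r] <<- l
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (l in order(best, na.last = NA)) {
    visited[] <- FALSE
    augment(l)
  }
  matched <- which(match_r != 0L)
  cbind(match_r[matched], matched)
}
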