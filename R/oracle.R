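# Brute-force reference implementations ---------------------------------------
#
# Test-only machinery: exhaustive enumeration of valid complete mappings
# (every valid mapping dominates the LCA-mapping node-wise, so each internal
# gene node ranges over the ancestors-or-self of its LCA image), and an
# exhaustive minimum antichain partition.  Never used on realistic sizes.

#' Enumerate all valid complete mappings
#'
#' Each internal gene node `v` ranges over the ancestors-or-self of `mu(v)`
#' (no valid mapping can go below the LCA-mapping), filtered by the
#' ancestor-consistency constraint against its children's images.  Refuses to
#' run if the predicted assignment space exceeds `max_space`.
#'
#' @inheritParams lca_mapping
#' @param max_space Cap on the product of per-node domain sizes.
#' @param fun Callback called with each alpha vector; if `NULL`, all alpha
#'   vectors are collected and returned.
#' @return A list of integer alpha vectors (invisibly, the count if `fun` is
#'   given).
#' @export
enumerate_valid_mappings <- function(G, S, smap, max_space = 2e5, fun = NULL) {
  mu <- lca_mapping(G, S, smap)$alpha
  internal <- G$postorder[!G$is_leaf[G$postorder]]
  domains <- lapply(internal, function(v) ancestors_or_self(S, mu[v]))
  space <- prod(vapply(domains, length, integer(1)))
  if (space > max_space) {
    stop("enumeration space ", space, " exceeds the budget of ", max_space,
         "; shrink the instance")
  }
  collect <- is.null(fun)
  acc <- if (collect) vector("list", 0) else NULL
  count <- 0L
  alpha <- rep(NA_integer_, G$n)
  alpha[as.integer(names(smap))] <- as.integer(smap)

  rec <- function(i, alpha) {
    if (i > length(internal)) {
      count <<- count + 1L
      if (collect) acc[[count]] <<- alpha else fun(alpha)
      return(invisible(NULL))
    }
    v <- internal[i]
    ch <- G$children[[v]]
    for (s in domains[[i]]) {
      if (is_ancestor(S, s, alpha[ch[1]]) && is_ancestor(S, s, alpha[ch[2]])) {
        alpha[v] <- s
        rec(i + 1L, alpha)
      }
    }
    invisible(NULL)
  }
  rec(1L, alpha)
  if (collect) acc else invisible(count)
}

#' Brute-force minimum-cost reconciliation
#'
#' Enumerates every valid complete mapping and returns the minimum of the
#' segmental cost, with one argmin mapping.  Deterministic: mappings are
#' enumerated in a fixed order and the first optimum is kept.
#'
#' @inheritParams enumerate_valid_mappings
#' @param delta,lambda Event costs.
#' @return List with `cost`, `summary` (a [cost_sd()] summary), `mapping`.
#' @export
brute_force_optimum <- function(G, S, smap, delta, lambda, max_space = 2e5) {
  best <- Inf
  best_alpha <- NULL
  enumerate_valid_mappings(G, S, smap, max_space = max_space, fun = function(alpha) {
    m <- new_mapping(G, S, smap, alpha)
    cost <- cost_sd(m, delta, lambda)$cost
    if (cost < best) {
      best <<- cost
      best_alpha <<- alpha
    }
  })
  m <- new_mapping(G, S, smap, best_alpha)
  list(cost = best, summary = cost_sd(m, delta, lambda), mapping = m)
}

#' Exact minimum antichain partition of a small poset
#'
#' Exhaustively partitions a set of gene nodes (with ancestry in the gene
#' forest as the order relation) into the minimum number of antichains --
#' the number of segmental events needed to cover a co-mapped duplication
#' set.  Branch-and-bound over assignments of elements to parts.
#'
#' @param G A `recon_forest`.
#' @param nodes Integer vector of at most 8 gene node ids.
#' @return Integer: the minimum number of antichains.
#' @export
min_antichain_partition <- function(G, nodes) {
  n <- length(nodes)
  if (n == 0L) return(0L)
  if (n > 8L) stop("min_antichain_partition: at most 8 elements supported")
  comp <- outer(nodes, nodes, function(x, y) {
    mapply(function(a, b) a != b && comparable(G, a, b), x, y)
  })
  best <- n
  parts <- vector("list", n)
  rec <- function(i, k) {
    if (k >= best) return(invisible(NULL))
    if (i > n) { best <<- k; return(invisible(NULL)) }
    for (j in seq_len(k)) {
      if (!any(comp[parts[[j]], i])) {
        parts[[j]] <<- c(parts[[j]], i)
        rec(i + 1L, k)
        parts[[j]] <<- parts[[j]][-length(parts[[j]])]
      }
    }
    parts[[k + 1L]] <<- i
    rec(i + 1L, k + 1L)
    parts[[k + 1L]] <<- integer(0)
  }
  rec(1L, 0L)
  best
}
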