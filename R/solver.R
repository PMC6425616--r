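# Exact solver for segmental duplication-loss reconciliation -------------------
#
# For delta <= lambda the LCA-mapping mu is optimal (and unique when
# lambda > delta), so solve() just returns it.  For delta > lambda the
# problem is NP-hard and we run a bounded branch-and-bound over partial
# mappings: undetermined nodes carry NA, determinedness is downward-closed,
# and the search maintains a *clean* state between branchings:
#   C1  no minimal undetermined node is "easy" (its optimal image is forced);
#   C2  no determined duplication sits strictly above the candidate species
#       of any minimal undetermined node.
# Each branching picks a lowest minimal undetermined node, tries the species
# on the path from the LCA of its children's images up to its
# ceiling(delta/lambda)-th ancestor (further remapping can never pay off:
# shifting a duplication down k arcs saves at least k losses at the price of
# at most one extra segmental event), forces co-mappable minimal nodes to the
# same species, and re-runs the easy-node fixpoint.  Every branching grows
# the sum of duplication heights by exactly 1, so the search depth is at
# most the duplication budget d.
#
# The recursive control flow (base cases, lowest-node choice, the candidate
# loop, the co-mapping forcing and the easy-node fixpoint) follows the
# published correctness argument for this search scheme; the admissible
# cost-bound pruning (partial cost only grows) is an implementation addition.

solver_ctx <- function(G, S, smap) {
  mu <- lca_mapping(G, S, smap)
  list(G = G, S = S, smap = smap, mu = mu$alpha, gnames = node_names(G))
}

empty_state <- function(ctx) {
  G <- ctx$G
  st <- list(
    alpha = rep(NA_integer_, G$n),
    isdup = rep(NA, G$n),
    chain = integer(G$n),
    heights = integer(ctx$S$n),
    dhat = 0L,
    losses = 0L
  )
  st$alpha[as.integer(names(ctx$smap))] <- as.integer(ctx$smap)
  st$isdup[ctx$G$leaves] <- FALSE
  st
}

state_mu_alpha <- function(ctx, st, v) {
  ch <- ctx$G$children[[v]]
  lca(ctx$S, st$alpha[ch[1]], st$alpha[ch[2]])
}

# assign v -> s; assumes children of v are determined and s dominates both
# child images.  Updates the event, duplication chain heights, the per-species
# height table and the loss count incrementally.
state_assign <- function(ctx, st, v, s) {
  G <- ctx$G; S <- ctx$S
  ch <- G$children[[v]]
  s1 <- st$alpha[ch[1]]; s2 <- st$alpha[ch[2]]
  st$alpha[v] <- s
  dup <- !(!comparable(S, s1, s2) && s == lca(S, s1, s2))
  st$isdup[v] <- dup
  loss <- (S$depth[s1] - S$depth[s]) + (S$depth[s2] - S$depth[s]) - if (dup) 0L else 2L
  st$losses <- st$losses + loss
  if (dup) {
    best <- 0L
    for (c in ch) {
      if (isTRUE(st$isdup[c]) && st$alpha[c] == s && st$chain[c] > best) best <- st$chain[c]
    }
    st$chain[v] <- best + 1L
    if (st$chain[v] > st$heights[s]) {
      st$dhat <- st$dhat + (st$chain[v] - st$heights[s])
      st$heights[s] <- st$chain[v]
    }
  }
  st
}

minimal_bot_nodes <- function(ctx, st) {
  G <- ctx$G
  out <- integer(0)
  for (v in seq_len(G$n)) {
    if (G$is_leaf[v] || !is.na(st$alpha[v])) next
    ch <- G$children[[v]]
    if (!is.na(st$alpha[ch[1]]) && !is.na(st$alpha[ch[2]])) out <- c(out, v)
  }
  out
}

#' Is a node a duplication in every completion?
#'
#' A minimal undetermined node `v` (children determined) is a *required
#' duplication* iff one of its children's images dominates the global
#' LCA-mapping image `mu(v)`; otherwise some completion makes it a
#' speciation.
#'
#' @param ctx Solver context from the internal constructor.
#' @param st Partial state.
#' @param v Minimal undetermined gene node.
#' @return Logical.
#' @keywords internal
is_required_duplication <- function(ctx, st, v) {
  ch <- ctx$G$children[[v]]
  if (is.na(st$alpha[ch[1]]) || is.na(st$alpha[ch[2]])) {
    stop("node ", v, " is not a minimal undetermined node")
  }
  muv <- ctx$mu[v]
  is_ancestor(ctx$S, st$alpha[ch[1]], muv) || is_ancestor(ctx$S, st$alpha[ch[2]], muv)
}

# easy = its image in any optimal completion is forced to the LCA of its
# children's images: either it is not a required duplication (it can be a
# speciation there), or mapping it there adds no duplication height (a free
# slot in the existing duplication chain).
is_easy <- function(ctx, st, v) {
  if (!is_required_duplication(ctx, st, v)) return(TRUE)
  s <- state_mu_alpha(ctx, st, v)
  best <- 0L
  for (c in ctx$G$children[[v]]) {
    if (isTRUE(st$isdup[c]) && st$alpha[c] == s && st$chain[c] > best) best <- st$chain[c]
  }
  (best + 1L) <= st$heights[s]
}

# map easy nodes until none remain; processing order: increasing depth of the
# forced image, then smallest canonical gene-node name (determinism only --
# any order gives the same final cost).
easy_fixpoint <- function(ctx, st) {
  repeat {
    M <- minimal_bot_nodes(ctx, st)
    if (length(M) == 0L) return(st)
    easy <- M[vapply(M, function(v) is_easy(ctx, st, v), logical(1))]
    if (length(easy) == 0L) return(st)
    mus <- vapply(easy, function(v) state_mu_alpha(ctx, st, v), integer(1))
    ord <- order(ctx$S$depth[mus], ctx$gnames[easy])
    v <- easy[ord[1]]
    st <- state_assign(ctx, st, v, mus[ord[1]])
  }
}

#' Initial clean partial mapping
#'
#' Starts from the all-undetermined mapping and repeatedly fixes every
#' minimal undetermined node that is not a required duplication to the LCA
#' of its children's images (making it a speciation).  The result is clean:
#' it contains no duplications at all and every remaining minimal
#' undetermined node is a required duplication.
#'
#' @inheritParams is_required_duplication
#' @return A partial state.
#' @keywords internal
initial_cleanup <- function(ctx) {
  st <- empty_state(ctx)
  for (v in ctx$G$postorder) {
    if (ctx$G$is_leaf[v]) next
    ch <- ctx$G$children[[v]]
    if (is.na(st$alpha[ch[1]]) || is.na(st$alpha[ch[2]])) next
    if (!is_required_duplication(ctx, st, v)) {
      st <- state_assign(ctx, st, v, state_mu_alpha(ctx, st, v))
    }
  }
  st
}

# a lowest minimal undetermined node: no other minimal undetermined node has
# its candidate species strictly below this one's.  Ties: deepest candidate
# species first, then smallest canonical name.
lowest_minimal_bot_node <- function(ctx, st) {
  M <- minimal_bot_nodes(ctx, st)
  if (length(M) == 0L) stop("state is complete")
  mus <- vapply(M, function(v) state_mu_alpha(ctx, st, v), integer(1))
  lowest <- vapply(seq_along(M), function(i) {
    !any(vapply(seq_along(M), function(j) {
      j != i && mus[j] != mus[i] && is_ancestor(ctx$S, mus[i], mus[j])
    }, logical(1)))
  }, logical(1))
  cand <- which(lowest)
  ord <- order(-ctx$S$depth[mus[cand]], ctx$gnames[M[cand]])
  M[cand[ord[1]]]
}

#' Candidate species for a branching node
#'
#' The species on the path from the LCA of the node's children's images up to
#' its `ceiling(delta/lambda)`-th ancestor, inclusive on both ends, clamped
#' and deduplicated at the root, ordered bottom-up.  Mapping the node any
#' higher can never be optimal: shifting a duplication down `k` arcs saves at
#' least `k` losses and costs at most one extra segmental duplication.
#'
#' @inheritParams is_required_duplication
#' @param delta,lambda Event costs, `delta > lambda > 0`.
#' @return Integer vector of species node ids, bottom-up.
#' @keywords internal
candidate_species <- function(ctx, st, v, delta, lambda) {
  k <- ceiling(delta / lambda)
  s <- state_mu_alpha(ctx, st, v)
  out <- s
  for (i in seq_len(k)) {
    p <- ctx$S$parent[s]
    if (p == 0L) break
    s <- p
    out <- c(out, s)
  }
  out
}

#' One branching step: assign and re-clean
#'
#' Maps the chosen lowest minimal undetermined node `v` to species `s`, maps
#' every other minimal undetermined node whose candidate species lies at or
#' below `s` to `s` as well (in an optimal completion they must share the
#' event), then runs the easy-node fixpoint.  The resulting state is clean
#' and its duplication-height sum exceeds the input's by exactly 1.
#'
#' @inheritParams candidate_species
#' @param s Species node id from [candidate_species()].
#' @return The new partial state.
#' @keywords internal
apply_and_cleanup <- function(ctx, st, v, s) {
  M <- setdiff(minimal_bot_nodes(ctx, st), v)
  st <- state_assign(ctx, st, v, s)
  for (w in M) {
    if (is_ancestor(ctx$S, s, state_mu_alpha(ctx, st, w))) {
      st <- state_assign(ctx, st, w, s)
    }
  }
  easy_fixpoint(ctx, st)
}

#' Minimum-cost reconciliation with a duplication budget
#'
#' Branch-and-bound search for a minimum-cost complete mapping whose sum of
#' duplication heights is at most `d`.  Requires `delta > lambda > 0`; use
#' [solve_mprst()] for the general entry point.
#'
#' @inheritParams lca_mapping
#' @param delta,lambda Event costs with `delta > lambda > 0`.
#' @param d Non-negative integer duplication-height budget.
#' @param best Initial upper bound on the cost (with its mapping in
#'   `best_alpha`), used for pruning; defaults to none.
#' @param best_alpha Optional complete alpha vector achieving `best`.
#' @param expansion_limit Safety valve on the number of search-tree edges.
#' @return A list with `cost` (`Inf` if no mapping fits the budget and no
#'   incumbent was given), `alpha`, `expansions`, and `limited` (`TRUE` if
#'   the expansion limit was hit, in which case the result may be
#'   suboptimal).
#' @export
solve_bounded <- function(G, S, smap, delta, lambda, d,
                          best = Inf, best_alpha = NULL,
                          expansion_limit = Inf) {
  stopifnot(delta > lambda, lambda > 0, d >= 0)
  ctx <- solver_ctx(G, S, smap)
  env <- new.env(parent = emptyenv())
  env$best <- best
  env$best_alpha <- best_alpha
  env$expansions <- 0L
  env$limited <- FALSE

  rec <- function(st) {
    if (env$limited) return(invisible(NULL))
    if (!anyNA(st$alpha)) {
      cost <- delta * st$dhat + lambda * st$losses
      if (cost < env$best) {
        env$best <- cost
        env$best_alpha <- st$alpha
      }
      return(invisible(NULL))
    }
    # a clean incomplete state needs at least one more duplication
    if (st$dhat >= d) return(invisible(NULL))
    if (delta * (st$dhat + 1L) + lambda * st$losses >= env$best) return(invisible(NULL))
    v <- lowest_minimal_bot_node(ctx, st)
    for (s in candidate_species(ctx, st, v, delta, lambda)) {
      env$expansions <- env$expansions + 1L
      if (env$expansions > expansion_limit) {
        env$limited <- TRUE
        return(invisible(NULL))
      }
      st2 <- apply_and_cleanup(ctx, st, v, s)
      if (st2$dhat > d) next
      if (delta * st2$dhat + lambda * st2$losses >= env$best) next
      rec(st2)
    }
    invisible(NULL)
  }

  rec(initial_cleanup(ctx))
  list(cost = env$best, alpha = env$best_alpha,
       expansions = env$expansions, limited = env$limited)
}

#' Loss-cost substitute for the lambda = 0 case
#'
#' With `lambda = 0` the objective is the pure duplication-height sum.  The
#' branch-and-bound needs `lambda > 0`, so we solve under a loss cost small
#' enough that even the maximum possible number of losses costs less than one
#' duplication: `lambda' = delta / (2 |V(G)| |V(S)| + 1)`.  The optimum under
#' `lambda'` minimizes the height sum, and among equal-height-sum mappings
#' minimizes losses; reported costs are then re-expressed with the true
#' `lambda = 0`.
#'
#' @param delta Duplication cost.
#' @param G,S Gene forest and species tree (their sizes set the bound).
#' @return The substituted loss cost, a positive number.
#' @export
zero_lambda_substitute <- function(delta, G, S) {
  delta / (2 * G$n * S$n + 1)
}

#' Solve the segmental most-parsimonious reconciliation problem
#'
#' Finds a reconciliation of the gene forest with the species tree minimizing
#' `delta * d_hat + lambda * losses`, where `d_hat` is the sum over species
#' of the height of the co-mapped duplication forest (the number of segmental
#' duplication events).  For `delta <= lambda` the LCA-mapping is returned
#' directly (it is optimal, and for `lambda > delta` uniquely so).  For
#' `delta > lambda` an exact branch-and-bound with iterative deepening over
#' the duplication budget is run; `lambda = 0` is handled through
#' [zero_lambda_substitute()], with losses reported but not charged.
#'
#' @inheritParams lca_mapping
#' @param delta Segmental duplication cost (> 0).
#' @param lambda Loss cost (>= 0).
#' @param budget `"auto"` (iterative deepening with a provable stop rule) or
#'   a fixed non-negative integer bound on the duplication-height sum.
#' @param expansion_limit Safety valve; if hit the result is flagged
#'   non-optimal.
#' @return A list of class `recon_solution`: `summary` (a [cost_sd()]
#'   summary at the true costs), `mapping` (a complete `recon_mapping`),
#'   `optimal` (logical), `expansions`, `feasible` (`FALSE` only when a fixed
#'   budget excludes every mapping, which cannot happen for
#'   `budget >= d_hat(mu)`).
#' @examples
#' S <- parse_newick("((A,B),C);")
#' G <- parse_newick("((A__1,B__1),(A__2,B__2));", expect = "forest")
#' sm <- leaf_map(G, S)
#' sol <- solve_mprst(G, S, sm, delta = 3, lambda = 1)
#' sol$summary
#' @export
solve_mprst <- function(G, S, smap, delta, lambda, budget = "auto",
                        expansion_limit = Inf) {
  stopifnot(delta > 0, lambda >= 0)
  true_lambda <- lambda
  if (lambda == 0) lambda <- zero_lambda_substitute(delta, G, S)

  mu <- lca_mapping(G, S, smap)

  finish <- function(alpha, optimal, expansions, feasible = TRUE) {
    m <- new_mapping(G, S, smap, alpha)
    out <- list(
      summary = if (feasible) cost_sd(m, delta, true_lambda) else NULL,
      mapping = if (feasible) m else NULL,
      optimal = optimal, expansions = expansions, feasible = feasible
    )
    class(out) <- "recon_solution"
    out
  }

  if (delta <= lambda) {
    return(finish(mu$alpha, optimal = TRUE, expansions = 0L))
  }

  mu_sum <- cost_sd(mu, delta, lambda)
  best <- mu_sum$cost
  best_alpha <- mu$alpha
  expansions <- 0L
  limited <- FALSE

  if (identical(budget, "auto")) {
    dd <- 0L
    repeat {
      res <- solve_bounded(G, S, smap, delta, lambda, dd,
                           best = best, best_alpha = best_alpha,
                           expansion_limit = expansion_limit - expansions)
      expansions <- expansions + res$expansions
      limited <- limited || res$limited
      if (res$cost < best) { best <- res$cost; best_alpha <- res$alpha }
      # any unexplored mapping has d_hat >= dd + 1, costing >= (dd+1) * delta;
      # and any mapping with d_hat >= d_hat(mu) costs >= cost(mu) since mu
      # minimizes losses
      if (limited) break
      if (best <= (dd + 1L) * delta) break
      if (dd + 1L >= mu_sum$d_hat) break
      dd <- dd + 1L
    }
    finish(best_alpha, optimal = !limited, expansions = expansions)
  } else {
    stopifnot(is.numeric(budget), budget >= 0)
    within_budget <- mu_sum$d_hat <= budget
    res <- solve_bounded(G, S, smap, delta, lambda, as.integer(budget),
                         best = if (within_budget) best else Inf,
                         best_alpha = if (within_budget) best_alpha else NULL,
                         expansion_limit = expansion_limit)
    if (is.null(res$alpha)) {
      return(finish(NULL, optimal = FALSE, expansions = res$expansions,
                    feasible = FALSE))
    }
    finish(res$alpha, optimal = !res$limited, expansions = res$expansions)
  }
}

#' @export
print.recon_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("<recon_solution> infeasible under the given duplication budget\n")
    return(invisible(x))
  }
  cat(sprintf("<recon_solution> %s, %d search expansions\n",
              if (x$optimal) "optimal" else "NOT proven optimal (expansion limit hit)",
              x$expansions))
  print(x$summary)
  invisible(x)
}
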