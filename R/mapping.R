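# Reconciliation mappings ------------------------------------------------------
#
# A mapping alpha assigns gene-forest nodes to species-tree nodes; NA plays
# the role of the "undetermined" (bottom) symbol of a partial mapping.
# Events are not stored: following the parsimony convention, an internal
# determined node v is a speciation iff alpha(v) is the LCA of its children's
# images and those images are incomparable, and a duplication otherwise;
# leaves are contemporary (C) events.  Determinedness is downward-closed:
# if a node is determined so are all its descendants.

#' Construct a reconciliation mapping
#'
#' @param G Gene forest.
#' @param S Species tree.
#' @param smap A [leaf_map()].
#' @param alpha Integer vector of length `G$n`: species node id per gene node,
#'   `NA` for undetermined. If missing, only the leaves are determined.
#' @return Object of class `recon_mapping`.
#' @export
new_mapping <- function(G, S, smap, alpha = NULL) {
  if (is.null(alpha)) {
    alpha <- rep(NA_integer_, G$n)
  }
  alpha[as.integer(names(smap))] <- as.integer(smap)
  m <- list(G = G, S = S, smap = smap, alpha = as.integer(alpha))
  class(m) <- "recon_mapping"
  m
}

#' @export
print.recon_mapping <- function(x, ...) {
  nd <- sum(!is.na(x$alpha))
  cat(sprintf("<recon_mapping> %d/%d gene nodes determined\n", nd, x$G$n))
  invisible(x)
}

is_complete <- function(m) !anyNA(m$alpha)

#' The LCA-mapping
#'
#' Maps each gene leaf to its species and each internal gene node to the LCA
#' of its children's images; this is the lowest valid reconciliation: every
#' valid mapping `alpha` satisfies `alpha(v) >= mu(v)` node-wise.  With the
#' parsimony event convention it is the classic most-parsimonious
#' duplication-loss reconciliation, computed per gene tree.
#'
#' @inheritParams new_mapping
#' @return A complete `recon_mapping`.
#' @export
lca_mapping <- function(G, S, smap) {
  m <- new_mapping(G, S, smap)
  a <- m$alpha
  for (v in G$postorder) {
    if (!G$is_leaf[v]) {
      ch <- G$children[[v]]
      a[v] <- lca(S, a[ch[1]], a[ch[2]])
    }
  }
  m$alpha <- a
  m
}

#' Event of one gene node under a mapping
#'
#' `"C"` for leaves, `"S"` iff the node's image is the LCA of its children's
#' images and those images are incomparable, `"D"` otherwise.
#'
#' @param m A `recon_mapping`.
#' @param v Gene node id; must be determined with determined children.
#' @return One of `"S"`, `"D"`, `"C"`.
#' @export
classify_event <- function(m, v) {
  a <- m$alpha
  if (is.na(a[v])) stop("node ", v, " is undetermined")
  if (m$G$is_leaf[v]) return("C")
  ch <- m$G$children[[v]]
  if (anyNA(a[ch])) stop("children of node ", v, " are undetermined")
  s1 <- a[ch[1]]; s2 <- a[ch[2]]
  if (!comparable(m$S, s1, s2) && a[v] == lca(m$S, s1, s2)) "S" else "D"
}

#' Events of all determined nodes
#' @param m A `recon_mapping`.
#' @return Character vector over gene nodes: `"C"`, `"S"`, `"D"`, or `NA` for
#'   undetermined nodes.
#' @export
mapping_events <- function(m) {
  a <- m$alpha; G <- m$G; S <- m$S
  ev <- rep(NA_character_, G$n)
  for (v in G$postorder) {
    if (is.na(a[v])) next
    if (G$is_leaf[v]) { ev[v] <- "C"; next }
    ch <- G$children[[v]]
    s1 <- a[ch[1]]; s2 <- a[ch[2]]
    ev[v] <- if (!comparable(S, s1, s2) && a[v] == lca(S, s1, s2)) "S" else "D"
  }
  ev
}

#' Loss count of a (possibly partial) mapping
#'
#' For each determined internal node `u` with children `u1, u2`,
#' losses are `dist(alpha(u), alpha(u1)) + dist(alpha(u), alpha(u2))`,
#' minus 2 if `u` is a speciation.  Undetermined nodes contribute nothing.
#'
#' @param m A `recon_mapping`.
#' @return Non-negative integer.
#' @export
count_losses <- function(m) {
  a <- m$alpha; G <- m$G; S <- m$S
  tot <- 0L
  for (v in seq_len(G$n)) {
    if (G$is_leaf[v] || is.na(a[v])) next
    ch <- G$children[[v]]
    s1 <- a[ch[1]]; s2 <- a[ch[2]]
    if (!is_ancestor(S, a[v], s1) || !is_ancestor(S, a[v], s2)) {
      stop("invalid mapping at node ", v, ": a child image is not below its parent's image")
    }
    l <- (S$depth[s1] - S$depth[a[v]]) + (S$depth[s2] - S$depth[a[v]])
    if (!comparable(S, s1, s2) && a[v] == lca(S, s1, s2)) l <- l - 2L
    tot <- tot + l
  }
  tot
}

#' Per-species duplication-forest heights
#'
#' For each species node `s`, the height (counted in nodes, so a single
#' duplication gives height 1) of the forest induced in the gene forest by
#' the duplication nodes mapped to `s`.  This equals the minimum number of
#' antichains partitioning those duplications, i.e. the minimum number of
#' segmental duplication events at `s`.
#'
#' @param m A `recon_mapping` (may be partial; only determined nodes count).
#' @return Integer vector indexed by species node id.
#' @export
dup_heights <- function(m) {
  a <- m$alpha; G <- m$G
  ev <- mapping_events(m)
  h <- integer(m$S$n)            # per-species forest height
  chain <- integer(G$n)          # per-gene-node duplication chain height
  for (v in G$postorder) {
    if (is.na(ev[v]) || ev[v] != "D") next
    best <- 0L
    for (c in G$children[[v]]) {
      if (!is.na(ev[c]) && ev[c] == "D" && a[c] == a[v] && chain[c] > best) best <- chain[c]
    }
    chain[v] <- best + 1L
    if (chain[v] > h[a[v]]) h[a[v]] <- chain[v]
  }
  h
}

#' Summarize a reconciliation under the segmental cost model
#'
#' Computes per-species duplication heights `h_alpha(s)`, their sum `d_hat`
#' (the number of segmental duplications), the plain duplication-node count,
#' the loss count, and the cost `delta * d_hat + lambda * losses`.
#'
#' @param m A complete (or partial, scored over determined nodes)
#'   `recon_mapping`.
#' @param delta Segmental duplication cost (> 0).
#' @param lambda Loss cost (>= 0).
#' @return Object of class `recon_summary` with fields `heights` (named,
#'   nonzero species only), `d_hat`, `d_plain`, `losses`, `cost`, `delta`,
#'   `lambda`.
#' @export
cost_sd <- function(m, delta = 1, lambda = 1) {
  stopifnot(delta > 0, lambda >= 0)
  h <- dup_heights(m)
  ev <- mapping_events(m)
  losses <- count_losses(m)
  d_hat <- sum(h)
  nz <- which(h > 0L)
  heights <- stats::setNames(h[nz], node_names(m$S)[nz])
  out <- list(
    heights = heights,
    h_full = h,
    d_hat = d_hat,
    d_plain = sum(ev == "D", na.rm = TRUE),
    losses = losses,
    cost = delta * d_hat + lambda * losses,
    delta = delta,
    lambda = lambda
  )
  class(out) <- "recon_summary"
  out
}

#' @export
print.recon_summary <- function(x, ...) {
  cat(sprintf(
    "<recon_summary> d_hat=%d  duplication nodes=%d  losses=%d  cost=%g (delta=%g, lambda=%g)\n",
    x$d_hat, x$d_plain, x$losses, x$cost, x$delta, x$lambda
  ))
  if (length(x$heights)) {
    cat("per-species duplication heights:\n")
    for (i in seq_along(x$heights)) {
      cat(sprintf("  %s: %d\n", names(x$heights)[i], x$heights[i]))
    }
  }
  invisible(x)
}

#' Validate a (possibly partial) mapping
#'
#' Checks the partial-mapping property (determinedness is downward-closed),
#' leaf anchoring (`alpha(l) = s(l)`), and validity (every determined node's
#' image is an ancestor-or-equal of each determined descendant's image).
#'
#' @param m A `recon_mapping`.
#' @return `TRUE` if valid, otherwise a character string naming the first
#'   offending node, of class `recon_violation`.
#' @export
validate_mapping <- function(m) {
  a <- m$alpha; G <- m$G; S <- m$S
  bad <- function(msg) structure(msg, class = "recon_violation")
  for (l in G$leaves) {
    want <- m$smap[[as.character(l)]]
    if (is.na(a[l]) || a[l] != want) {
      return(bad(paste0("leaf ", G$label[l], " not anchored to its species")))
    }
  }
  for (v in seq_len(G$n)) {
    p <- G$parent[v]
    if (p == 0L) next
    if (!is.na(a[v]) && is.na(a[p])) next # parent may be undetermined
    if (is.na(a[v]) && !is.na(a[p])) {
      return(bad(paste0("node ", v, " undetermined below determined node ", p)))
    }
    if (!is.na(a[v]) && !is.na(a[p]) && !is_ancestor(S, a[p], a[v])) {
      return(bad(paste0(
        "node ", v, " mapped to ", node_names(S)[a[v]],
        " above its parent's image ", node_names(S)[a[p]]
      )))
    }
  }
  TRUE
}

#' Remap one gene node
#' @param m A `recon_mapping`.
#' @param v Gene node id.
#' @param s Species node id.
#' @return The modified mapping (not checked for validity; see
#'   [validate_mapping()]).
#' @export
remap <- function(m, v, s) {
  m$alpha[v] <- as.integer(s)
  m
}
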