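# Shared fixtures, built in code.

# The reconstructed worked-example instance: species tree (A,(B,C)) with
# internal species E = B|C and F = A|B|C, and a two-tree gene forest whose
# LCA-mapping has duplication heights 1 at A, B, C, E and 2 at F.
worked_instance <- function() {
  S <- parse_newick("(A,(B,C));")
  G <- parse_newick(c(
    "((((B__1,C__1),(B__2,C__2)),((B__3,C__3),A__1)),(B__5,C__5));",
    "((A__3,A__4),((B__6,B__7),(C__6,C__7)));"
  ), expect = "forest")
  smap <- leaf_map(G, S)
  list(S = S, G = G, smap = smap)
}

# Alternative mapping of the worked example: the duplications at B, C and E
# remapped to the species root F, dragging their ancestors along.
worked_alt_alpha <- function(inst) {
  mu <- lca_mapping(inst$G, inst$S, inst$smap)
  a <- mu$alpha
  root_s <- find_nodes(inst$S, "A|B|C")
  for (nm in c("B__1|B__2|C__1|C__2", "B__6|B__7", "C__6|C__7",
               "B__6|B__7|C__6|C__7", "A__3|A__4|B__6|B__7|C__6|C__7")) {
    a[find_nodes(inst$G, nm)] <- root_s
  }
  a
}

# Random small instance via the simulator, resampled until the gene forest
# has an internal-node count in [min_int, max_int] and the brute-force
# enumeration space stays within budget.  Deterministic given the RNG state.
random_small_instance <- function(n_species = 4:6, n_families = 1:2,
                                  min_int = 1, max_int = 7,
                                  max_space = 3e4, tries = 60) {
  for (i in seq_len(tries)) {
    S <- random_species_tree(sample(n_species, 1))
    inst <- tryCatch(
      plant_episodes(S, n_families = sample(n_families, 1),
                     dup_rate = stats::runif(1, 0.1, 0.45),
                     loss_rate = stats::runif(1, 0, 0.25)),
      error = function(e) NULL
    )
    if (is.null(inst)) next
    n_int <- sum(!inst$G$is_leaf)
    if (n_int < min_int || n_int > max_int) next
    mu <- lca_mapping(inst$G, S, inst$smap)$alpha
    space <- prod(vapply(which(!inst$G$is_leaf), function(v) {
      length(ancestors_or_self(S, mu[v]))
    }, integer(1)))
    if (space > max_space) next
    return(inst)
  }
  stop("could not draw a small instance in ", tries, " tries")
}

# Random valid complete mapping: start from mu and remap random nodes upward
# (top-down so validity is preserved).
random_valid_mapping <- function(G, S, smap, p_move = 0.4) {
  mu <- lca_mapping(G, S, smap)
  a <- mu$alpha
  for (v in rev(G$postorder)) { # parents before children
    if (G$is_leaf[v]) next
    if (stats::runif(1) < p_move) {
      top <- if (G$parent[v] == 0L) S$roots[1] else a[G$parent[v]]
      path <- ancestors_or_self(S, a[v])
      path <- path[vapply(path, function(s) is_ancestor(S, top, s), logical(1))]
      a[v] <- path[sample(length(path), 1)]
    }
  }
  new_mapping(G, S, smap, a)
}
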