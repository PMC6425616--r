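# Rooted binary forests -------------------------------------------------------
#
# A `recon_forest` is a node-addressable rooted binary forest: integer node ids
# 1..n, per-node parent links (0 for a root), ordered children (0 or 2), and
# leaf labels that are unique across the whole forest.  A species tree is a
# `recon_forest` with exactly one root (class `recon_tree`).  Ancestry queries
# use precomputed DFS intervals, so is_ancestor() is O(1).

#' Construct a rooted forest from parent links
#'
#' Low-level constructor. Users normally obtain forests from
#' [parse_newick()] or the simulator.
#'
#' @param parent Integer vector; `parent[i]` is the parent id of node `i`,
#'   or 0 if `i` is a root.
#' @param label Character vector; leaf labels, `NA` for internal nodes.
#' @param child_order Optional integer vector of node ids giving the order in
#'   which children are attached to their parents (defaults to ascending id);
#'   lets parsers preserve the source child order.
#' @return An object of class `recon_forest` (and `recon_tree` if it has a
#'   single root).
#' @keywords internal
new_forest <- function(parent, label, child_order = NULL) {
  n <- length(parent)
  stopifnot(length(label) == n, n >= 1L)
  parent <- as.integer(parent)
  if (is.null(child_order)) child_order <- seq_len(n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in as.integer(child_order)) {
    p <- parent[i]
    if (p != 0L) {
      if (p < 1L || p > n) stop("parent id out of range for node ", i)
      children[[p]] <- c(children[[p]], i)
    }
  }
  roots <- which(parent == 0L)
  if (length(roots) == 0L) stop("forest has no root")
  deg <- lengths(children)
  bad <- which(deg != 0L & deg != 2L)
  if (length(bad)) {
    stop("non-binary node: node ", bad[1], " has out-degree ", deg[bad[1]])
  }
  is_leaf <- deg == 0L
  if (any(is_leaf & is.na(label))) stop("leaf without a label")
  labs <- label[is_leaf]
  if (anyDuplicated(labs)) {
    stop("duplicate leaf label: ", labs[duplicated(labs)][1])
  }

  # iterative DFS from each root: depth, tree id, entry/exit intervals, postorder
  depth <- integer(n); tree_id <- integer(n)
  tin <- integer(n); tout <- integer(n)
  postorder <- integer(n)
  clock <- 0L; pi <- 0L
  for (ti in seq_along(roots)) {
    stack <- roots[ti]; state <- 0L # state per stack slot: 0 enter, 1 exit
    st_state <- 0L
    # simple explicit stack of (node, phase)
    nodes <- integer(2L * n); phase <- integer(2L * n); top <- 1L
    nodes[1L] <- roots[ti]; phase[1L] <- 0L
    while (top > 0L) {
      v <- nodes[top]; ph <- phase[top]; top <- top - 1L
      if (ph == 0L) {
        clock <- clock + 1L
        tin[v] <- clock
        tree_id[v] <- ti
        depth[v] <- if (parent[v] == 0L) 0L else depth[parent[v]] + 1L
        top <- top + 1L; nodes[top] <- v; phase[top] <- 1L
        ch <- children[[v]]
        for (c in rev(ch)) { top <- top + 1L; nodes[top] <- c; phase[top] <- 0L }
      } else {
        tout[v] <- clock
        pi <- pi + 1L
        postorder[pi] <- v
      }
    }
  }
  if (pi != n) stop("forest contains a cycle or unreachable nodes")

  f <- list(
    n = n, parent = parent, children = children, label = label,
    roots = roots, tree_id = tree_id, depth = depth,
    tin = tin, tout = tout, postorder = postorder,
    is_leaf = is_leaf, leaves = which(is_leaf)
  )
  class(f) <- if (length(roots) == 1L) c("recon_tree", "recon_forest") else "recon_forest"
  f
}

#' Number of trees in a forest
#' @param f A `recon_forest`.
#' @return Integer count of connected components.
#' @export
n_trees <- function(f) length(f$roots)

#' @export
print.recon_forest <- function(x, ...) {
  cat(sprintf(
    "<recon_%s> %d node(s), %d tree(s), %d leaves\n",
    if (inherits(x, "recon_tree")) "tree" else "forest",
    x$n, length(x$roots), length(x$leaves)
  ))
  invisible(x)
}

# Newick I/O -------------------------------------------------------------------

phylo_to_forest <- function(ph) {
  # single-leaf trees come back from ape with Nnode == 0 or 1 and no edges
  ntip <- length(ph$tip.label)
  if (ntip == 1L) {
    return(new_forest(parent = 0L, label = ph$tip.label))
  }
  n <- ntip + ph$Nnode
  parent <- integer(n)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  label <- rep(NA_character_, n)
  label[seq_len(ntip)] <- ph$tip.label
  # non-binary internal nodes rejected by new_forest, but give the clearer
  # message the parser contract asks for
  deg <- tabulate(ph$edge[, 1], nbins = n)
  bad <- which(deg > 0L & deg != 2L)
  if (length(bad)) stop("non-binary node (out-degree ", deg[bad[1]], ") in Newick input")
  # the edge matrix is in cladewise order, preserving the source child order
  new_forest(parent, label, child_order = ph$edge[, 2])
}

parse_one_newick <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) stop("empty Newick string")
  if (!grepl(";\\s*$", line)) stop("Newick parse error: missing trailing semicolon in: ", line)
  if (!grepl("\\(", line)) {
    # single-leaf tree, e.g. "A;" (possibly with a branch length)
    lab <- sub(";\\s*$", "", line)
    lab <- sub(":.*$", "", lab)
    lab <- gsub("^'|'$", "", trimws(lab))
    if (!nzchar(lab)) stop("Newick parse error: empty leaf label in: ", line)
    return(new_forest(parent = 0L, label = lab))
  }
  ph <- tryCatch(
    ape::read.tree(text = line),
    error = function(e) stop("Newick parse error in \"", line, "\": ", conditionMessage(e))
  )
  if (is.null(ph)) stop("Newick parse error in: ", line)
  phylo_to_forest(ph)
}

#' Parse rooted binary trees from Newick text
#'
#' Standard rooted Newick; branch lengths and internal-node labels are parsed
#' and discarded (the reconciliation model is topology-only).  Quoted labels
#' are supported and the trailing semicolon is required.  With
#' `expect = "forest"`, every non-empty line holds one tree and leaf labels
#' must be unique across the whole forest.
#'
#' @param text Character scalar (may contain newlines) or vector of lines.
#' @param expect Either `"tree"` (exactly one tree) or `"forest"`.
#' @return A `recon_tree` or `recon_forest`.
#' @examples
#' parse_newick("((A,B),C);")
#' parse_newick("((A,B),C);\n(X,Y);", expect = "forest")
#' @export
parse_newick <- function(text, expect = c("tree", "forest")) {
  expect <- match.arg(expect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty Newick input")
  if (expect == "tree") {
    if (length(lines) != 1L) stop("expected a single tree, got ", length(lines), " lines")
    return(parse_one_newick(lines[1]))
  }
  trees <- lapply(lines, parse_one_newick)
  combine_forest(trees)
}

#' Combine a list of trees into one forest
#' @param trees List of `recon_forest` objects.
#' @return A `recon_forest` whose components are the input trees, in order.
#' @keywords internal
combine_forest <- function(trees) {
  offs <- cumsum(c(0L, vapply(trees, function(t) t$n, integer(1))))
  parent <- integer(0); label <- character(0); child_order <- integer(0)
  for (i in seq_along(trees)) {
    t <- trees[[i]]
    p <- t$parent
    p[p != 0L] <- p[p != 0L] + offs[i]
    parent <- c(parent, p)
    label <- c(label, t$label)
    # keep each parent's stored child order across the renumbering
    child_order <- c(child_order, unlist(t$children) + offs[i])
  }
  roots <- which(parent == 0L)
  new_forest(parent, label, child_order = c(roots, child_order))
}

#' Read a species tree from a Newick file
#' @param path File with one rooted binary Newick tree.
#' @return A `recon_tree`.
#' @export
read_species_tree <- function(path) {
  parse_newick(readLines(path, warn = FALSE), expect = "tree")
}

#' Read a gene forest from a multi-Newick file (one tree per line)
#' @param path File path.
#' @return A `recon_forest`.
#' @export
read_gene_forest <- function(path) {
  parse_newick(readLines(path, warn = FALSE), expect = "forest")
}

serialize_node <- function(f, v) {
  if (f$is_leaf[v]) return(f$label[v])
  ch <- f$children[[v]]
  paste0("(", serialize_node(f, ch[1]), ",", serialize_node(f, ch[2]), ")")
}

#' Serialize a forest to Newick strings
#' @param f A `recon_forest`.
#' @return Character vector, one Newick string per tree, preserving child order.
#' @export
write_newick <- function(f) {
  vapply(f$roots, function(r) paste0(serialize_node(f, r), ";"), character(1))
}

# Ancestry machinery -----------------------------------------------------------

#' Ancestor-or-equal test
#'
#' `is_ancestor(f, x, y)` is `TRUE` iff `x` is an ancestor of `y` or `x == y`,
#' within the same tree of the forest. Constant time via DFS intervals.
#' @param f A `recon_forest`.
#' @param x,y Node ids.
#' @return Logical.
#' @export
is_ancestor <- function(f, x, y) {
  f$tree_id[x] == f$tree_id[y] & f$tin[x] <= f$tin[y] & f$tout[y] <= f$tout[x]
}

comparable <- function(f, x, y) is_ancestor(f, x, y) || is_ancestor(f, y, x)

#' Lowest common ancestor of two nodes
#'
#' @param f A `recon_forest` or `recon_tree`.
#' @param x,y Node ids belonging to the same tree; an error is raised for
#'   nodes in different trees of a forest (the LCA is undefined there).
#' @return Node id of the LCA.
#' @export
lca <- function(f, x, y) {
  if (f$tree_id[x] != f$tree_id[y]) {
    stop("LCA undefined: nodes ", x, " and ", y, " are in different trees")
  }
  while (x != y) {
    if (f$depth[x] > f$depth[y]) x <- f$parent[x]
    else if (f$depth[y] > f$depth[x]) y <- f$parent[y]
    else { x <- f$parent[x]; y <- f$parent[y] }
  }
  x
}

#' Arc distance from an ancestor down to a descendant
#'
#' @param f A `recon_forest`.
#' @param x Ancestor-or-equal of `y`.
#' @param y Descendant node.
#' @return Number of arcs on the path; `node_dist(f, x, x)` is 0.
#' @export
node_dist <- function(f, x, y) {
  if (!is_ancestor(f, x, y)) {
    stop("node_dist: node ", y, " is not a descendant of node ", x)
  }
  f$depth[y] - f$depth[x]
}

#' k-th parent of a node
#'
#' Follows the convention in which `par_k(f, x, 0)` is already the parent of
#' `x` (not `x` itself): `par_k(f, x, k)` applies the parent link `k + 1`
#' times.  The parent of a root is the root itself, so the walk clamps there.
#'
#' @param f A `recon_forest`.
#' @param x Node id.
#' @param k Non-negative integer.
#' @return Node id.
#' @export
par_k <- function(f, x, k) {
  stopifnot(k >= 0)
  for (i in seq_len(k + 1L)) {
    p <- f$parent[x]
    if (p == 0L) return(x) # par(root) = root
    x <- p
  }
  x
}

#' Leaf labels under each node
#' @param f A `recon_forest`.
#' @return List of character vectors, indexed by node id.
#' @keywords internal
leafsets <- function(f) {
  out <- vector("list", f$n)
  for (v in f$postorder) {
    if (f$is_leaf[v]) out[[v]] <- f$label[v]
    else out[[v]] <- c(out[[f$children[[v]][1]]], out[[f$children[[v]][2]]])
  }
  out
}

#' Canonical node names
#'
#' A leaf is named by its label; an internal node by the sorted labels of the
#' leaves below it, joined with `"|"`.  These names are stable under node-id
#' renumbering and are used in all text outputs and mapping files.
#'
#' @param f A `recon_forest`.
#' @return Character vector of names, indexed by node id.
#' @export
node_names <- function(f) {
  ls <- leafsets(f)
  vapply(seq_len(f$n), function(v) {
    if (f$is_leaf[v]) f$label[v] else paste(sort(ls[[v]]), collapse = "|")
  }, character(1))
}

#' Look up nodes by canonical name
#' @param f A `recon_forest`.
#' @param names Character vector of canonical names (see [node_names()]).
#' @return Integer node ids; errors on unknown names.
#' @export
find_nodes <- function(f, names) {
  nn <- node_names(f)
  idx <- match(names, nn)
  if (anyNA(idx)) stop("unknown node name: ", names[which(is.na(idx))[1]])
  idx
}

#' Canonical topology string (for isomorphism checks)
#'
#' Serializes with children sorted by their canonical name, so two forests
#' get the same string iff they are isomorphic as leaf-labeled forests.
#' @param f A `recon_forest`.
#' @return Character scalar.
#' @export
canonical_form <- function(f) {
  rec <- function(v) {
    if (f$is_leaf[v]) return(f$label[v])
    parts <- sort(vapply(f$children[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste(sort(vapply(f$roots, rec, character(1))), collapse = ";")
}

#' Ancestors of a node, bottom-up, including the node itself
#' @param f A `recon_forest`.
#' @param v Node id.
#' @return Integer vector `v, par(v), ..., root`.
#' @export
ancestors_or_self <- function(f, v) {
  out <- v
  while (f$parent[v] != 0L) {
    v <- f$parent[v]
    out <- c(out, v)
  }
  out
}
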