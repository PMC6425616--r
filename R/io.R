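# Text outputs and pipelines ---------------------------------------------------
#
# All outputs are plain text.  Internal nodes are referred to by their
# canonical leaf-set names (sorted leaf labels joined with "|"), which are
# stable across runs and parsers.

#' Write a mapping as a three-column TSV
#'
#' Columns: canonical gene node name, canonical species node name, event
#' (`S`/`D`/`C`).  Undetermined nodes are written with `-` in both columns.
#'
#' @param m A `recon_mapping`.
#' @param path Output path.
#' @export
write_mapping_tsv <- function(m, path) {
  gn <- node_names(m$G)
  sn <- node_names(m$S)
  ev <- mapping_events(m)
  sp <- ifelse(is.na(m$alpha), "-", sn[m$alpha])
  df <- data.frame(node = gn, species = sp, event = ifelse(is.na(ev), "-", ev))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a mapping from a TSV of node assignments
#'
#' Accepts the format of [write_mapping_tsv()] (header optional, extra
#' columns ignored): canonical gene node name, canonical species node name.
#' Rows with species `-` leave the node undetermined.  Leaves may be omitted;
#' they are always anchored by the leaf map.
#'
#' @inheritParams lca_mapping
#' @param path Path to the TSV.
#' @return A `recon_mapping` (validated).
#' @export
read_mapping_tsv <- function(G, S, smap, path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) && identical(tolower(tab[1, 1]), "node")) tab <- tab[-1, , drop = FALSE]
  keep <- tab[[2]] != "-"
  tab <- tab[keep, , drop = FALSE]
  gidx <- find_nodes(G, tab[[1]])
  sidx <- find_nodes(S, tab[[2]])
  m <- new_mapping(G, S, smap)
  m$alpha[gidx] <- sidx
  v <- validate_mapping(m)
  if (!isTRUE(v)) stop("mapping file describes an invalid mapping: ", v)
  m
}

#' Score a user-supplied mapping
#'
#' Evaluates the segmental cost of an explicit node-to-species assignment,
#' e.g. to compare alternative duplication scenarios for the same forest.
#'
#' @inheritParams lca_mapping
#' @param mapping A `recon_mapping`, or a path to a TSV readable by
#'   [read_mapping_tsv()].
#' @param delta,lambda Event costs.
#' @return A [cost_sd()] summary.
#' @export
score_mapping <- function(G, S, smap, mapping, delta = 1, lambda = 1) {
  m <- if (inherits(mapping, "recon_mapping")) mapping
       else read_mapping_tsv(G, S, smap, mapping)
  cost_sd(m, delta, lambda)
}

annotate_node <- function(f, v, sn, alpha, ev) {
  tag <- if (is.na(alpha[v])) "" else {
    paste0("[&&NHX:species=", sn[alpha[v]], ":event=", ev[v], "]")
  }
  if (f$is_leaf[v]) return(paste0(f$label[v], tag))
  ch <- f$children[[v]]
  paste0("(", annotate_node(f, ch[1], sn, alpha, ev), ",",
         annotate_node(f, ch[2], sn, alpha, ev), ")", tag)
}

#' Annotated Newick with per-node species and event tags
#'
#' NHX-style comments `[&&NHX:species=...:event=...]` on every determined
#' node.
#'
#' @param m A `recon_mapping`.
#' @return Character vector, one annotated Newick string per gene tree.
#' @export
annotated_newick <- function(m) {
  sn <- node_names(m$S)
  ev <- mapping_events(m)
  vapply(m$G$roots, function(r) {
    paste0(annotate_node(m$G, r, sn, m$alpha, ev), ";")
  }, character(1))
}

#' Write a per-species height summary TSV
#'
#' One row per species node with nonzero duplication height, plus total rows
#' for `d_hat`, the plain duplication count, losses, and the cost.
#'
#' @param summary A `recon_summary`.
#' @param path Output path.
#' @export
write_summary_tsv <- function(summary, path) {
  lines <- c("key\tvalue")
  for (i in seq_along(summary$heights)) {
    lines <- c(lines, paste0("height:", names(summary$heights)[i], "\t",
                             summary$heights[i]))
  }
  lines <- c(
    lines,
    paste0("d_hat\t", summary$d_hat),
    paste0("max_height\t", if (length(summary$heights)) max(summary$heights) else 0L),
    paste0("d_plain\t", summary$d_plain),
    paste0("losses\t", summary$losses),
    paste0("delta\t", format(summary$delta, digits = 17)),
    paste0("lambda\t", format(summary$lambda, digits = 17)),
    paste0("cost\t", format(summary$cost, digits = 17))
  )
  writeLines(lines, path)
}

#' Reconcile input files end to end
#'
#' Reads the species tree, gene forest and leaf map, runs [solve_mprst()],
#' and (optionally) writes the per-node assignment TSV, the per-species
#' summary TSV, the annotated Newick forest, and a manifest echoing the
#' configuration.
#'
#' @param species_tree Path to the species tree Newick file.
#' @param gene_trees Path to the multi-Newick gene forest file.
#' @param leaf_map_file Path to the leaf map TSV, or `NULL` to use the
#'   `SPECIES__geneid` label convention.
#' @param delta,lambda Event costs.
#' @param budget `"auto"` or an integer duplication-height budget.
#' @param out_prefix If non-`NULL`, output files are written as
#'   `<out_prefix>.mapping.tsv`, `.summary.tsv`, `.annotated.nwk`,
#'   `.manifest.tsv`.
#' @param expansion_limit Safety valve for the search.
#' @return The `recon_solution`, invisibly when writing files.
#' @export
run_reconcile <- function(species_tree, gene_trees, leaf_map_file = NULL,
                          delta = 2, lambda = 1, budget = "auto",
                          out_prefix = NULL, expansion_limit = Inf) {
  S <- read_species_tree(species_tree)
  G <- read_gene_forest(gene_trees)
  smap <- if (is.null(leaf_map_file)) leaf_map(G, S)
          else read_leaf_map(G, S, leaf_map_file)
  sol <- solve_mprst(G, S, smap, delta, lambda, budget = budget,
                     expansion_limit = expansion_limit)
  if (!is.null(out_prefix) && sol$feasible) {
    write_mapping_tsv(sol$mapping, paste0(out_prefix, ".mapping.tsv"))
    write_summary_tsv(sol$summary, paste0(out_prefix, ".summary.tsv"))
    writeLines(annotated_newick(sol$mapping), paste0(out_prefix, ".annotated.nwk"))
    writeLines(c(
      "key\tvalue",
      paste0("species_tree\t", species_tree),
      paste0("gene_trees\t", gene_trees),
      paste0("leaf_map\t", if (is.null(leaf_map_file)) "<label convention>" else leaf_map_file),
      paste0("delta\t", format(delta, digits = 17)),
      paste0("lambda\t", format(lambda, digits = 17)),
      paste0("budget\t", paste(budget, collapse = "")),
      paste0("optimal\t", sol$optimal),
      paste0("expansions\t", sol$expansions)
    ), paste0(out_prefix, ".manifest.tsv"))
    return(invisible(sol))
  }
  sol
}

#' Sweep duplication costs on the 16-eukaryote gene-tree compendium
#'
#' Reruns the segmental reconciliation on the classic 53-gene-tree,
#' 16-eukaryote dataset for a range of duplication costs (default
#' `delta` in 1, 28, 61, 62, 100 with `lambda = 1`), reporting `d_hat`, the
#' maximum per-species height, and whether any duplication is placed on the
#' branch leading to the Tetrapoda clade.  The dataset is not bundled: supply
#' a directory containing `species.nwk`, `genes.nwk` and `leafmap.tsv`
#' obtained from the method's public repository.
#'
#' @param dir Directory with the user-supplied dataset files.
#' @param deltas Numeric vector of duplication costs to sweep.
#' @param lambda Loss cost.
#' @param tetrapoda_leaves Character vector of species-tree leaf labels whose
#'   LCA is the Tetrapoda ancestor (used to locate the branch in the
#'   user-supplied tree).
#' @param expansion_limit Safety valve per sweep point.
#' @return Data frame with one row per `delta`: `delta`, `d_hat`,
#'   `max_height`, `losses`, `cost`, `dup_on_tetrapoda` (`NA` if the clade
#'   could not be located).
#' @export
run_experiment_guigo <- function(dir,
                                 deltas = c(1, 28, 61, 62, 100),
                                 lambda = 1,
                                 tetrapoda_leaves = NULL,
                                 expansion_limit = Inf) {
  needed <- file.path(dir, c("species.nwk", "genes.nwk", "leafmap.tsv"))
  if (!all(file.exists(needed))) {
    stop(
      "the 16-eukaryote dataset is not bundled with this package.\n",
      "Place the species tree (species.nwk), the 53 gene trees (genes.nwk, ",
      "one Newick per line) and the leaf map (leafmap.tsv) in ", dir,
      "; they are available from the public repository of the original ",
      "implementation. No download is attempted."
    )
  }
  S <- read_species_tree(needed[1])
  G <- read_gene_forest(needed[2])
  smap <- read_leaf_map(G, S, needed[3])
  tet <- if (!is.null(tetrapoda_leaves)) {
    Reduce(function(a, b) lca(S, a, b), find_nodes(S, tetrapoda_leaves))
  } else NA_integer_
  rows <- lapply(deltas, function(delta) {
    sol <- solve_mprst(G, S, smap, delta, lambda,
                       expansion_limit = expansion_limit)
    s <- sol$summary
    data.frame(
      delta = delta,
      d_hat = s$d_hat,
      max_height = if (length(s$heights)) max(s$heights) else 0L,
      losses = s$losses,
      cost = s$cost,
      dup_on_tetrapoda = if (is.na(tet)) NA else s$h_full[tet] > 0L,
      optimal = sol$optimal
    )
  })
  do.call(rbind, rows)
}
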