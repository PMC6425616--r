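# Seeded simulator of gene-family evolution ------------------------------------
#
# Generates species trees, gene families evolving top-down inside them by
# duplication and loss, and planted segmental episodes (several families
# forced to duplicate on the same species branch), with the true node-to-
# species mapping recorded.  Ground-truth costs are always recomputed through
# cost_sd() on the recorded mapping, so the generator and the scorer cannot
# drift apart.
#
# Generative conventions (see the methods vignette):
#  * a lineage entering a species branch is first lost with probability
#    `loss_rate`, then undergoes the planted episode duplication if one is
#    placed on that branch for its family, then each resulting copy
#    duplicates at most once more with probability `dup_rate`;
#  * planted episodes duplicate each listed family exactly once per entering
#    lineage, so on otherwise event-free instances the duplications of one
#    episode form an antichain of height 1;
#  * fully lost subtrees are pruned with unary-node suppression, so the
#    recorded loss count (computed from the recorded mapping by the
#    reconciliation distance formulas) can exceed the raw number of pruning
#    events.

#' Random rooted binary species tree
#'
#' Uniformly random topology by sequential coalescence of the leaf set,
#' leaves labeled `S1..Sn`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Optional integer seed (local to this call).
#' @return A `recon_tree`.
#' @export
random_species_tree <- function(n_leaves, seed = NULL) {
  stopifnot(n_leaves >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_leaves - 1L
  parent <- integer(n)
  label <- c(paste0("S", seq_len(n_leaves)), rep(NA_character_, n_leaves - 1L))
  active <- seq_len(n_leaves)
  nxt <- n_leaves + 1L
  while (length(active) > 1L) {
    pick <- sample(length(active), 2L)
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  new_forest(parent, label)
}

# recursive top-down simulation of one family; returns a nested node list
# {species, children} / {species, leaf = TRUE} or NULL if the lineage dies
sim_family_rec <- function(S, s, fam, dup_rate, loss_rate, episode_species, env,
                           stage = c("enter", "post_episode", "at_node")) {
  stage <- match.arg(stage)
  dup_node <- function(l, r) {
    if (is.null(l)) return(r)
    if (is.null(r)) return(l)
    list(species = s, children = list(l, r))
  }
  if (stage == "enter") {
    if (stats::runif(1) < loss_rate) {
      env$pruned <- env$pruned + 1L
      return(NULL)
    }
    if (s %in% episode_species) {
      l <- sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "post_episode")
      r <- sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "post_episode")
      return(dup_node(l, r))
    }
    return(sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "post_episode"))
  }
  if (stage == "post_episode") {
    if (stats::runif(1) < dup_rate) {
      l <- sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "at_node")
      r <- sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "at_node")
      return(dup_node(l, r))
    }
    return(sim_family_rec(S, s, fam, dup_rate, loss_rate, episode_species, env, "at_node"))
  }
  # at_node: lineage has reached species node s
  if (S$is_leaf[s]) {
    env$leaf_counter <- env$leaf_counter + 1L
    return(list(species = s, leaf = TRUE,
                label = paste0(S$label[s], "__f", fam, "g", env$leaf_counter)))
  }
  ch <- S$children[[s]]
  l <- sim_family_rec(S, ch[1], fam, dup_rate, loss_rate, episode_species, env, "enter")
  r <- sim_family_rec(S, ch[2], fam, dup_rate, loss_rate, episode_species, env, "enter")
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  list(species = s, children = list(l, r))
}

# flatten a nested simulated tree into parent/label/species vectors
flatten_sim_tree <- function(node) {
  parent <- integer(0); label <- character(0); species <- integer(0)
  add <- function(nd, par) {
    id <- length(parent) + 1L
    parent[id] <<- par
    label[id] <<- if (isTRUE(nd$leaf)) nd$label else NA_character_
    species[id] <<- nd$species
    if (!isTRUE(nd$leaf)) {
      for (c in nd$children) add(c, id)
    }
    id
  }
  add(node, 0L)
  list(parent = parent, label = label, species = species)
}

#' Simulate one gene family inside a species tree
#'
#' Top-down birth-death walk: the family starts as one lineage at the species
#' root; on each species branch a lineage may be lost or duplicate (see the
#' module comments for the event order), and surviving lineages end at
#' species leaves as extant genes labeled `SPECIES__f<fam>g<k>`.  Extinct
#' families are resampled up to `retry` times.
#'
#' @param S Species tree.
#' @param fam Integer family index (used in leaf labels).
#' @param dup_rate,loss_rate Per-branch event probabilities in `[0, 1]`.
#' @param episode_species Integer vector of species node ids where this
#'   family is forced to duplicate (planted episodes).
#' @param retry Resampling cap for extinct families.
#' @return List with `tree` (a single-tree `recon_forest`), `true_species`
#'   (integer vector: the recorded species node per gene node), and
#'   `pruned` (number of loss events drawn).
#' @export
evolve_family <- function(S, fam, dup_rate, loss_rate,
                          episode_species = integer(0), retry = 100L) {
  stopifnot(dup_rate >= 0, dup_rate <= 1, loss_rate >= 0, loss_rate <= 1)
  if (length(episode_species) && any(episode_species < 1L | episode_species > S$n)) {
    stop("episode references a species node outside the tree")
  }
  for (i in seq_len(retry)) {
    env <- new.env(parent = emptyenv())
    env$leaf_counter <- 0L
    env$pruned <- 0L
    nd <- sim_family_rec(S, S$roots[1], fam, dup_rate, loss_rate,
                         episode_species, env, "enter")
    if (!is.null(nd)) {
      flat <- flatten_sim_tree(nd)
      tree <- new_forest(flat$parent, flat$label)
      return(list(tree = tree, true_species = flat$species, pruned = env$pruned))
    }
  }
  stop("family ", fam, " went extinct in ", retry, " consecutive resamples")
}

#' Simulate a multi-family instance with planted segmental episodes
#'
#' Generates `n_families` gene families in the given (or freshly simulated)
#' species tree and returns the instance together with its ground truth.
#'
#' @param S A species tree, or an integer leaf count to simulate one.
#' @param n_families Number of gene families.
#' @param dup_rate,loss_rate Per-branch background event probabilities.
#' @param episodes List of planted episodes, each a list with `species`
#'   (a species node id or canonical node name) and `families` (integer
#'   indices of the families that duplicate there).
#' @param seed Optional integer seed (local to this call).
#' @return A list of class `sim_instance`: `S`, `G`, `smap`, `truth` (a
#'   complete `recon_mapping` of the recorded scenario), `truth_summary`
#'   (its [cost_sd()] at `delta = 1, lambda = 1`), `episodes` (normalized,
#'   with node ids), `params`.
#' @export
plant_episodes <- function(S, n_families, dup_rate = 0, loss_rate = 0,
                           episodes = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(S) && length(S) == 1L) S <- random_species_tree(S)
  episodes <- lapply(episodes, function(e) {
    sp <- e$species
    if (is.character(sp)) sp <- find_nodes(S, sp)
    list(species = as.integer(sp), families = as.integer(e$families))
  })
  fams <- lapply(seq_len(n_families), function(f) {
    ep <- unlist(lapply(episodes, function(e) if (f %in% e$families) e$species))
    evolve_family(S, f, dup_rate, loss_rate,
                  episode_species = if (is.null(ep)) integer(0) else ep)
  })
  G <- combine_forest(lapply(fams, `[[`, "tree"))
  true_species <- unlist(lapply(fams, `[[`, "true_species"))
  smap <- leaf_map(G, S) # label convention SPECIES__geneid
  truth <- new_mapping(G, S, smap, alpha = true_species)
  v <- validate_mapping(truth)
  if (!isTRUE(v)) stop("internal error: simulated ground truth invalid: ", v)
  out <- list(
    S = S, G = G, smap = smap, truth = truth,
    truth_summary = cost_sd(truth, 1, 1),
    episodes = episodes,
    params = list(n_families = n_families, dup_rate = dup_rate,
                  loss_rate = loss_rate, seed = seed)
  )
  class(out) <- "sim_instance"
  out
}

#' Write a simulated instance to plain-text fixture files
#'
#' Emits `species.nwk`, `genes.nwk` (one tree per line), `leafmap.tsv`,
#' `truth_mapping.tsv` (canonical gene node name, species node name, event),
#' and `manifest.tsv` (key-value pairs, including the seed and episode list).
#' [read_fixture()] reproduces the instance exactly.
#'
#' @param inst A `sim_instance`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(inst, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(inst$S), file.path(dir, "species.nwk"))
  writeLines(write_newick(inst$G), file.path(dir, "genes.nwk"))
  write_leaf_map(inst$smap, inst$G, inst$S, file.path(dir, "leafmap.tsv"))
  write_mapping_tsv(inst$truth, file.path(dir, "truth_mapping.tsv"))
  ep <- vapply(inst$episodes, function(e) {
    paste0(node_names(inst$S)[e$species], ":", paste(e$families, collapse = ","))
  }, character(1))
  man <- c(
    paste0("n_families\t", inst$params$n_families),
    paste0("dup_rate\t", format(inst$params$dup_rate, digits = 17)),
    paste0("loss_rate\t", format(inst$params$loss_rate, digits = 17)),
    paste0("seed\t", if (is.null(inst$params$seed)) "NA" else inst$params$seed),
    paste0("episodes\t", paste(ep, collapse = ";"))
  )
  writeLines(man, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read back a fixture written by [write_fixture()]
#' @param dir Directory containing the fixture files.
#' @return A list with `S`, `G`, `smap`, `truth`, `manifest` (named character
#'   vector).
#' @export
read_fixture <- function(dir) {
  S <- read_species_tree(file.path(dir, "species.nwk"))
  G <- read_gene_forest(file.path(dir, "genes.nwk"))
  smap <- read_leaf_map(G, S, file.path(dir, "leafmap.tsv"))
  truth <- read_mapping_tsv(G, S, smap, file.path(dir, "truth_mapping.tsv"))
  man_lines <- readLines(file.path(dir, "manifest.tsv"), warn = FALSE)
  kv <- strsplit(man_lines, "\t", fixed = TRUE)
  manifest <- stats::setNames(
    vapply(kv, function(x) if (length(x) > 1L) x[2] else "", character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  list(S = S, G = G, smap = smap, truth = truth, manifest = manifest)
}

#' Parse an episode specification string
#'
#' Format: `speciesNodeName:fam1,fam2;speciesNodeName:fam3` where species
#' node names are canonical names (see [node_names()]).
#' @param spec Character scalar (possibly empty).
#' @return A list of episodes suitable for [plant_episodes()].
#' @export
parse_episode_spec <- function(spec) {
  if (is.null(spec) || !nzchar(trimws(spec))) return(list())
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed episode spec: ", p)
    list(species = kv[1],
         families = as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
  })
}
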