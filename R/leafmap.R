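# Gene-leaf -> species-leaf maps ----------------------------------------------

#' Build a leaf map from a two-column table
#'
#' The map sends every gene-forest leaf label to a species-tree leaf label.
#' It must be total on gene leaves but need not be injective (several genes
#' of one family in the same species) nor surjective (species without genes).
#'
#' @param G Gene forest (`recon_forest`).
#' @param S Species tree (`recon_tree`).
#' @param table Data frame or matrix with columns gene label, species label,
#'   or `NULL` to derive the map from the `SPECIES__geneid` label convention.
#' @return Named integer vector `smap`: for each gene leaf node id (names are
#'   the ids), the species-tree leaf node id it maps to.  Class `leaf_map`.
#' @export
leaf_map <- function(G, S, table = NULL) {
  gl <- G$label[G$leaves]
  if (is.null(table)) {
    sp <- sub("__.*$", "", gl)
    missing_sep <- !grepl("__", gl)
    if (any(missing_sep)) {
      stop(
        "no mapping table given and gene leaf \"", gl[missing_sep][1],
        "\" does not follow the SPECIES__geneid convention"
      )
    }
  } else {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (ncol(table) < 2L) stop("leaf map table needs two columns: gene, species")
    idx <- match(gl, as.character(table[[1]]))
    if (anyNA(idx)) stop("gene leaf without a species assignment: ", gl[which(is.na(idx))[1]])
    sp <- as.character(table[[2]])[idx]
  }
  sidx <- match(sp, S$label[S$leaves])
  if (anyNA(idx <- which(is.na(sidx)))) {
    stop("species leaf \"", sp[idx[1]], "\" (for gene \"", gl[idx[1]], "\") not in the species tree")
  }
  smap <- S$leaves[sidx]
  names(smap) <- as.character(G$leaves)
  structure(smap, class = "leaf_map")
}

#' Read a leaf map from a TSV file
#'
#' File format: two whitespace/tab-separated columns, `gene_leaf species_leaf`,
#' no header. Lines starting with `#` are ignored.
#'
#' @inheritParams leaf_map
#' @param path Path to the mapping file.
#' @return A `leaf_map` (see [leaf_map()]).
#' @export
read_leaf_map <- function(G, S, path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  leaf_map(G, S, tab)
}

#' Write a leaf map to a TSV file
#' @param smap A `leaf_map`.
#' @param G,S The forest and species tree it refers to.
#' @param path Output path.
#' @export
write_leaf_map <- function(smap, G, S, path) {
  gl <- G$label[as.integer(names(smap))]
  sl <- S$label[as.integer(smap)]
  utils::write.table(data.frame(gene = gl, species = sl),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
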