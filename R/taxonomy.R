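# Rank-annotated taxonomy trees supporting ancestor and LCA queries.
# Nodes are (taxon_id, parent_id, rank, name); the root points to itself
# (or has an empty parent).

#' Build a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. The root is the unique node whose parent is itself or `NA`.
#' @return an object of class `taxonomy_tree` with components `nodes`,
#'   `root`, and named lookup vectors `parent`, `rank`, `name`, `depth`
#'   (root depth 1).
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  missing <- setdiff(req, names(nodes))
  if (length(missing)) stopf("taxonomy: missing column '%s'", missing[1])
  id <- as.character(nodes$taxon_id)
  if (anyDuplicated(id))
    stopf("taxonomy: duplicated taxon_id %s", id[duplicated(id)][1])
  parent <- as.character(nodes$parent_id)
  is_root <- is.na(parent) | parent == "" | parent == id
  if (sum(is_root) != 1L)
    stopf("taxonomy must have exactly one root, found %d", sum(is_root))
  root <- id[is_root]
  orphan <- setdiff(parent[!is_root], id)
  if (length(orphan))
    stopf("taxonomy: node with absent parent taxon_id %s", orphan[1])

  pmap <- stats::setNames(parent, id)
  pmap[root] <- NA_character_
  # depth by walking to the root; also detects cycles
  n <- length(id)
  depth <- stats::setNames(rep(NA_integer_, n), id)
  for (i in id) {
    path <- i
    cur <- i
    while (!is.na(pmap[[cur]])) {
      cur <- pmap[[cur]]
      if (cur %in% path)
        stopf("taxonomy cycle: %s", paste(c(path, cur), collapse = " -> "))
      path <- c(path, cur)
      if (length(path) > n) stopf("taxonomy cycle involving %s", i)
    }
    depth[[i]] <- length(path)
  }
  structure(list(nodes = nodes, root = root, parent = pmap,
                 rank = stats::setNames(as.character(nodes$rank), id),
                 name = stats::setNames(as.character(nodes$name), id),
                 depth = depth),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root %s (%s), max depth %d\n",
              nrow(x$nodes), x$root, x$name[[x$root]], max(x$depth)))
  invisible(x)
}

#' Read a taxonomy table
#'
#' @param path TSV with header columns `taxon_id`, `parent_id`, `rank`,
#'   `name`; `#` lines are comments.
#' @return a [taxonomy_tree()] (validated: single root, no orphans, no
#'   cycles).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  taxonomy_tree(df)
}

#' @rdname read_taxonomy
#' @param tree a `taxonomy_tree`.
#' @param params optional named list recorded in the `#` comment block.
#' @export
write_taxonomy <- function(tree, path, params = NULL) {
  write_commented_tsv(tree$nodes, path, params)
}

.check_taxa <- function(tree, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown)) stopf("unknown taxon: %s", unknown[1])
  taxa
}

#' Ancestors of a taxon (self first, root last)
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon a single taxon id.
#' @return character vector of taxon ids from `taxon` up to the root.
#' @export
tax_ancestors <- function(tree, taxon) {
  taxon <- .check_taxa(tree, taxon)[1]
  path <- taxon
  while (!is.na(tree$parent[[taxon]])) {
    taxon <- tree$parent[[taxon]]
    path <- c(path, taxon)
  }
  path
}

#' Test descent from a clade root
#'
#' @param tree a `taxonomy_tree`.
#' @param taxa taxon ids (vectorised).
#' @param clade_root taxon id of the clade root.
#' @return logical: is each taxon the clade root or one of its descendants?
#' @export
tax_is_descendant <- function(tree, taxa, clade_root) {
  clade_root <- .check_taxa(tree, clade_root)[1]
  vapply(.check_taxa(tree, taxa), function(t)
    clade_root %in% tax_ancestors(tree, t), logical(1), USE.NAMES = FALSE)
}

#' Ancestor-or-self at a given rank
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon a single taxon id.
#' @param rank rank label, e.g. `"family"`.
#' @return the taxon id of the ancestor (or self) with that rank, or `NA`
#'   if the lineage has none.
#' @export
tax_ancestor_at_rank <- function(tree, taxon, rank) {
  path <- tax_ancestors(tree, taxon)
  hit <- path[tree$rank[path] == rank]
  if (length(hit)) hit[1] else NA_character_
}
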