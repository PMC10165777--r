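# Food-source assignment: filter nucleotide hits of non-mosquito contigs,
# resolve equal-best hits to their last common ancestor, lift to family and
# genus rank, and aggregate per-kingdom profiles.

#' Filter candidate food-source hits
#'
#' Hits to arthropod taxa (presumptive host contigs) are removed first;
#' the survivors must satisfy all three criteria: e-value at most 1e-5,
#' aligned fragment strictly longer than 200 bp, and alignment covering
#' strictly more than 80 percent of the contig. Query coverage is
#' recomputed from the supplied contig lengths (clamped to 1 for gapped
#' alignments); coverage columns in the input are ignored.
#'
#' @param hits nucleotide-space hit data.frame (see [read_hit_table()]).
#' @param contig_lengths named vector of contig lengths; every query must
#'   be present.
#' @param tree optional [taxonomy_tree()] used for the arthropod exclusion.
#' @param arthropod_root taxon id of the arthropod clade root in `tree`.
#' @param evalue_max,min_fragment,min_coverage the three criteria.
#' @return the retained hit rows with recomputed `query_coverage`.
#' @export
filter_food_hits <- function(hits, contig_lengths, tree = NULL,
                             arthropod_root = NULL, evalue_max = 1e-5,
                             min_fragment = 200, min_coverage = 0.80) {
  missing <- setdiff(hits$query_id, names(contig_lengths))
  if (length(missing)) stopf("no length for contig %s", missing[1])
  if (!is.null(tree) && !is.null(arthropod_root) && nrow(hits)) {
    known <- as.character(hits$subject_taxon_id) %in% names(tree$parent)
    arth <- known
    arth[known] <- tax_is_descendant(tree, hits$subject_taxon_id[known],
                                     arthropod_root)
    hits <- hits[!arth, , drop = FALSE]
  }
  if (!nrow(hits)) return(hits)
  hits$query_coverage <- pmin(1, hits$aligned_length /
                                 contig_lengths[hits$query_id])
  keep <- hits$evalue <= evalue_max &
    hits$aligned_length > min_fragment &
    hits$query_coverage > min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Last common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon.
#'
#' @param taxa taxon ids (all must exist in the tree).
#' @param tree a [taxonomy_tree()].
#' @return a single taxon id.
#' @export
lca <- function(taxa, tree) {
  taxa <- unique(.check_taxa(tree, taxa))
  if (!length(taxa)) stopf("lca of an empty set")
  cur <- taxa[1]
  for (t in taxa[-1]) {
    anc <- tax_ancestors(tree, cur)
    depths <- tree$depth[anc]
    walk <- t
    while (!(walk %in% anc)) walk <- tree$parent[[walk]]
    cur <- walk
  }
  cur
}

#' Assign one contig to a food source
#'
#' The equal-best hit set contains every hit whose bitscore is within
#' `bitscore_tolerance` of the maximum. A single best hit is assigned to
#' its own taxon; multiple equal-best hits are assigned to their last
#' common ancestor. The assignment is then lifted to family rank (and
#' genus, where resolvable); an LCA above family rank is reported as
#' unresolved, and assignments landing in fungi are discarded.
#'
#' @param hits filtered hits of one contig (>= 1 row).
#' @param tree a [taxonomy_tree()] with `kingdom`, `family` and `genus`
#'   ranks.
#' @param bitscore_tolerance hits with `bitscore >= max - tolerance` count
#'   as equal-best. The default 0 (exact equality) is the conservative
#'   reading of "equivalent bitscores".
#' @param fungi_root taxon id of the fungal clade, or `NULL` to skip the
#'   fungi exclusion.
#' @return one-row data.frame: `contig_id`, `assigned_taxon`,
#'   `assigned_rank`, `family`, `genus` (names, `NA` when unresolved),
#'   `kingdom`, `status` (`resolved`, `unresolved`, `discarded_fungi`),
#'   `supporting_hits`.
#' @export
assign_food_source <- function(hits, tree, bitscore_tolerance = 0,
                               fungi_root = NULL) {
  if (!nrow(hits)) stopf("assign_food_source needs at least one hit")
  contig <- hits$query_id[1]
  best <- max(hits$bitscore)
  eq <- hits[hits$bitscore >= best - bitscore_tolerance, , drop = FALSE]
  taxa <- unique(as.character(eq$subject_taxon_id))
  node <- if (length(taxa) == 1) .check_taxa(tree, taxa) else lca(taxa, tree)

  row <- data.frame(contig_id = contig, assigned_taxon = node,
                    assigned_rank = unname(tree$rank[node]),
                    family = NA_character_, genus = NA_character_,
                    kingdom = NA_character_, status = "unresolved",
                    supporting_hits = nrow(eq), stringsAsFactors = FALSE)
  if (!is.null(fungi_root) && tax_is_descendant(tree, node, fungi_root)) {
    row$status <- "discarded_fungi"
    return(row)
  }
  king <- tax_ancestor_at_rank(tree, node, "kingdom")
  if (!is.na(king)) row$kingdom <- unname(tree$name[king])
  fam <- tax_ancestor_at_rank(tree, node, "family")
  if (is.na(fam)) return(row)      # LCA above family rank: unresolved
  gen <- tax_ancestor_at_rank(tree, node, "genus")
  row$family <- unname(tree$name[fam])
  row$genus <- if (!is.na(gen)) unname(tree$name[gen]) else NA_character_
  row$status <- "resolved"
  row
}

#' Assign many contigs at once
#'
#' @param hits filtered hit data.frame covering several contigs; each
#'   contig is assigned independently from its own equal-best set.
#' @param library_of optional named vector mapping contig id to library id
#'   (added as a `library_id` column).
#' @inheritParams assign_food_source
#' @return data.frame with one row per contig.
#' @export
assign_food_sources <- function(hits, tree, bitscore_tolerance = 0,
                                fungi_root = NULL, library_of = NULL) {
  parts <- split(hits, hits$query_id)
  out <- do.call(rbind, lapply(parts, assign_food_source, tree = tree,
                               bitscore_tolerance = bitscore_tolerance,
                               fungi_root = fungi_root))
  rownames(out) <- NULL
  if (!is.null(library_of)) out$library_id <- unname(library_of[out$contig_id])
  out
}

#' Aggregate food-source assignments into family profiles
#'
#' Counts resolved contig assignments per (family, library), split by
#' kingdom (Metazoa = bloodmeal sources, Viridiplantae = plant diet), with
#' an optional roll-up to mosquito species.
#'
#' @param assignments output of [assign_food_sources()] with a
#'   `library_id` column.
#' @param libraries library metadata (used for the species roll-up); may be
#'   `NULL`.
#' @return list with `metazoa` and `viridiplantae` family x library count
#'   matrices, and (when `libraries` is given) `metazoa_by_species` /
#'   `viridiplantae_by_species`.
#' @export
aggregate_food_profile <- function(assignments, libraries = NULL) {
  res <- assignments[assignments$status == "resolved" &
                       !is.na(assignments$kingdom), , drop = FALSE]
  one_kingdom <- function(kingdom) {
    sub <- res[res$kingdom == kingdom, , drop = FALSE]
    if (!nrow(sub))
      return(matrix(0L, 0, 0, dimnames = list(character(), character())))
    tab <- table(sub$family, sub$library_id)
    matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  }
  out <- list(metazoa = one_kingdom("Metazoa"),
              viridiplantae = one_kingdom("Viridiplantae"))
  if (!is.null(libraries)) {
    sp <- stats::setNames(libraries$species, libraries$library_id)
    roll <- function(m) {
      if (!ncol(m)) return(m)
      t(rowsum(t(m), group = sp[colnames(m)]))
    }
    out$metazoa_by_species <- roll(out$metazoa)
    out$viridiplantae_by_species <- roll(out$viridiplantae)
  }
  out
}

#' Family x library presence matrix from assignments
#'
#' Presence of a food family in a library means at least one resolved
#' contig assignment; the matrix spans every library in the metadata so it
#' can be paired with an OTU presence matrix in co-occurrence tests.
#'
#' @param assignments output of [assign_food_sources()] with `library_id`.
#' @param libraries library metadata data.frame.
#' @return logical family x library matrix.
#' @export
food_presence_matrix <- function(assignments, libraries) {
  res <- assignments[assignments$status == "resolved" &
                       !is.na(assignments$family), , drop = FALSE]
  libs <- libraries$library_id
  fams <- sort(unique(res$family))
  m <- matrix(FALSE, length(fams), length(libs),
              dimnames = list(fams, libs))
  if (nrow(res))
    m[cbind(match(res$family, fams), match(res$library_id, libs))] <- TRUE
  m
}

#' Food-family saturation curve
#'
#' Mean number of distinct families observed in the first `m` libraries,
#' averaged over random library orderings; the curve is monotone
#' non-decreasing by construction.
#'
#' @param family_sets named list: per library, the character vector of
#'   families detected (>= 2 libraries).
#' @param orderings number of random orderings.
#' @param seed integer seed.
#' @return data.frame `n_libraries`, `mean_families`, `sd_families`.
#' @export
saturation_curve <- function(family_sets, orderings = 100, seed = 1) {
  n <- length(family_sets)
  if (n < 2) stopf("saturation curve needs >= 2 libraries")
  set.seed(seed)
  counts <- matrix(0, orderings, n)
  for (o in seq_len(orderings)) {
    ord <- sample.int(n)
    seen <- character(0)
    for (m in seq_len(n)) {
      seen <- union(seen, family_sets[[ord[m]]])
      counts[o, m] <- length(seen)
    }
  }
  data.frame(n_libraries = seq_len(n),
             mean_families = colMeans(counts),
             sd_families = apply(counts, 2, stats::sd))
}
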