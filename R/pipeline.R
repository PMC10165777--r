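# End-to-end discovery driver: candidate selection -> false-positive
# removal -> length filter -> greedy clustering -> OTU table with novelty
# and completeness calls.

#' Run the virus-discovery filter chain
#'
#' Applies, in order: database-specific candidate selection
#' ([select_viral_candidates()]), false-positive removal against host and
#' general databases ([remove_false_positives()]), the strict >300 nt
#' length rule ([filter_by_length()]), CD-HIT-style greedy clustering of
#' the surviving contigs at the nucleotide deduplication threshold
#' ([greedy_cluster()]), and per-cluster novelty
#' ([classify_novelty()]) and completeness ([call_completeness()]) calls
#' on the representative's best hits.
#'
#' @param hits_by_db named list of protein-space hit tables
#'   (`genbank_viral`, `ictv_vmr`, `rdrp_cdd`).
#' @param contigs named character vector (or coercible
#'   [Biostrings::DNAStringSet]) of contig sequences.
#' @param host_hits,nr_nt_hits competitor hit tables for false-positive
#'   removal (may be `NULL` / empty).
#' @param nt_hits nucleotide-space hits against known viruses; the best
#'   hit per contig supplies the nucleotide identity of the novelty rule
#'   (absent hit = nucleotide condition satisfied).
#' @param cutoffs candidate e-value cutoffs, see
#'   [select_viral_candidates()].
#' @param cluster_threshold nucleotide identity above which contigs are
#'   redundant duplicates (default 0.90).
#' @param min_length length rule, exclusive (default 300 nt).
#' @param identity_fn optional clustering identity engine (see
#'   [greedy_cluster()]).
#' @return data.frame with one row per virus OTU: `otu_id`,
#'   `representative`, `members` (semicolon-joined), `novelty`,
#'   `completeness`, `closest_known`, `closest_aa_identity`,
#'   `closest_nt_identity`, `rules`.
#' @export
discover_viruses <- function(hits_by_db, contigs, host_hits = NULL,
                             nr_nt_hits = NULL, nt_hits = NULL,
                             cutoffs = DEFAULT_CANDIDATE_CUTOFFS,
                             cluster_threshold = 0.90, min_length = 300,
                             identity_fn = NULL) {
  contigs <- stats::setNames(as.character(contigs), names(contigs))
  cand <- select_viral_candidates(hits_by_db, cutoffs)
  cand <- remove_false_positives(cand, host_hits = host_hits,
                                 nr_nt_hits = nr_nt_hits)
  cand <- filter_by_length(cand, nchar(contigs), min_length = min_length)
  if (!nrow(cand))
    return(data.frame(otu_id = character(), representative = character(),
                      members = character(), novelty = character(),
                      completeness = character(),
                      closest_known = character(),
                      closest_aa_identity = numeric(),
                      closest_nt_identity = numeric(), rules = character(),
                      stringsAsFactors = FALSE))
  seqs <- data.frame(id = cand$contig_id,
                     sequence = unname(contigs[cand$contig_id]),
                     stringsAsFactors = FALSE)
  cl <- greedy_cluster(seqs, threshold = cluster_threshold,
                       identity_fn = identity_fn, mode = "nucleotide")

  nt_best <- NULL
  if (!is.null(nt_hits) && nrow(nt_hits)) {
    sp <- split(nt_hits, nt_hits$query_id)
    nt_best <- vapply(sp, function(h)
      h$pct_identity[which.max(h$bitscore)], numeric(1))
  }
  reps <- unique(cl$representative)
  rows <- lapply(seq_along(reps), function(i) {
    rep_id <- reps[i]
    members <- cl$id[cl$representative == rep_id]
    info <- cand[cand$contig_id == rep_id, ]
    nt_id <- if (!is.null(nt_best) && rep_id %in% names(nt_best))
      unname(nt_best[rep_id]) else NA_real_
    data.frame(
      otu_id = sprintf("OTU_%03d", i), representative = rep_id,
      members = paste(sort(members), collapse = ";"),
      novelty = classify_novelty(info$pct_identity, nt_id),
      completeness = call_completeness(info$subject_coverage),
      closest_known = info$subject_id,
      closest_aa_identity = info$pct_identity,
      closest_nt_identity = nt_id, rules = info$rules,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
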