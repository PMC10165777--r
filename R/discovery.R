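# Virus discovery filter chain: database-specific candidate selection,
# false-positive removal, CD-HIT-style greedy clustering of contigs,
# novelty/completeness calls and multi-segment co-assignment.

DEFAULT_CANDIDATE_CUTOFFS <- list(genbank_viral = 1e-5, ictv_vmr = 1e-5,
                                  rdrp_cdd = 1e-2)

#' Select candidate viral contigs from database-specific hit tables
#'
#' A contig is a candidate if it has at least one hit passing the e-value
#' cutoff of its database: a viral-protein database and a curated
#' RNA-virus reference set at 1e-5, and RdRp profile (domain) searches at
#' the more permissive 1e-2. Each candidate records which rule(s) fired and
#' carries its maximum-bitscore passing hit.
#'
#' @param hits_by_db named list of hit data.frames (see [read_hit_table()]);
#'   allowed names: `genbank_viral`, `ictv_vmr`, `rdrp_cdd`.
#' @param cutoffs named list of e-value cutoffs per database key.
#' @return data.frame: `contig_id`, `rules` (semicolon-joined database keys
#'   whose cutoff passed), and best-hit fields `best_db`, `subject_id`,
#'   `pct_identity`, `evalue`, `bitscore`, `subject_coverage`.
#' @export
select_viral_candidates <- function(hits_by_db,
                                    cutoffs = DEFAULT_CANDIDATE_CUTOFFS) {
  unknown <- setdiff(names(hits_by_db), names(DEFAULT_CANDIDATE_CUTOFFS))
  if (length(unknown))
    stopf("unknown hit-table key '%s' (expected %s)", unknown[1],
          paste(names(DEFAULT_CANDIDATE_CUTOFFS), collapse = ", "))
  unknown <- setdiff(names(cutoffs), names(DEFAULT_CANDIDATE_CUTOFFS))
  if (length(unknown)) stopf("unknown cutoff key '%s'", unknown[1])

  passing <- lapply(names(hits_by_db), function(db) {
    h <- hits_by_db[[db]]
    h <- h[h$evalue <= cutoffs[[db]], , drop = FALSE]
    if (nrow(h)) h$db <- db
    h
  })
  passing <- passing[vapply(passing, nrow, 1L) > 0]
  if (!length(passing))
    return(data.frame(contig_id = character(), rules = character(),
                      best_db = character(), subject_id = character(),
                      pct_identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), subject_coverage = numeric(),
                      stringsAsFactors = FALSE))
  all_pass <- do.call(rbind, lapply(passing, function(h)
    h[c("query_id", "subject_id", "pct_identity", "evalue", "bitscore",
        "subject_coverage", "db")]))
  split_by_contig <- split(all_pass, all_pass$query_id)
  rows <- lapply(split_by_contig, function(h) {
    best <- h[order(-h$bitscore, h$subject_id), , drop = FALSE][1, ]
    data.frame(contig_id = best$query_id,
               rules = paste(sort(unique(h$db)), collapse = ";"),
               best_db = best$db, subject_id = best$subject_id,
               pct_identity = best$pct_identity, evalue = best$evalue,
               bitscore = best$bitscore,
               subject_coverage = best$subject_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove false-positive candidates
#'
#' A candidate is dropped when its best overall hit -- the maximum bitscore
#' across the viral evidence and all provided competitor tables (mosquito
#' host genome matches, general protein/nucleotide database matches) -- is
#' non-viral, or when its best viral subject is a retrovirus. Retained
#' candidates therefore have their best hit among RNA-virus (Riboviria,
#' excluding retroviruses) proteins.
#'
#' @param candidates output of [select_viral_candidates()].
#' @param host_hits hit data.frame against the host (Culicidae) genome, or
#'   `NULL`.
#' @param nr_nt_hits best hits against general databases, or `NULL`. Rows
#'   whose `subject_taxon_id` is in `viral_taxa` are counted as viral
#'   support, all others as non-viral competitors.
#' @param viral_taxa taxon ids regarded as viral in `nr_nt_hits`.
#' @param retro_subjects subject ids that are retroviruses; candidates whose
#'   best viral subject is among them are dropped.
#' @return the retained candidate rows with a `best_hit_is_riboviria`
#'   column (all `TRUE`).
#' @export
remove_false_positives <- function(candidates, host_hits = NULL,
                                   nr_nt_hits = NULL, viral_taxa = character(),
                                   retro_subjects = character()) {
  if (!nrow(candidates)) {
    candidates$best_hit_is_riboviria <- logical(0)
    return(candidates)
  }
  best_competitor <- stats::setNames(rep(-Inf, nrow(candidates)),
                                     candidates$contig_id)
  gather <- function(hits, viral_ok) {
    if (is.null(hits) || !nrow(hits)) return()
    if (viral_ok)
      hits <- hits[!(as.character(hits$subject_taxon_id) %in%
                       as.character(viral_taxa)), , drop = FALSE]
    if (!nrow(hits)) return()
    agg <- tapply(hits$bitscore, hits$query_id, max)
    common <- intersect(names(agg), names(best_competitor))
    best_competitor[common] <<- pmax(best_competitor[common], agg[common])
  }
  gather(host_hits, viral_ok = FALSE)
  gather(nr_nt_hits, viral_ok = TRUE)

  keep <- candidates$bitscore >= best_competitor[candidates$contig_id] &
    !(candidates$subject_id %in% retro_subjects)
  out <- candidates[keep, , drop = FALSE]
  out$best_hit_is_riboviria <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Length filter for candidate contigs
#'
#' Contigs are kept only if strictly longer than `min_length` nucleotides.
#'
#' @param candidates candidate data.frame with a `contig_id` column.
#' @param contig_lengths named numeric vector of contig lengths (nt).
#' @param min_length minimum length, exclusive. Default 300.
#' @return the retained rows, with a `contig_length_nt` column.
#' @export
filter_by_length <- function(candidates, contig_lengths, min_length = 300) {
  missing <- setdiff(candidates$contig_id, names(contig_lengths))
  if (length(missing)) stopf("no length for contig %s", missing[1])
  len <- contig_lengths[candidates$contig_id]
  out <- candidates[len > min_length, , drop = FALSE]
  out$contig_length_nt <- unname(len[len > min_length])
  rownames(out) <- NULL
  out
}

#' Pairwise sequence identity from a global alignment
#'
#' Identity is the number of matching columns divided by the total number
#' of alignment columns (gap columns included) of a Needleman-Wunsch global
#' alignment with unit match score, mismatch -1, gap opening 2 and gap
#' extension 1. The definition is symmetric and `identity(x, x) = 1`.
#'
#' @param seq_a,seq_b character strings (non-empty).
#' @param mode `"nucleotide"` or `"protein"`.
#' @return identity as a fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("empty sequence")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (mode == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    a <- Biostrings::DNAString(seq_a); b <- Biostrings::DNAString(seq_b)
  } else {
    letters <- Biostrings::AA_ALPHABET
    mat <- matrix(-1, length(letters), length(letters),
                  dimnames = list(letters, letters))
    diag(mat) <- 1
    a <- Biostrings::AAString(seq_a); b <- Biostrings::AAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / ncol_aln
}

#' CD-HIT-style greedy incremental clustering
#'
#' Sequences are processed in order of decreasing length (ties broken by
#' lexicographic id). Each sequence joins the first existing cluster whose
#' representative it matches at an identity strictly greater than the
#' threshold, otherwise it seeds a new cluster. Because sequences are
#' processed longest-first, the representative is always the longest member.
#'
#' @param seqs data.frame with columns `id`, `sequence` and optionally
#'   `length` (defaults to `nchar(sequence)`).
#' @param threshold identity threshold in `(0, 1]`, exclusive (a pair at
#'   exactly the threshold is not merged).
#' @param identity_fn pairwise identity provider
#'   `function(seq_a, seq_b) -> [0,1]`; defaults to [pairwise_identity()]
#'   in the given `mode`. Any CD-HIT-compatible engine can be substituted.
#' @param mode alphabet for the default identity engine.
#' @return data.frame with columns `id`, `cluster` (integer),
#'   `representative` (id of the cluster representative), `is_representative`.
#' @export
greedy_cluster <- function(seqs, threshold,
                           identity_fn = NULL,
                           mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  if (is.null(identity_fn))
    identity_fn <- function(a, b) pairwise_identity(a, b, mode = mode)
  if (!nrow(seqs))
    return(data.frame(id = character(), cluster = integer(),
                      representative = character(),
                      is_representative = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(seqs$length)) seqs$length <- nchar(seqs$sequence)
  ord <- order(-seqs$length, seqs$id)
  seqs <- seqs[ord, , drop = FALSE]

  rep_idx <- integer(0)          # row index of each cluster representative
  assignment <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    joined <- 0L
    for (ci in seq_along(rep_idx)) {
      idt <- identity_fn(seqs$sequence[i], seqs$sequence[rep_idx[ci]])
      if (idt > threshold) { joined <- ci; break }
    }
    if (joined == 0L) {
      rep_idx <- c(rep_idx, i)
      joined <- length(rep_idx)
    }
    assignment[i] <- joined
  }
  data.frame(id = seqs$id, cluster = assignment,
             representative = seqs$id[rep_idx[assignment]],
             is_representative = seq_len(nrow(seqs)) %in% rep_idx,
             stringsAsFactors = FALSE)
}

#' Classify virus novelty from identities to the closest known homolog
#'
#' A virus is novel when it matches its closest known relative at less than
#' 80 percent amino-acid identity and less than 90 percent nucleotide
#' identity (both strict). An absent nucleotide identity (no
#' nucleotide-level homolog found) satisfies the nucleotide condition.
#'
#' @param closest_aa_identity amino-acid identity in `[0, 100]`.
#' @param closest_nt_identity nucleotide identity in `[0, 100]` or `NA`.
#' @param aa_max,nt_max the two thresholds (percent).
#' @return character vector, `"novel"` or `"known"` (vectorised).
#' @export
classify_novelty <- function(closest_aa_identity, closest_nt_identity = NA,
                             aa_max = 80, nt_max = 90) {
  n <- max(length(closest_aa_identity), length(closest_nt_identity))
  aa <- rep_len(closest_aa_identity, n)
  nt <- rep_len(closest_nt_identity, n)
  if (any(is.na(aa))) stopf("aa identity must be present")
  if (any(aa < 0 | aa > 100) || any(!is.na(nt) & (nt < 0 | nt > 100)))
    stopf("identity outside [0,100]")
  ifelse(aa < aa_max & (is.na(nt) | nt < nt_max), "novel", "known")
}

#' Call RdRp completeness from coverage of the closest known virus
#'
#' The RdRp is "complete or nearly complete" when the alignment covers
#' strictly more than 80 percent of the known virus protein.
#'
#' @param best_subject_coverage coverage fraction in `[0, 1]` (vectorised).
#' @param min_coverage threshold, exclusive. Default 0.80.
#' @return `"complete"` or `"partial"`.
#' @export
call_completeness <- function(best_subject_coverage, min_coverage = 0.80) {
  if (any(best_subject_coverage < 0 | best_subject_coverage > 1, na.rm = TRUE))
    stopf("coverage outside [0,1]")
  ifelse(best_subject_coverage > min_coverage, "complete", "partial")
}

#' Relative synonymous codon usage (RSCU) vector
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family. Stop codons and the single-codon families (ATG, TGG)
#' are uninformative, leaving 59 codons. Families absent from the sequence
#' get RSCU 0.
#'
#' @param sequence an in-frame coding nucleotide sequence (length is
#'   truncated to a multiple of 3).
#' @return named numeric vector over the 59 informative codons.
#' @export
rscu_vector <- function(sequence) {
  gc <- Biostrings::GENETIC_CODE
  informative <- names(gc)[gc != "*" &
                             gc %in% names(which(table(gc[gc != "*"]) > 1))]
  sequence <- toupper(sequence)
  n <- (nchar(sequence) %/% 3) * 3
  if (n < 3) stopf("sequence too short for codon usage")
  codons <- substring(sequence, seq(1, n - 2, 3), seq(3, n, 3))
  counts <- table(factor(codons, levels = names(gc)))
  out <- stats::setNames(numeric(length(informative)), informative)
  for (aa in unique(gc[informative])) {
    fam <- informative[gc[informative] == aa]
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- as.numeric(counts[fam]) * length(fam) / tot
  }
  out
}

.cosine_dist <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

.jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Co-assign genome segments to one virus
#'
#' Segmented RNA viruses leave one OTU per segment; segments of the same
#' virus co-occur across libraries and share codon-usage bias. Two OTUs are
#' linked when the Jaccard similarity of their presence profiles is at
#' least `jaccard_min` and the cosine distance of their RSCU vectors is at
#' most `rscu_max_dist`; segment groups are the connected components of the
#' link graph. This rule is a heuristic; both knobs are reported in the
#' result attributes.
#'
#' @param presence logical OTU x library matrix (rownames = OTU ids).
#' @param rscu numeric matrix of RSCU vectors (rownames = OTU ids); OTUs
#'   without an RSCU row are excluded from linking with a warning and form
#'   singleton groups.
#' @param jaccard_min minimum presence-profile Jaccard similarity.
#' @param rscu_max_dist maximum RSCU cosine distance.
#' @return named character vector mapping OTU id to segment-group label.
#' @export
link_segments <- function(presence, rscu, jaccard_min = 0.8,
                          rscu_max_dist = 0.1) {
  otus <- rownames(presence)
  linkable <- otus[otus %in% rownames(rscu)]
  skipped <- setdiff(otus, linkable)
  if (length(skipped))
    warnf("no RSCU vector for OTU %s; excluded from segment linking",
          paste(skipped, collapse = ", "))
  n <- length(linkable)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      jac <- .jaccard(presence[linkable[i], ], presence[linkable[j], ])
      if (jac >= jaccard_min &&
          .cosine_dist(rscu[linkable[i], ], rscu[linkable[j], ]) <=
            rscu_max_dist)
        adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  # connected components by BFS
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  labels <- stats::setNames(rep(NA_character_, length(otus)), otus)
  labels[linkable] <- sprintf("seg%02d", comp)
  for (s in skipped) {
    cur <- cur + 1L
    labels[s] <- sprintf("seg%02d", cur)
  }
  structure(labels, jaccard_min = jaccard_min, rscu_max_dist = rscu_max_dist)
}
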