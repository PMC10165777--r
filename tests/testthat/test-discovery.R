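mk_hits <- function(...) do.call(rbind, list(...))
hit <- function(q, s = "ref", evalue = 1e-10, bits = 200, pident = 50,
                len = 300, qlen = NA, slen = NA, staxid = NA,
                type = "protein")
  viromeflow:::.hit_row(q, s, pident, len, evalue, bits, qlen, slen, staxid,
                        search_type = type)

test_that("candidate selection applies the three database cutoffs", {
  hits <- list(genbank_viral = hit("c_gb", evalue = 1e-4),
               rdrp_cdd = hit("c_cdd", evalue = 1e-3),
               ictv_vmr = hit("c_all", evalue = 1e-7))
  hits$genbank_viral <- rbind(hits$genbank_viral,
                              hit("c_all", evalue = 1e-6, bits = 300))
  hits$rdrp_cdd <- rbind(hits$rdrp_cdd, hit("c_all", evalue = 1e-5))
  cand <- select_viral_candidates(hits)
  # domain-only evidence at 1e-3 passes its permissive 1e-2 cutoff
  expect_true("c_cdd" %in% cand$contig_id)
  expect_equal(cand$rules[cand$contig_id == "c_cdd"], "rdrp_cdd")
  # a 1e-4 hit against the 1e-5 databases is not a candidate
  expect_false("c_gb" %in% cand$contig_id)
  # all three rules recorded, best hit is the max-bitscore one
  expect_equal(cand$rules[cand$contig_id == "c_all"],
               "genbank_viral;ictv_vmr;rdrp_cdd")
  expect_equal(cand$bitscore[cand$contig_id == "c_all"], 300)
  expect_error(select_viral_candidates(list(foo = hit("x"))), "foo")
})

test_that("false-positive removal compares best bitscores and drops host", {
  cand <- select_viral_candidates(list(
    genbank_viral = mk_hits(hit("host_like", bits = 150),
                            hit("viral", bits = 200),
                            hit("lonely", bits = 90))))
  host <- mk_hits(hit("host_like", s = "mosquito_scaffold", bits = 400),
                  hit("viral", bits = 150))
  kept <- remove_false_positives(cand, host_hits = host)
  expect_setequal(kept$contig_id, c("viral", "lonely"))
  expect_true(all(kept$best_hit_is_riboviria))
  # retroviral best subjects are excluded from Riboviria
  kept2 <- remove_false_positives(cand, retro_subjects = "ref")
  expect_equal(nrow(kept2), 0L)
})

test_that("length rule is strict and order-stable in the chain", {
  hits <- list(genbank_viral = mk_hits(hit("a"), hit("b"), hit("c")))
  lens <- c(a = 301, b = 300, c = 5000)
  cand <- select_viral_candidates(hits)
  after <- filter_by_length(cand, lens)
  expect_setequal(after$contig_id, c("a", "c"))
  # filtering lengths before candidate selection gives the same final set
  pre <- names(lens)[lens > 300]
  hits_pre <- list(genbank_viral =
    hits$genbank_viral[hits$genbank_viral$query_id %in% pre, ])
  expect_setequal(select_viral_candidates(hits_pre)$contig_id,
                  after$contig_id)
})

test_that("pairwise identity matches hand-computed global alignments", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwise_identity("MKV", "MKV", mode = "protein"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  # symmetry and self-identity on random sequences
  set.seed(5)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("greedy clustering reproduces the worked example and edge cases", {
  ident <- matrix(c(1, .95, .5, .95, 1, .5, .5, .5, 1), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # encode each sequence as its own id so the stub engine can look it up
  seqs <- data.frame(id = c("A", "B", "C"), sequence = c("A", "B", "C"),
                     length = c(30, 20, 10), stringsAsFactors = FALSE)
  cl <- greedy_cluster(seqs, 0.90, identity_fn = function(a, b) ident[a, b])
  expect_equal(sort(cl$representative[cl$id %in% c("A", "B")]),
               c("A", "A"))
  expect_equal(cl$representative[cl$id == "C"], "C")

  one <- greedy_cluster(seqs[1, ], 0.9,
                        identity_fn = function(a, b) stop("unused"))
  expect_equal(one$cluster, 1L)
  all_same <- data.frame(id = paste0("s", 1:5),
                         sequence = paste0("s", 1:5),
                         length = 5:1, stringsAsFactors = FALSE)
  cl5 <- greedy_cluster(all_same, 0.9, identity_fn = function(a, b) 1.0)
  expect_equal(length(unique(cl5$cluster)), 1L)
  expect_equal(cl5$representative[1], "s1")  # longest member represents
})

test_that("greedy clustering satisfies the all-pairs oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 20
    ids <- sprintf("q%02d", 1:n)
    m <- matrix(stats::runif(n * n, 0.2, 1), n, n,
                dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    seqs <- data.frame(id = ids, sequence = ids,
                       length = sample(100:1000, n),
                       stringsAsFactors = FALSE)
    thr <- 0.9
    cl <- greedy_cluster(seqs, thr, identity_fn = function(a, b) m[a, b])
    # every member within threshold of its representative
    expect_true(all(m[cbind(cl$id, cl$representative)] > thr |
                      cl$id == cl$representative))
    # no two representatives within threshold of each other
    reps <- unique(cl$representative)
    if (length(reps) > 1) {
      pairs <- utils::combn(reps, 2)
      expect_true(all(m[t(pairs)] <= thr))
    }
  }
})

test_that("novelty rule is strict, handles absent nt identity, monotone", {
  expect_equal(classify_novelty(79.9, 89.9), "novel")
  expect_equal(classify_novelty(85.0, 89.0), "known")
  expect_equal(classify_novelty(80.0, 90.0), "known")   # boundary: strict
  expect_equal(classify_novelty(79.9, NA), "novel")     # no nt homolog
  expect_equal(classify_novelty(85.0, NA), "known")
  expect_error(classify_novelty(101, 50), "\\[0,100\\]")
  # monotone: decreasing either identity never flips novel -> known
  set.seed(7)
  for (i in 1:50) {
    aa <- stats::runif(1, 0, 100); nt <- stats::runif(1, 0, 100)
    if (classify_novelty(aa, nt) == "novel") {
      expect_equal(classify_novelty(aa * 0.9, nt), "novel")
      expect_equal(classify_novelty(aa, nt * 0.9), "novel")
    }
  }
})

test_that("completeness call is strict at 80% subject coverage", {
  expect_equal(call_completeness(0.85), "complete")
  expect_equal(call_completeness(0.80), "partial")
  expect_equal(call_completeness(1.0), "complete")
  expect_error(call_completeness(1.2), "\\[0,1\\]")
})

test_that("RSCU vectors cover the 59 informative codons", {
  v <- rscu_vector("ATGGCTGCCGCAGCG")  # ATG + all four Ala codons once
  expect_length(v, 59)
  expect_false("ATG" %in% names(v))
  expect_false("TGG" %in% names(v))
  ala <- c("GCT", "GCC", "GCA", "GCG")
  expect_equal(unname(v[ala]), rep(1, 4))  # uniform family -> RSCU 1
  expect_true(all(v[setdiff(names(v), ala)] == 0))
})

test_that("segment linkage requires both co-occurrence and codon usage", {
  pres <- rbind(s1 = c(TRUE, TRUE, TRUE, FALSE),
                s2 = c(TRUE, TRUE, TRUE, FALSE),
                s3 = c(FALSE, FALSE, FALSE, TRUE),
                s4 = c(TRUE, TRUE, TRUE, TRUE))
  r <- rscu_vector(paste(rep("GCTGAACGT", 30), collapse = ""))
  rscu <- rbind(s1 = r, s2 = r, s3 = r, s4 = r * 0 + 1)
  # identical presence + identical RSCU -> linked
  g <- link_segments(pres, rscu)
  expect_equal(g[["s1"]], g[["s2"]])
  # disjoint presence (Jaccard 0) -> never linked
  expect_false(g[["s3"]] == g[["s1"]])
  # Jaccard 3/4 against jaccard_min 0.8 -> not linked
  expect_equal(viromeflow:::.jaccard(pres["s1", ], pres["s4", ]), 0.75)
  expect_false(g[["s4"]] == g[["s1"]])
  # OTU without an RSCU vector is excluded with a warning
  expect_warning(g2 <- link_segments(pres, rscu[1:3, ]), "s4")
  expect_false(is.na(g2[["s4"]]))
})
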