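food_hit <- function(q, staxid, evalue = 1e-8, len = 300, bits = 500,
                     pident = 95)
  viromeflow:::.hit_row(q, paste0("acc_", staxid), pident, len, evalue,
                        bits, NA, len + 50, staxid,
                        search_type = "nucleotide")

test_that("food-hit filter enforces the three criteria and host exclusion", {
  tree <- fixture_taxonomy()
  lens <- c(c1 = 280, c2 = 280, c3 = 280, c4 = 600, c5 = 280, c6 = 280)
  hits <- rbind(
    food_hit("c1", "62", evalue = 1e-6, len = 250),    # all criteria pass
    food_hit("c2", "62", evalue = 1e-6, len = 200),    # fragment boundary
    food_hit("c3", "62", evalue = 1e-4, len = 250),    # e-value fails
    food_hit("c4", "62", evalue = 1e-6, len = 250),    # coverage 250/600
    food_hit("c5", "27", evalue = 1e-9, len = 250),    # arthropod subject
    food_hit("c6", "62", evalue = 1e-5, len = 230))    # e-value boundary: kept
  kept <- filter_food_hits(hits, lens, tree, "20")
  expect_setequal(kept$query_id, c("c1", "c6"))
  # retained hits satisfy every criterion; filtering is idempotent
  expect_true(all(kept$evalue <= 1e-5 & kept$aligned_length > 200 &
                    kept$query_coverage > 0.8))
  expect_equal(filter_food_hits(kept, lens, tree, "20"), kept)
  expect_error(filter_food_hits(hits, lens[-1], tree, "20"), "c1")
})

test_that("LCA agrees with the path-intersection oracle on the fixture", {
  tree <- fixture_taxonomy()
  expect_equal(lca(c("62", "62"), tree), "62")
  expect_equal(tree$name[[lca(c("60", "61"), tree)]], "Hominidae")
  expect_equal(tree$name[[lca(c("60", "80"), tree)]], "Eukaryota")
  expect_error(lca(c("60", "9999"), tree), "9999")
  set.seed(21)
  species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
  for (i in 1:40) {
    taxa <- as.character(sample(species, sample(2:4, 1)))
    expect_equal(lca(taxa, tree), lca_oracle(taxa, tree))
  }
})

test_that("assignment lifts best hits to family, ties to their LCA", {
  tree <- fixture_taxonomy()
  # dominant Bos taurus hit
  a <- assign_food_source(rbind(food_hit("x", "62", bits = 500),
                                food_hit("x", "60", bits = 420)), tree)
  expect_equal(a$family, "Bovidae")
  expect_equal(a$genus, "Bos")
  expect_equal(a$kingdom, "Metazoa")
  expect_equal(a$status, "resolved")
  expect_equal(a$supporting_hits, 1L)
  # equal-bitscore tie between two hominid species -> family, no genus
  b <- assign_food_source(rbind(food_hit("y", "60", bits = 500),
                                food_hit("y", "61", bits = 500)), tree)
  expect_equal(b$family, "Hominidae")
  expect_true(is.na(b$genus))
  expect_equal(b$supporting_hits, 2L)
  # cross-kingdom tie resolves above family -> unresolved
  d <- assign_food_source(rbind(food_hit("z", "60", bits = 500),
                                food_hit("z", "80", bits = 500)), tree)
  expect_equal(d$status, "unresolved")
  expect_true(is.na(d$family))
  # fungal assignment is discarded
  f <- assign_food_source(food_hit("w", "87"), tree, fungi_root = "12")
  expect_equal(f$status, "discarded_fungi")
  # a bitscore tolerance turns a near-tie into an LCA call
  g <- assign_food_source(rbind(food_hit("v", "60", bits = 500),
                                food_hit("v", "61", bits = 499.5)), tree,
                          bitscore_tolerance = 1)
  expect_equal(g$family, "Hominidae")
  expect_equal(g$supporting_hits, 2L)
})

test_that("family profiles conserve counts and split kingdoms", {
  tree <- fixture_taxonomy()
  libs <- data.frame(library_id = c("L1", "L2"),
                     species = c("Ae.alb", "Cx.pip"),
                     location = c("HK", "SY"), year = c(2018L, 2019L),
                     n_nonrrna_reads = c(1e6, 1e6), stringsAsFactors = FALSE)
  hits <- rbind(food_hit("m1", "60"), food_hit("m2", "60"),
                food_hit("m3", "60"), food_hit("m4", "82"),
                food_hit("m5", "84"))
  asg <- assign_food_sources(hits, tree,
                             library_of = c(m1 = "L1", m2 = "L1", m3 = "L1",
                                            m4 = "L2", m5 = "L1"))
  prof <- aggregate_food_profile(asg, libs)
  expect_equal(prof$metazoa["Hominidae", "L1"], 3L)
  expect_equal(sum(prof$metazoa), sum(asg$kingdom == "Metazoa" &
                                        asg$status == "resolved"))
  expect_equal(sum(prof$viridiplantae),
               sum(asg$kingdom == "Viridiplantae" & asg$status == "resolved"))
  expect_equal(unname(prof$viridiplantae_by_species["Poaceae", "Cx.pip"]), 1L)
  # empty assignments give empty tables
  empty <- aggregate_food_profile(asg[0, ], libs)
  expect_equal(dim(empty$metazoa), c(0L, 0L))
  # presence matrix spans all libraries
  fp <- food_presence_matrix(asg, libs)
  expect_equal(colnames(fp), libs$library_id)
  expect_true(fp["Hominidae", "L1"])
  expect_false(fp["Hominidae", "L2"])
})

test_that("saturation curves are monotone with the expected extremes", {
  same <- list(L1 = c("A", "B"), L2 = c("A", "B"), L3 = c("A", "B"))
  flat <- saturation_curve(same, orderings = 20, seed = 1)
  expect_equal(flat$mean_families, rep(2, 3))
  disjoint <- list(L1 = "A", L2 = "B", L3 = "C", L4 = "D")
  lin <- saturation_curve(disjoint, orderings = 20, seed = 1)
  expect_equal(lin$mean_families, 1:4)
  set.seed(9)
  random <- lapply(1:6, function(i) sample(LETTERS[1:8], sample(1:5, 1)))
  names(random) <- paste0("L", 1:6)
  cur <- saturation_curve(random, orderings = 30, seed = 2)
  expect_true(all(diff(cur$mean_families) >= 0))
  expect_equal(cur$mean_families,
               saturation_curve(random, orderings = 30, seed = 2)$mean_families)
  expect_error(saturation_curve(same[1]), ">= 2")
})
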