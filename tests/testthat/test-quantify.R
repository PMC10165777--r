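test_that("expressed call is strict at 50% reference coverage", {
  expect_true(call_expressed(0.51))
  expect_false(call_expressed(0.50))
  expect_true(call_expressed(1.0))
  expect_error(call_expressed(1.5), "\\[0,1\\]")
})

test_that("RPM follows the formula and is scale invariant", {
  expect_equal(compute_rpm(500, 1e6), 500)
  expect_equal(compute_rpm(0, 1e6), 0)
  expect_equal(compute_rpm(123, 2e6), 61.5)
  expect_equal(compute_rpm(123, 2e6), compute_rpm(123 * 7, 2e6 * 7))
  expect_error(compute_rpm(10, 0, library_id = "L9"), "L9")
})

test_that("Shannon index matches closed forms and respects its bounds", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  set.seed(3)
  for (i in 1:50) {
    x <- stats::rexp(sample(1:12, 1))
    h <- shannon_index(x)
    expect_gte(h, 0)
    expect_lte(h, log(sum(x > 0)) + 1e-12)
  }
})

make_mapping <- function() {
  data.frame(
    otu_id = c("o1", "o1", "o2", "o2", "o3"),
    library_id = c("L1", "L2", "L1", "L2", "L1"),
    mapped_reads = c(100, 200, 50, 7, 3),
    ref_coverage = c(0.9, 0.8, 0.45, 0.7, 0.95),
    stringsAsFactors = FALSE)
}

make_libs <- function() {
  data.frame(library_id = c("L1", "L2"), species = c("Ae.alb", "Ae.alb"),
             location = c("HK", "SY"), year = c(2018L, 2019L),
             n_nonrrna_reads = c(1e6, 2e6), stringsAsFactors = FALSE)
}

test_that("abundance matrix zeroes non-expressed cells", {
  am <- build_abundance_matrix(make_mapping(), make_libs())
  expect_equal(dim(am$rpm), c(3L, 2L))
  expect_true(all(am$rpm[!am$present] == 0))
  expect_false(am$present["o2", "L1"])   # coverage 0.45 below the rule
  expect_equal(am$rpm["o1", "L1"], 100)
  expect_equal(am$rpm["o2", "L2"], 3.5)
  dv <- diversity_table(am)
  expect_equal(dv$richness, c(2L, 2L))
  expect_equal(dv$shannon[1], shannon_index(am$rpm[am$present[, 1], 1]))
})

test_that("downsampling is identity at rate 1, binomial otherwise", {
  mapping <- make_mapping()
  libs <- make_libs()
  full <- downsample_dataset(mapping, libs, rate = 1, seed = 1)[[1]]
  ref <- build_abundance_matrix(mapping, libs)
  expect_identical(full$rpm, ref$rpm)
  expect_identical(full$present, ref$present)

  big <- data.frame(otu_id = "o1", library_id = "L1",
                    mapped_reads = 1e6, ref_coverage = 0.9,
                    stringsAsFactors = FALSE)
  reps <- downsample_dataset(big, make_libs(), rate = 0.5, seed = 9,
                             replicates = 30)
  # recover counts: rpm * scaled denominator / 1e6
  counts <- vapply(reps, function(a) a$rpm["o1", "L1"] * 5e5 / 1e6,
                   numeric(1))
  se <- sqrt(1e6 * 0.25) / sqrt(30)
  expect_lt(abs(mean(counts) - 5e5), 3 * se * sqrt(30))  # 3 sd of one draw
  # fixed seed reproducibility, bit-identical
  again <- downsample_dataset(big, make_libs(), rate = 0.5, seed = 9,
                              replicates = 30)
  expect_identical(lapply(reps, `[[`, "rpm"), lapply(again, `[[`, "rpm"))
})

test_that("expected richness is non-increasing as the rate drops", {
  set.seed(2)
  mapping <- data.frame(
    otu_id = rep(sprintf("o%02d", 1:10), each = 4),
    library_id = rep(c("L1", "L2"), 20),
    mapped_reads = sample(1:6, 40, TRUE),
    ref_coverage = stats::runif(40, 0.55, 1),
    stringsAsFactors = FALSE)
  libs <- make_libs()
  mean_rich <- vapply(c(0.25, 0.5, 1), function(rate) {
    reps <- downsample_dataset(mapping, libs, rate, seed = 31,
                               replicates = 40)
    mean(vapply(reps, function(a) sum(a$present), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rich) >= 0))
})

test_that("rank-sum test: exact regime matches exhaustive enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_equal(rank_sum_test(c(4, 5, 6), c(4, 5, 6))$p_value, 1)
  expect_error(rank_sum_test(c(1, 2), c(3, 4, 5)), "at least 3")
  set.seed(13)
  for (i in 1:20) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    if (nx + ny > 8) next
    v <- sample(100, nx + ny)        # tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    res <- rank_sum_test(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, perm_ranksum_p(x, y), tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2, tolerance = 1e-9)
  expect_equal(res$statistic, kw_h_oracle(list(1:3, 4:6, 7:9)),
               tolerance = 1e-9)
  expect_equal(res$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  flat <- kruskal_wallis(list(rep(2, 3), rep(2, 4), rep(2, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # tie-rich random groups still agree with the oracle
  set.seed(17)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) sample(1:4, sample(3:6, 1), TRUE))
    expect_equal(kruskal_wallis(g)$statistic, kw_h_oracle(g),
                 tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3, 4:6)), ">=3 groups")
})

triangle_am <- function() {
  # two libraries at distance 3, 4, 5 from each other (right triangle)
  rpm <- rbind(o1 = c(0, 3, 0), o2 = c(0, 0, 4))
  colnames(rpm) <- c("L1", "L2", "L3")
  structure(list(rpm = rpm, present = rpm > 0, otus = rownames(rpm),
                 libraries = colnames(rpm)), class = "abundance_matrix")
}

test_that("classical MDS reproduces Euclidean geometry", {
  ord <- composition_ordination(triangle_am(), transform = "none")
  d <- as.matrix(stats::dist(ord[, c("MDS1", "MDS2")]))
  expect_equal(sort(d[upper.tri(d)]), c(3, 4, 5), tolerance = 1e-6)

  # identical libraries land on the same point
  am <- triangle_am()
  am$rpm <- cbind(am$rpm, L4 = am$rpm[, "L3"])
  am$present <- am$rpm > 0
  am$libraries <- colnames(am$rpm)
  ord2 <- composition_ordination(am, transform = "none")
  p3 <- unlist(ord2[ord2$library_id == "L3", c("MDS1", "MDS2")])
  p4 <- unlist(ord2[ord2$library_id == "L4", c("MDS1", "MDS2")])
  expect_equal(p3, p4, tolerance = 1e-8)

  # adding a constant OTU to every library changes no distance
  am3 <- triangle_am()
  am3$rpm <- rbind(am3$rpm, o3 = c(7, 7, 7))
  am3$present <- am3$rpm > 0
  am3$otus <- rownames(am3$rpm)
  ord3 <- composition_ordination(am3, transform = "none")
  d3 <- as.matrix(stats::dist(ord3[, c("MDS1", "MDS2")]))
  expect_equal(sort(d3[upper.tri(d3)]), c(3, 4, 5), tolerance = 1e-6)

  # degenerate all-equal matrix: zero coordinates and a warning
  am4 <- triangle_am()
  am4$rpm[] <- 5; am4$present[] <- TRUE
  expect_warning(ord4 <- composition_ordination(am4, transform = "none"),
                 "degenerate")
  expect_true(all(ord4$MDS1 == 0 & ord4$MDS2 == 0))
})

test_that("k-means recovers planted clusters and is deterministic", {
  set.seed(8)
  base1 <- c(rep(100, 10), rep(0, 10))
  base2 <- rev(base1)
  rpm <- rbind(
    do.call(rbind, lapply(1:6, function(i) base1 + stats::runif(20, 0, 2))),
    do.call(rbind, lapply(1:6, function(i) base2 + stats::runif(20, 0, 2))))
  rownames(rpm) <- sprintf("o%02d", 1:12)
  colnames(rpm) <- sprintf("L%02d", 1:20)
  am <- structure(list(rpm = rpm, present = rpm > 0, otus = rownames(rpm),
                       libraries = colnames(rpm)),
                  class = "abundance_matrix")
  cl <- cluster_virus_profiles(am, k = 2, seed = 4)
  expect_equal(length(unique(cl[1:6])), 1L)
  expect_equal(length(unique(cl[7:12])), 1L)
  expect_false(cl[[1]] == cl[[7]])
  expect_identical(c(cl), c(cluster_virus_profiles(am, k = 2, seed = 4)))
  # k = number of OTUs: every OTU its own cluster, zero WCSS
  cl_all <- cluster_virus_profiles(am, k = 12, seed = 4)
  expect_equal(length(unique(cl_all)), 12L)
  expect_equal(attr(cl_all, "fit")$tot.withinss, 0, tolerance = 1e-9)
  expect_error(cluster_virus_profiles(am, k = 13, seed = 1), "exceeds")
})

test_that("virus sharing recomputes the worked fractions from integers", {
  # 54 distinct viruses across three species, 46 exclusive
  sets <- list(A = c(sprintf("a%02d", 1:20), paste0("s", 1:4)),
               B = c(sprintf("b%02d", 1:16), paste0("s", 1:8)),
               C = c(sprintf("c%02d", 1:10), paste0("s", 5:8)))
  sh <- virus_sharing(sets)
  expect_equal(sh$total, 54L)
  expect_equal(sh$exclusive, 46L)
  expect_equal(sh$pct_exclusive, 85.19)
  expect_equal(unname(100 * sh$exclusive / sh$total),
               100 * 46 / 54, tolerance = 1e-12)

  # 4 of 17 island viruses shared with other regions
  sh2 <- virus_sharing(list(
    hainan = sprintf("h%02d", 1:17),
    continents = c(sprintf("h%02d", 1:4), sprintf("e%02d", 1:30))))
  pg <- sh2$per_group
  expect_equal(pg$n_shared[pg$group == "hainan"], 4)
  expect_equal(pg$pct_shared[pg$group == "hainan"], 23.53)

  # identical groups: nothing exclusive
  sh3 <- virus_sharing(list(x = letters[1:5], y = letters[1:5]))
  expect_equal(sh3$pct_exclusive, 0)
  expect_equal(unname(sh3$degree_counts["2"]), 5L)
  expect_error(virus_sharing(list(a = "x")), "2 groups")
})

test_that("transmission labels require presence in every sampled year", {
  pres <- rbind(v1 = c(TRUE, TRUE, TRUE),
                v2 = c(FALSE, TRUE, FALSE),
                v3 = c(TRUE, FALSE, TRUE))
  colnames(pres) <- 2018:2020
  lab <- classify_transmission(pres)
  expect_equal(unname(lab), c("vertical-candidate", "environment-derived",
                              "environment-derived"))
  # restricting the required years changes the call
  lab2 <- classify_transmission(pres, years_required = c("2018", "2020"))
  expect_equal(unname(lab2["v3"]), "vertical-candidate")
  expect_error(classify_transmission(pres, years_required = "2021"), "2021")
})
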