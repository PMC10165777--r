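# Independent oracles and small fixtures used across the suite.

# Upper-tail hypergeometric by direct summation of the pmf (independent of
# stats::phyper).
hyper_upper_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(nx+ny, nx) rank assignments (tie-free inputs).
perm_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H by the standard rank formula with tie correction,
# assembled independently of stats::kruskal.test.
kw_h_oracle <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# LCA by full ancestor-path intersection (deepest shared node).
lca_oracle <- function(taxa, tree) {
  paths <- lapply(unique(as.character(taxa)),
                  function(t) tax_ancestors(tree, t))
  shared <- Reduce(intersect, paths)
  shared[which.max(tree$depth[shared])]
}

# A 5-node linear lineage used by taxonomy I/O tests.
linear_tree_df <- function() {
  data.frame(taxon_id = 1:5, parent_id = c(1, 1:4),
             rank = c("no rank", "kingdom", "class", "family", "species"),
             name = paste0("node", 1:5), stringsAsFactors = FALSE)
}

# Write a hit table body (no header) to a temp file.
write_hit_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Two standard 12-column rows, one with scientific-notation fields.
hit12 <- function(q = "c1", s = "s1", pident = "90.5", len = "400",
                  evalue = "1e-06", bits = "350") {
  paste(q, s, pident, len, "38", "1", "1", len, "1", len, evalue, bits,
        sep = "\t")
}

# One small simulated dataset shared by the heavier tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(seed = 11, n_libraries = 60))
    cache
  }
})
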