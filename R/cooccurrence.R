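# Virus / food-source co-occurrence statistics across sequencing libraries,
# and the tripartite virus-mosquito-host association tables.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: from `N` libraries of
#' which `K` contain the food family, `n` are drawn (contain the virus) and
#' `X` counts the overlap. Computed in log space via [stats::phyper()] for
#' numerical stability.
#'
#' @param k observed libraries containing both (`0 <= k <= min(K, n)`).
#' @param K libraries containing the food family.
#' @param n libraries containing the virus.
#' @param N libraries tested.
#' @return the upper-tail p-value.
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stopf("inconsistent hypergeometric counts (k=%s K=%s n=%s N=%s)",
          k, K, n, N)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric co-occurrence tests for all virus-family pairs
#'
#' One upper-tail (over-representation) test per (virus, food family) pair
#' that co-occurs in at least one library. Pairs with `k = 0` are not
#' tested (their p-value is 1 by construction); the number of excluded
#' pairs is recorded in the result attributes. Benjamini-Hochberg adjusted
#' p-values are reported alongside; following the raw-threshold practice
#' this package emulates, `significant` is `raw p < alpha` by default.
#'
#' @param virus_presence logical OTU x library matrix.
#' @param food_presence logical family x library matrix sharing the same
#'   library axis (any column order).
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @param use_adjusted set `TRUE` to apply `alpha` to the BH-adjusted
#'   p-value instead.
#' @return data.frame of class `cooccurrence_result` with columns `virus`,
#'   `food_family`, `N`, `K`, `n`, `k`, `p_value`, `p_adjusted`,
#'   `significant`, sorted by p-value.
#' @export
test_all_pairs <- function(virus_presence, food_presence, alpha = 0.01,
                           use_adjusted = FALSE) {
  libs <- colnames(virus_presence)
  if (is.null(libs) || is.null(colnames(food_presence)) ||
      !setequal(libs, colnames(food_presence)) ||
      ncol(virus_presence) != ncol(food_presence))
    stopf("virus and food presence matrices must share the library axis")
  food_presence <- food_presence[, libs, drop = FALSE]
  N <- length(libs)
  rows <- list()
  for (v in rownames(virus_presence)) {
    vp <- virus_presence[v, ]
    n <- sum(vp)
    for (f in rownames(food_presence)) {
      fp <- food_presence[f, ]
      k <- sum(vp & fp)
      if (k == 0) next
      K <- sum(fp)
      rows[[length(rows) + 1L]] <- data.frame(
        virus = v, food_family = f, N = N, K = K, n = n, k = k,
        p_value = hypergeometric_upper_tail(k, K, n, N),
        stringsAsFactors = FALSE)
    }
  }
  n_skipped <- nrow(virus_presence) * nrow(food_presence) - length(rows)
  if (!length(rows)) {
    out <- data.frame(virus = character(), food_family = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- (if (use_adjusted) out$p_adjusted else out$p_value) <
      alpha
    out <- out[order(out$p_value, out$virus, out$food_family), ]
    rownames(out) <- NULL
  }
  attr(out, "alpha") <- alpha
  attr(out, "criterion") <- if (use_adjusted) "BH-adjusted" else "raw"
  attr(out, "n_untested_zero_overlap") <- n_skipped
  class(out) <- c("cooccurrence_result", class(out))
  out
}

#' Tripartite virus-mosquito-host association table
#'
#' Combines (virus, mosquito species) detections from this dataset with
#' external (virus, host) records -- e.g. host-virus records curated from
#' public databases -- into an edge list with node classes, and classifies
#' each virus by the host classes it reaches. Viruses with no external
#' record are mosquito-exclusive.
#'
#' @param virus_mosquito data.frame with columns `virus`, `mosquito_species`.
#' @param host_records data.frame with columns `virus`, `host`,
#'   `host_class` (`"animal"` or `"plant"`), or `NULL` for none.
#' @return list with `edges` (data.frame `source`, `target`,
#'   `target_class`), `virus_classes` (named character:
#'   `"mosquito-only"`, `"mosquito+animal"`, `"mosquito+plant"`,
#'   `"mosquito+animal+plant"`), and `venn_counts` (table over those
#'   classes).
#' @export
build_tripartite_table <- function(virus_mosquito, host_records = NULL) {
  req <- c("virus", "mosquito_species")
  missing <- setdiff(req, names(virus_mosquito))
  if (length(missing)) stopf("virus_mosquito: missing column '%s'",
                             missing[1])
  edges <- data.frame(source = virus_mosquito$virus,
                      target = virus_mosquito$mosquito_species,
                      target_class = "mosquito", stringsAsFactors = FALSE)
  if (!is.null(host_records) && nrow(host_records)) {
    bad <- setdiff(unique(host_records$host_class), c("animal", "plant"))
    if (length(bad)) stopf("unknown host_class '%s'", bad[1])
    edges <- rbind(edges, data.frame(
      source = host_records$virus, target = host_records$host,
      target_class = paste0(host_records$host_class, "-host"),
      stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  viruses <- sort(unique(virus_mosquito$virus))
  classes <- vapply(viruses, function(v) {
    cls <- edges$target_class[edges$source == v]
    has_a <- "animal-host" %in% cls
    has_p <- "plant-host" %in% cls
    if (has_a && has_p) "mosquito+animal+plant"
    else if (has_a) "mosquito+animal"
    else if (has_p) "mosquito+plant"
    else "mosquito-only"
  }, character(1))
  lv <- c("mosquito-only", "mosquito+animal", "mosquito+plant",
          "mosquito+animal+plant")
  list(edges = edges, virus_classes = classes,
       venn_counts = table(factor(classes, levels = lv)))
}
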