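# OTU-level presence/abundance, Shannon diversity, binomial downsampling,
# composition ordination/clustering, sharing summaries and the rank-based
# group comparisons.

#' Expressed-virus call from reference coverage
#'
#' An OTU counts as expressed in a library only when mapped reads cover
#' strictly more than half of its reference.
#'
#' @param ref_coverage fraction of the OTU reference covered by at least
#'   one read, in `[0, 1]` (vectorised).
#' @param min_coverage threshold, exclusive. Default 0.50.
#' @return logical vector.
#' @export
call_expressed <- function(ref_coverage, min_coverage = 0.50) {
  if (any(ref_coverage < 0 | ref_coverage > 1, na.rm = TRUE))
    stopf("ref_coverage outside [0,1]")
  ref_coverage > min_coverage
}

#' Reads-per-million normalisation
#'
#' `rpm = mapped_reads / n_nonrrna_reads * 1e6`, with the total non-rRNA
#' read count of the library as denominator.
#'
#' @param mapped_reads mapped viral read count (vectorised).
#' @param n_nonrrna_reads library denominator; must be positive.
#' @param library_id optional id used in the zero-denominator error.
#' @return RPM values.
#' @export
compute_rpm <- function(mapped_reads, n_nonrrna_reads, library_id = NULL) {
  bad <- which(n_nonrrna_reads <= 0)
  if (length(bad)) {
    id <- if (!is.null(library_id)) rep_len(library_id,
      max(length(mapped_reads), length(n_nonrrna_reads)))[bad[1]] else "?"
    stopf("library %s has non-positive non-rRNA read total", id)
  }
  mapped_reads / n_nonrrna_reads * 1e6
}

#' Build an OTU x library abundance matrix
#'
#' Combines mapping summaries with library metadata into RPM and
#' expressed-presence matrices. Cells without a mapping record are absent
#' (RPM 0). RPM is set to 0 wherever the expressed call is `FALSE`, so the
#' matrix invariant `rpm == 0` whenever `present == FALSE` always holds.
#'
#' @param mapping mapping-summary data.frame (`otu_id`, `library_id`,
#'   `mapped_reads`, `ref_coverage`).
#' @param libraries library metadata data.frame (see
#'   [read_library_metadata()]).
#' @return an object of class `abundance_matrix`: list with `rpm` and
#'   `present` matrices (OTU rows, library columns), `otus`, `libraries`.
#' @export
build_abundance_matrix <- function(mapping, libraries) {
  unknown <- setdiff(mapping$library_id, libraries$library_id)
  if (length(unknown)) stopf("mapping refers to unknown library %s",
                             unknown[1])
  otus <- sort(unique(mapping$otu_id))
  libs <- libraries$library_id
  denom <- stats::setNames(libraries$n_nonrrna_reads, libs)
  used <- unique(mapping$library_id[mapping$mapped_reads > 0])
  if (any(denom[used] <= 0))
    stopf("library %s has non-positive non-rRNA read total",
          used[denom[used] <= 0][1])

  rpm <- matrix(0, length(otus), length(libs), dimnames = list(otus, libs))
  present <- matrix(FALSE, length(otus), length(libs),
                    dimnames = list(otus, libs))
  expressed <- call_expressed(mapping$ref_coverage) & mapping$mapped_reads > 0
  idx <- cbind(match(mapping$otu_id, otus), match(mapping$library_id, libs))
  present[idx] <- expressed
  vals <- ifelse(expressed,
                 compute_rpm(mapping$mapped_reads,
                             denom[mapping$library_id],
                             mapping$library_id), 0)
  rpm[idx] <- vals
  structure(list(rpm = rpm, present = present, otus = otus, libraries = libs),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d OTUs x %d libraries, %d expressed cells\n",
              length(x$otus), length(x$libraries), sum(x$present)))
  invisible(x)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over the proportional abundances of the
#' positive entries (natural log; zero entries contribute nothing).
#'
#' @param abundances non-negative abundance vector with at least one
#'   positive entry.
#' @return the Shannon index, in `[0, ln(S)]` where `S` is the number of
#'   positive entries.
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stopf("negative abundance")
  x <- abundances[abundances > 0]
  if (!length(x)) stopf("Shannon index undefined for an all-zero vector")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Per-library richness, abundance and diversity
#'
#' @param am an [build_abundance_matrix()] result.
#' @return data.frame with `library_id`, `richness` (expressed OTU count),
#'   `abundance` (summed RPM) and `shannon` (0 when richness <= 1).
#' @export
diversity_table <- function(am) {
  richness <- colSums(am$present)
  abundance <- colSums(am$rpm)
  shannon <- vapply(seq_along(am$libraries), function(j) {
    if (richness[j] <= 1) return(0)
    shannon_index(am$rpm[, j])
  }, numeric(1))
  data.frame(library_id = am$libraries, richness = as.integer(richness),
             abundance = unname(abundance), shannon = shannon,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binomial downsampling of a virome dataset
#'
#' Emulates reduced sequencing effort: each mapped-read count is binomially
#' thinned at the given rate, library denominators are scaled by the same
#' rate, and expressed calls and RPM are recomputed per replicate. Rate 1
#' returns the input matrix unchanged. An alternative mode that subsamples
#' whole libraries is provided by [subsample_libraries()].
#'
#' @param mapping mapping-summary data.frame.
#' @param libraries library metadata data.frame.
#' @param rate sampling rate in `(0, 1]` (the study design uses 0.25, 0.50
#'   and 1.00).
#' @param seed integer seed; fixed seed gives bit-identical replicates.
#' @param replicates number of replicate matrices.
#' @return list of `abundance_matrix` objects of length `replicates`.
#' @export
downsample_dataset <- function(mapping, libraries, rate, seed,
                               replicates = 1) {
  if (rate <= 0 || rate > 1) stopf("rate must be in (0, 1]")
  if (rate == 1)
    return(replicate(replicates, build_abundance_matrix(mapping, libraries),
                     simplify = FALSE))
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    m <- mapping
    m$mapped_reads <- stats::rbinom(nrow(m), size = m$mapped_reads,
                                    prob = rate)
    libs <- libraries
    libs$n_nonrrna_reads <- pmax(1, round(libs$n_nonrrna_reads * rate))
    build_abundance_matrix(m, libs)
  })
}

#' Subsample whole libraries
#'
#' Second downsampling mode: draw `n` libraries without replacement,
#' `replicates` times.
#'
#' @param libraries library metadata data.frame.
#' @param n libraries per replicate.
#' @param seed integer seed.
#' @param replicates number of draws.
#' @return list of library data.frames.
#' @export
subsample_libraries <- function(libraries, n, seed, replicates = 1) {
  if (n > nrow(libraries)) stopf("cannot draw %d of %d libraries", n,
                                 nrow(libraries))
  set.seed(seed)
  lapply(seq_len(replicates), function(r)
    libraries[sort(sample.int(nrow(libraries), n)), , drop = FALSE])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most 10 values and the
#' pooled values are tie-free; normal approximation with tie correction
#' otherwise. The method used is recorded in the result.
#'
#' @param x,y numeric vectors of at least 3 values each.
#' @return list with `p_value`, `statistic` (the rank-sum statistic W of
#'   `x`) and `method` (`"exact"` or `"normal-approximation"`).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stopf("rank-sum test needs at least 3 values per sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = !exact))
  list(p_value = unname(res$p.value), statistic = unname(res$statistic),
       method = if (exact) "exact" else "normal-approximation")
}

#' Kruskal-Wallis rank test across multiple groups
#'
#' H statistic with tie correction against a chi-square reference with
#' `k - 1` degrees of freedom. When every pooled value is identical the
#' statistic is defined as 0 with p-value 1.
#'
#' @param groups list of at least 3 numeric vectors with at least 3 values
#'   each.
#' @return list with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3 || any(lengths(groups) < 3))
    stopf("Kruskal-Wallis needs >=3 groups of >=3 values")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  res <- stats::kruskal.test(groups)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Classical multidimensional scaling of virome composition
#'
#' Libraries are embedded in two dimensions by classical metric MDS
#' (eigendecomposition of the double-centred squared-distance matrix) on
#' Euclidean distances of the transformed RPM matrix. The sign of each
#' axis is fixed by making its first nonzero coordinate positive.
#'
#' @param am an `abundance_matrix`.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return data.frame `library_id`, `MDS1`, `MDS2`; the eigenvalues are in
#'   `attr(, "eig")` and the transform in `attr(, "transform")`.
#' @export
composition_ordination <- function(am, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  if (length(am$libraries) < 3) stopf("ordination needs >=3 libraries")
  x <- t(am$rpm)
  if (transform == "log1p") x <- log1p(x)
  d <- stats::dist(x)
  if (all(d < 1e-12)) {
    warnf("all libraries identical; ordination is degenerate")
    out <- data.frame(library_id = am$libraries, MDS1 = 0, MDS2 = 0,
                      stringsAsFactors = FALSE)
    attr(out, "eig") <- rep(0, length(am$libraries))
    attr(out, "transform") <- transform
    return(out)
  }
  mds <- stats::cmdscale(d, k = 2, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < 2) pts <- cbind(pts, 0)
  for (j in 1:2) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  out <- data.frame(library_id = am$libraries, MDS1 = pts[, 1],
                    MDS2 = pts[, 2], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "eig") <- mds$eig
  attr(out, "transform") <- transform
  out
}

#' K-means clustering of virus abundance profiles
#'
#' OTU rows are normalised to proportions across libraries and clustered
#' with Lloyd's algorithm on Euclidean distances, keeping the best of
#' `n_init` seeded restarts by within-cluster sum of squares.
#'
#' @param am an `abundance_matrix`.
#' @param k number of clusters (>= 2, <= number of OTUs). The study design
#'   this package targets used k = 5.
#' @param seed integer seed; results are deterministic under a fixed seed.
#' @param n_init number of random restarts.
#' @return named integer vector of cluster labels per OTU; the fitted
#'   `kmeans` object is in `attr(, "fit")`.
#' @export
cluster_virus_profiles <- function(am, k = 5, seed = 1, n_init = 25) {
  if (k < 2) stopf("k must be >= 2")
  if (k > length(am$otus)) stopf("k = %d exceeds %d OTUs", k,
                                 length(am$otus))
  prof <- am$rpm
  rs <- rowSums(prof)
  if (any(rs == 0))
    stopf("OTU %s has zero abundance everywhere; drop it before clustering",
          am$otus[which(rs == 0)[1]])
  prof <- prof / rs
  set.seed(seed)
  fit <- stats::kmeans(prof, centers = k, nstart = n_init,
                       algorithm = "Lloyd", iter.max = 100)
  structure(stats::setNames(fit$cluster, am$otus), fit = fit)
}

#' Virus sharing across groups
#'
#' For each OTU, records the set of groups containing it, and summarises
#' how exclusive the groups' viromes are: total distinct OTUs, the count
#' found in exactly one group (species-/region-specific), pairwise and
#' k-way intersection counts, and per-group shared fractions. Percentages
#' are recomputed from their integer numerator and denominator and reported
#' to two decimals (half-up).
#'
#' @param per_group_sets named list (>= 2 entries) of character vectors of
#'   OTU ids.
#' @return list of class `virus_sharing`: `membership` (data.frame `otu`,
#'   `groups`, `n_groups`), `total`, `exclusive`, `pct_exclusive`,
#'   `per_group` (data.frame with `n`, `n_exclusive`, `n_shared`,
#'   `pct_shared`), `pairwise` intersection matrix, `degree_counts` (OTUs
#'   in exactly j groups).
#' @export
virus_sharing <- function(per_group_sets) {
  if (length(per_group_sets) < 2) stopf("need at least 2 groups")
  if (is.null(names(per_group_sets)) || any(!nzchar(names(per_group_sets))))
    stopf("groups must be named")
  groups <- names(per_group_sets)
  all_otus <- sort(unique(unlist(per_group_sets)))
  member <- vapply(per_group_sets, function(s) all_otus %in% s,
                   logical(length(all_otus)))
  if (length(all_otus) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(all_otus,
                                                              groups))
  n_groups <- rowSums(member)
  total <- length(all_otus)
  exclusive <- sum(n_groups == 1)
  per_group <- data.frame(
    group = groups,
    n = colSums(member),
    n_exclusive = vapply(seq_along(groups), function(j)
      sum(member[, j] & n_groups == 1), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  per_group$n_shared <- per_group$n - per_group$n_exclusive
  per_group$pct_shared <- round_half_up(
    ifelse(per_group$n > 0, 100 * per_group$n_shared / per_group$n, 0), 2)
  pairwise <- crossprod(member)
  degree_counts <- table(factor(n_groups, levels = seq_along(groups)))
  structure(list(
    membership = data.frame(
      otu = all_otus,
      groups = apply(member, 1, function(r) paste(groups[r], collapse = ";")),
      n_groups = as.integer(n_groups),
      row.names = NULL, stringsAsFactors = FALSE),
    total = total, exclusive = exclusive,
    pct_exclusive = round_half_up(100 * exclusive / total, 2),
    per_group = per_group, pairwise = pairwise,
    degree_counts = degree_counts), class = "virus_sharing")
}

#' @export
print.virus_sharing <- function(x, ...) {
  cat(sprintf("virus_sharing: %d OTUs over %d groups; %d (%.2f%%) exclusive\n",
              x$total, nrow(x$per_group), x$exclusive, x$pct_exclusive))
  invisible(x)
}

#' Classify transmission mode from year persistence
#'
#' Within one mosquito species, a virus detected in every required sampling
#' year is a vertical-transmission candidate; a mosaic, non-persistent
#' presence is labelled environment-derived. Labels are hypotheses, not
#' proofs, and feed the cross-region sharing contrasts.
#'
#' @param presence_by_year logical OTU x year matrix (colnames = years) for
#'   a single species.
#' @param years_required years that must all be positive; defaults to every
#'   column.
#' @return named character vector, `"vertical-candidate"` or
#'   `"environment-derived"`.
#' @export
classify_transmission <- function(presence_by_year,
                                  years_required = colnames(presence_by_year)) {
  missing <- setdiff(years_required, colnames(presence_by_year))
  if (length(missing)) stopf("year %s not in presence matrix", missing[1])
  sub <- presence_by_year[, years_required, drop = FALSE]
  stats::setNames(ifelse(rowSums(sub) == length(years_required),
                         "vertical-candidate", "environment-derived"),
                  rownames(presence_by_year))
}
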