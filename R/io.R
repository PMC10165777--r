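# Readers and writers for the tabular formats the pipeline consumes:
# 12-column tabular alignment hits (with optional qlen/slen/staxid extras),
# library metadata, and per-OTU read-mapping summaries.

# Standard 12-column tabular alignment output, in canonical order.
BLAST12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT_EXTRAS <- c("qlen", "slen", "staxid")

.hit_numeric_cols <- c("pident", "length", "mismatch", "gapopen", "qstart",
                       "qend", "sstart", "send", "evalue", "bitscore",
                       "qlen", "slen", "staxid")

#' Read a tabular alignment-hit file
#'
#' Parses the standard 12-column tabular alignment dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally extended with `qlen`, `slen` and `staxid`
#' columns. The column order can be declared in the file itself with a
#' leading `"# columns: ..."` comment line, or passed via `columns`.
#'
#' Query and subject coverages are always recomputed as
#' `length / qlen` and `length / slen`; coverage columns present in the
#' input are never trusted. Gapped alignments can make the aligned length
#' exceed a sequence length, in which case the coverage is clamped to 1.
#'
#' @param path path to a tab-separated hit file. Lines starting with `#`
#'   are treated as comments.
#' @param search_type `"protein"` or `"nucleotide"`; recorded on the result
#'   so that amino-acid and nucleotide identity thresholds are never mixed.
#' @param columns optional character vector giving the column order; must
#'   contain all of the 12 standard names, plus any of `qlen`, `slen`,
#'   `staxid`.
#' @return a data.frame of hits with canonical columns `query_id`,
#'   `subject_id`, `pct_identity`, `aligned_length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`,
#'   `query_length`, `subject_length`, `subject_taxon_id`,
#'   `query_coverage`, `subject_coverage`, `search_type`. An empty file
#'   yields a zero-row data.frame with a warning.
#' @export
read_hit_table <- function(path, search_type = c("protein", "nucleotide"),
                           columns = NULL) {
  search_type <- match.arg(search_type)
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  lines <- readLines(path)
  decl <- grep("^#\\s*columns\\s*:", lines, value = TRUE)
  if (is.null(columns) && length(decl)) {
    columns <- strsplit(sub("^#\\s*columns\\s*:\\s*", "", decl[1]),
                        "[ \t,]+")[[1]]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    warnf("hit table %s is empty", path)
    return(hit_frame(NULL, search_type))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stopf("ragged hit table %s: rows have %s columns", path,
          paste(unique(ncols), collapse = "/"))
  nc <- ncols[1]
  if (is.null(columns)) {
    columns <- switch(as.character(nc),
      "12" = BLAST12,
      "15" = c(BLAST12, HIT_EXTRAS),
      stopf(paste0("hit table %s has %d columns; declare their order with a ",
                   "'# columns:' header or the `columns` argument"), path, nc))
  }
  if (length(columns) != nc)
    stopf("hit table %s: %d columns found but %d declared", path, nc,
          length(columns))
  missing_std <- setdiff(BLAST12, columns)
  if (length(missing_std))
    stopf("hit table %s: missing required column '%s'", path, missing_std[1])

  raw <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(raw) <- columns
  for (col in intersect(.hit_numeric_cols, columns)) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) &
                   toupper(raw[[col]]) != "NA")
    if (length(bad))
      stopf("hit table %s: cannot parse column '%s' at data row %d ('%s')",
            path, col, bad[1], raw[[col]][bad[1]])
    raw[[col]] <- parsed
  }
  hit_frame(raw, search_type)
}

# Normalise a raw parsed table (or NULL) into the canonical hit data.frame.
hit_frame <- function(raw, search_type) {
  if (is.null(raw) || !nrow(raw)) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aligned_length = numeric(),
                      mismatch = numeric(), gapopen = numeric(),
                      qstart = numeric(), qend = numeric(),
                      sstart = numeric(), send = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      query_length = numeric(), subject_length = numeric(),
                      subject_taxon_id = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      search_type = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    query_id = raw$qseqid, subject_id = raw$sseqid,
    pct_identity = raw$pident, aligned_length = raw$length,
    mismatch = raw$mismatch, gapopen = raw$gapopen,
    qstart = raw$qstart, qend = raw$qend,
    sstart = raw$sstart, send = raw$send,
    evalue = raw$evalue, bitscore = raw$bitscore,
    query_length = if ("qlen" %in% names(raw)) raw$qlen else NA_real_,
    subject_length = if ("slen" %in% names(raw)) raw$slen else NA_real_,
    subject_taxon_id = if ("staxid" %in% names(raw)) raw$staxid else NA_real_,
    stringsAsFactors = FALSE)
  bad <- which(out$pct_identity < 0 | out$pct_identity > 100)
  if (length(bad))
    stopf("hit row %d: pct_identity %.3f outside [0,100]", bad[1],
          out$pct_identity[bad[1]])
  bad <- which(out$evalue < 0 | out$bitscore < 0 | out$aligned_length <= 0)
  if (length(bad))
    stopf("hit row %d: negative e-value/bitscore or non-positive length",
          bad[1])
  out$query_coverage <- pmin(1, out$aligned_length / out$query_length)
  out$subject_coverage <- pmin(1, out$aligned_length / out$subject_length)
  out$search_type <- search_type
  out
}

#' Write a hit table
#'
#' Emits the canonical 15-column layout with a `# columns:` declaration so
#' that [read_hit_table()] round-trips the records exactly.
#'
#' @param hits a hit data.frame as returned by [read_hit_table()].
#' @param path output path.
#' @param params optional named list recorded in the `#` comment block.
#' @return the path, invisibly.
#' @export
write_hit_table <- function(hits, path, params = NULL) {
  cols <- c(BLAST12, HIT_EXTRAS)
  raw <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$pct_identity, length = hits$aligned_length,
    mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = hits$evalue, bitscore = hits$bitscore,
    qlen = hits$query_length, slen = hits$subject_length,
    staxid = hits$subject_taxon_id, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(params), con)
  writeLines(paste0("# columns: ", paste(cols, collapse = " ")), con)
  utils::write.table(format(raw, digits = 15, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-library metadata
#'
#' @param path TSV with header columns `library_id`, `species`, `location`,
#'   `year`, `n_nonrrna_reads`. Lines starting with `#` are skipped.
#' @param year_range libraries with years outside this range trigger a
#'   warning (not an error; the tool is reusable beyond the 2018-2020
#'   sampling design).
#' @return data.frame of libraries with an added logical `usable_for_rpm`
#'   flag (`FALSE` when `n_nonrrna_reads` is 0, such libraries cannot enter
#'   RPM computation).
#' @export
read_library_metadata <- function(path, year_range = c(2018L, 2020L)) {
  req <- c("library_id", "species", "location", "year", "n_nonrrna_reads")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("library metadata %s: missing column '%s'", path, missing[1])
  dup <- unique(df$library_id[duplicated(df$library_id)])
  if (length(dup))
    stopf("duplicated library_id: %s", paste(dup, collapse = ", "))
  if (any(df$n_nonrrna_reads < 0))
    stopf("negative n_nonrrna_reads for library %s",
          df$library_id[which(df$n_nonrrna_reads < 0)[1]])
  outside <- df$year < year_range[1] | df$year > year_range[2]
  if (any(outside))
    warnf("%d libraries have years outside [%d, %d]", sum(outside),
          year_range[1], year_range[2])
  df$usable_for_rpm <- df$n_nonrrna_reads > 0
  if (any(!df$usable_for_rpm))
    warnf("library %s has 0 non-rRNA reads; flagged unusable for RPM",
          paste(df$library_id[!df$usable_for_rpm], collapse = ", "))
  df[req] <- lapply(df[req], function(x) x)
  df
}

#' @rdname read_library_metadata
#' @param libraries library data.frame.
#' @param params optional named list recorded in the `#` comment block.
#' @export
write_library_metadata <- function(libraries, path, params = NULL) {
  cols <- c("library_id", "species", "location", "year", "n_nonrrna_reads")
  write_commented_tsv(libraries[cols], path, params)
}

#' Read per-OTU read-mapping summaries
#'
#' Mapping summaries arrive pre-aggregated (one row per OTU x library) with
#' the number of mapped reads and the fraction of the OTU reference covered
#' by at least one read.
#'
#' @param path TSV with header columns `otu_id`, `library_id`,
#'   `mapped_reads`, `ref_coverage`.
#' @return validated data.frame.
#' @export
read_mapping_summary <- function(path) {
  req <- c("otu_id", "library_id", "mapped_reads", "ref_coverage")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("mapping summary %s: missing column '%s'", path, missing[1])
  if (any(df$mapped_reads < 0)) stopf("negative mapped_reads")
  if (any(df$ref_coverage < 0 | df$ref_coverage > 1))
    stopf("ref_coverage outside [0,1] at row %d",
          which(df$ref_coverage < 0 | df$ref_coverage > 1)[1])
  df
}

#' @rdname read_mapping_summary
#' @param mapping mapping-summary data.frame.
#' @param params optional named list recorded in the `#` comment block.
#' @export
write_mapping_summary <- function(mapping, path, params = NULL) {
  cols <- c("otu_id", "library_id", "mapped_reads", "ref_coverage")
  write_commented_tsv(mapping[cols], path, params)
}
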