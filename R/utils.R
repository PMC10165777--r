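#' Round half away from zero
#'
#' Percentage summaries in this package are reported to a fixed number of
#' decimals with ties rounded up (so 85.185 -> 85.19), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Comment block prefixed to every table this package writes: tool version and
# the parameters the caller wants recorded.
output_header <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("viromeflow"))
  lines <- sprintf("# viromeflow %s", ver)
  if (length(params)) {
    kv <- vapply(seq_along(params), function(i) {
      sprintf("# %s = %s", names(params)[i],
              paste(format(params[[i]]), collapse = ","))
    }, character(1))
    lines <- c(lines, kv)
  }
  lines
}

write_commented_tsv <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
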