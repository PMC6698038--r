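#' @keywords internal
"_PACKAGE"

# Column-standardize a vector; zero-variance input returns zeros.
std_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV with a commented provenance header
#'
#' All pipeline writers go through this function so every output table
#' carries the package version and the parameters that produced it.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list echoed into the `#` header line.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, params = list()) {
  pv <- as.character(utils::packageVersion("tras"))
  ptxt <- if (length(params)) {
    paste(vapply(names(params), function(k)
      paste0(k, "=", paste(format(params[[k]]), collapse = ",")),
      character(1)), collapse = "; ")
  } else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tras %s%s", pv,
                     if (nzchar(ptxt)) paste0(" | ", ptxt) else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_commented (or any plain TSV);
# '#' lines are skipped.
read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

stop_tras <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pearson correlation with two-sided p from the t transform on n - 2 df.
# Degenerate (zero-variance) input is flagged, not an error.
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = 1, n = n, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}
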