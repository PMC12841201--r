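#' Normalize typeset scientific notation to ASCII
#'
#' Published association tables print p-values as, e.g., \code{"3.01 x 10^-2^"}
#' with a typographic multiplication sign and minus.  This pre-pass rewrites
#' such strings to plain \code{"3.01e-2"} so they parse with
#' \code{as.numeric()}.  Already-ASCII numbers pass through unchanged and the
#' transformation is idempotent.
#'
#' @param x character vector of numeric strings.
#' @return character vector of the same length, ASCII-normalized.
#' @examples
#' normalize_scientific("3.01 \u00d7 10^\u22122^")  # "3.01e-2"
#' @export
normalize_scientific <- function(x) {
  x <- gsub("\u2212", "-", x)   # typographic minus (U+2212)
  x <- gsub("\u00d7", "x", x)   # multiplication sign (U+00D7)
  x <- gsub("\\s*[xX]\\s*10\\^?\\s*(-?[0-9]+)\\^?", "e\\1", x)
  trimws(x)
}

#' Round half away from zero
#'
#' Commercial rounding, used when reporting coefficients of variation to
#' three decimals (\code{base::round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3).
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shared field separator lookup for the tabular readers.
dialect_sep <- function(dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") "\t" else ","
}

# Read a delimited file as an all-character data.frame, header required.
read_delim_chr <- function(path, sep) {
  if (!file.exists(path)) {
    format_error(sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) format_error(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e)))
  )
  if (ncol(df) < 1L || any(!nzchar(colnames(df)))) {
    format_error(sprintf("%s: missing or empty header row", path))
  }
  if (anyDuplicated(colnames(df))) {
    format_error(sprintf("%s: duplicated column names in header", path))
  }
  df
}

# Case-insensitive gene lookup: returns the stored gene name matching `gene`,
# or NA if absent.  Gene symbols are matched case-insensitively but stored as
# read, because published tables mix capitalizations (Slc44a1 / slc44a1).
match_gene <- function(gene, genes) {
  hit <- match(tolower(gene), tolower(genes))
  if (is.na(hit)) NA_character_ else genes[hit]
}
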