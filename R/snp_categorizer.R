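# Funnel stage 4 (annotation): classify GWAS SNP-phenotype association rows
# into alcohol / liver / developmental disorder categories with an ordered
# first-match-wins rule set, filter on the association p-value, and count
# rows per category.  Rows, not unique variants, are the counting unit: a
# variant reported against two phenotypes contributes to both categories.

SNP_CATEGORIES <- c("alcohol", "liver", "developmental")

#' Default phenotype-category mapping
#'
#' Ordered rules, applied first-match-wins and case-insensitively:
#' ICD-style prefixes \code{K70} (alcoholic liver disease) and \code{F10}
#' (mental/behavioral disorders due to alcohol) are alcohol-related before
#' any keyword is consulted, then the substring \code{"alcohol"}; liver
#' keywords (\code{liver}, \code{gamma glutamyltransferase}, \code{lipid},
#' \code{cholesterol}, \code{triglyceride}) mark liver disorders; everything
#' else falls through to developmental.  One guard rule precedes the liver
#' keywords: \code{"delivery"} maps to developmental, because the word
#' contains \code{"liver"} as a substring and obstetric-complication labels
#' would otherwise be miscounted as liver disorders.  This is the minimal
#' ordered rule set consistent with all six published per-gene category
#' counts; the packaged copy (\code{extdata/category_rules.tsv}) is an
#' editable plain-text version of the same rules.
#'
#' @return object of class \code{"category_mapping"}: a data.frame of rules
#'   (match_kind, pattern, category) with attribute \code{fallthrough}.
#' @export
default_category_mapping <- function() {
  category_mapping(
    data.frame(
      match_kind = c("prefix", "prefix", "substring", "substring", "substring",
                     "substring", "substring", "substring", "substring"),
      pattern = c("K70", "F10", "alcohol", "delivery", "liver",
                  "gamma glutamyltransferase", "lipid", "cholesterol",
                  "triglyceride"),
      category = c("alcohol", "alcohol", "alcohol", "developmental", "liver",
                   "liver", "liver", "liver", "liver"),
      stringsAsFactors = FALSE),
    fallthrough = "developmental")
}

#' Construct a category mapping
#'
#' @param rules data.frame with columns \code{match_kind} (\code{"prefix"} or
#'   \code{"substring"}), \code{pattern}, \code{category}; rules apply in row
#'   order, first match wins, matching is case-insensitive.
#' @param fallthrough category for unmatched labels, or \code{"NONE"} to make
#'   an unmatched label an error.
#' @return object of class \code{"category_mapping"}.
#' @export
category_mapping <- function(rules, fallthrough = "NONE") {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (!all(rules$match_kind %in% c("prefix", "substring"))) {
    validation_error("match_kind must be 'prefix' or 'substring'")
  }
  if (!all(rules$category %in% SNP_CATEGORIES)) {
    validation_error(sprintf("categories must be one of: %s",
                             paste(SNP_CATEGORIES, collapse = ", ")))
  }
  if (!(fallthrough %in% c(SNP_CATEGORIES, "NONE"))) {
    validation_error("fallthrough must be a category or 'NONE'")
  }
  structure(rules, fallthrough = fallthrough,
            class = c("category_mapping", "data.frame"))
}

#' Read a category mapping from a plain-text ruleset
#'
#' Tab-separated columns \code{order}, \code{match_kind}, \code{pattern},
#' \code{category}; a final row with \code{match_kind = "fallthrough"} names
#' the catch-all category.
#'
#' @param path file path.
#' @return a \code{\link{category_mapping}}.
#' @export
read_category_mapping <- function(path) {
  df <- read_delim_chr(path, "\t")
  needed <- c("order", "match_kind", "pattern", "category")
  if (!all(needed %in% colnames(df))) {
    format_error(sprintf("%s: mapping needs columns %s", path,
                         paste(needed, collapse = ", ")))
  }
  df <- df[order(as.numeric(df$order)), ]
  ft <- df$match_kind == "fallthrough"
  fallthrough <- if (any(ft)) df$category[ft][1L] else "NONE"
  category_mapping(df[!ft, c("match_kind", "pattern", "category")], fallthrough)
}

#' Filter association records on p-value
#'
#' Retains records with \code{p <= p_max}: only associations strictly over
#' the cutoff are excluded, so a p of exactly 0.05 survives the default.
#'
#' @param records a \code{\link{snp_records}} data.frame.
#' @param p_max cutoff in (0, 1), default 0.05.
#' @return the retained records.
#' @export
filter_by_pvalue <- function(records, p_max = 0.05) {
  if (!(p_max > 0 && p_max < 1)) validation_error("p_max must lie in (0, 1)")
  out <- records[records$p_value <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize one phenotype label
#'
#' @param label phenotype text (non-empty).
#' @param mapping a \code{\link{category_mapping}}.
#' @return the category of the first matching rule, or the fallthrough.
#' @export
categorize_phenotype <- function(label, mapping = default_category_mapping()) {
  if (!nzchar(trimws(label))) validation_error("phenotype label is empty")
  low <- tolower(label)
  for (i in seq_len(nrow(mapping))) {
    pat <- tolower(mapping$pattern[i])
    hit <- switch(mapping$match_kind[i],
                  prefix = startsWith(low, pat),
                  substring = grepl(pat, low, fixed = TRUE))
    if (hit) return(mapping$category[i])
  }
  ft <- attr(mapping, "fallthrough")
  if (identical(ft, "NONE")) {
    abort(sprintf("no category rule matches phenotype label '%s'", label),
          "uncategorized_error", label = label)
  }
  ft
}

#' Categorize every record
#'
#' @param records a \code{\link{snp_records}} data.frame.
#' @param mapping a \code{\link{category_mapping}}.
#' @return the records with \code{category} filled in.
#' @export
categorize_records <- function(records, mapping = default_category_mapping()) {
  records$category <- vapply(records$phenotype, categorize_phenotype,
                             character(1), mapping = mapping, USE.NAMES = FALSE)
  records
}

#' Count categorized rows per category
#'
#' @param records categorized \code{\link{snp_records}} (all rows belonging
#'   to one gene).
#' @param gene gene symbol for labelling the result.
#' @return list with \code{gene}, \code{counts} (named integer over the three
#'   categories) and \code{total_rows}.
#' @export
count_categories <- function(records, gene = NA_character_) {
  counts <- vapply(SNP_CATEGORIES,
                   function(k) sum(records$category == k), integer(1))
  list(gene = gene, counts = counts, total_rows = nrow(records))
}
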