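# Funnel stage 1: haplotype variability.  A gene stays in only if its
# parental-origin calls differ somewhere across the strain panel; variation is
# at least two distinct codes among B6/D2/H/R.  NV is a gene-level flag
# meaning "no variation across the panel" and always eliminates the gene.

#' Decide haplotypic variability for one gene
#'
#' @param calls character vector of haplotype codes (one per panel strain).
#' @return list with fields \code{variable} (logical), \code{distinct_calls}
#'   (sorted unique codes) and \code{reason} (text).
#' @export
is_variable <- function(calls) {
  if (length(calls) == 0L) validation_error("no haplotype calls supplied")
  bad <- setdiff(calls, HAPLOTYPE_CODES)
  if (length(bad)) {
    validation_error(sprintf("unknown haplotype code '%s'", bad[1L]))
  }
  if (any(calls == "NV")) {
    if (!all(calls == "NV")) {
      validation_error("NV mixed with per-strain calls: NV is a gene-level flag")
    }
    return(list(variable = FALSE, distinct_calls = "NV",
                reason = "no variation across panel (NV)"))
  }
  distinct <- sort(unique(calls))
  variable <- length(distinct) >= 2L
  list(variable = variable, distinct_calls = distinct,
       reason = if (variable)
         sprintf("variable: calls {%s}", paste(distinct, collapse = ", "))
       else
         sprintf("uniform %s across panel", distinct))
}

#' Filter genes by haplotypic variability across a strain panel
#'
#' Partitions the table's genes into those with at least one haplotypic
#' difference over the panel columns and those without.
#'
#' @param table a \code{\link{haplotype_table}}.
#' @param panel character vector of strain ids to evaluate on (default: all
#'   strains in the table); must have at least 2 strains.
#' @return list with \code{retained} (character vector, input gene order) and
#'   \code{removed} (data.frame gene/reason).
#' @export
filter_by_haplotype <- function(table, panel = colnames(table)) {
  absent <- setdiff(panel, colnames(table))
  if (length(absent)) {
    abort(sprintf("panel strain(s) not in table: %s", paste(absent, collapse = ", ")),
          "key_error", strains = absent)
  }
  if (length(panel) < 2L) {
    validation_error("panel must contain at least 2 strains")
  }
  genes <- rownames(table)
  decisions <- lapply(genes, function(g) is_variable(table[g, panel]))
  keep <- vapply(decisions, `[[`, logical(1), "variable")
  list(
    retained = genes[keep],
    removed = data.frame(gene = genes[!keep],
                         reason = vapply(decisions[!keep], `[[`, character(1), "reason"),
                         stringsAsFactors = FALSE)
  )
}
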