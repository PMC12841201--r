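# Funnel stage 2: liver proteome evidence.  Genes are removed when absent
# from the proteome dataset, when not clearly above the detection background
# (log2 abundance 7), or when showing zero abundance variation across the
# panel (coefficient of variation 0).

#' Coefficient of variation, in percent
#'
#' \code{100 * sd(x) / mean(x)} with the sample (n-1) standard deviation.
#' Full precision is returned; reports round half-away-from-zero to three
#' decimals (see \code{\link{round_half_away}}), which reproduces the
#' published per-gene values from the abundance table.
#'
#' @param values numeric vector of abundances (at least 2 finite values,
#'   nonzero mean).
#' @return CV as a percentage.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    abort("need at least 2 finite values for a coefficient of variation",
          "insufficient_data_error")
  }
  m <- mean(values)
  if (m == 0) abort("mean is zero; CV undefined", "degenerate_mean_error")
  100 * stats::sd(values) / m
}

#' Filter genes by proteome detection above background
#'
#' A gene is retained only if it appears in the proteome table with at least
#' two non-missing panel values and every non-missing panel value is strictly
#' above the background threshold.  Genes with no proteome row are reported
#' \code{NO_DATA}; strains with missing cells are excluded gene-wise rather
#' than failing the gene.
#'
#' @param table a \code{\link{proteome_table}}.
#' @param genes candidate gene symbols (matched case-insensitively).
#' @param panel strain ids to evaluate (default: all table strains).
#' @param threshold log2-abundance background cutoff (default 7; a value of
#'   exactly 7 does not pass).
#' @return list with \code{retained} (genes, input order) and \code{removed}
#'   (data.frame gene/status/reason), plus \code{values} (named list of the
#'   per-strain abundances used for each retained gene).
#' @export
filter_by_background <- function(table, genes = rownames(table),
                                 panel = colnames(table), threshold = 7) {
  if (!is.finite(threshold)) validation_error("background threshold must be finite")
  absent <- setdiff(panel, colnames(table))
  if (length(absent)) {
    abort(sprintf("panel strain(s) not in table: %s", paste(absent, collapse = ", ")),
          "key_error", strains = absent)
  }
  retained <- character(0)
  removed <- list()
  values <- list()
  for (g in genes) {
    row <- match_gene(g, rownames(table))
    if (is.na(row)) {
      removed[[g]] <- data.frame(gene = g, status = "NO_DATA",
                                 reason = "gene absent from proteome dataset",
                                 stringsAsFactors = FALSE)
      next
    }
    v <- unclass(table)[row, panel]
    v <- v[is.finite(v)]
    if (length(v) < 2L) {
      removed[[g]] <- data.frame(gene = g, status = "NO_DATA",
                                 reason = "fewer than 2 non-missing panel values",
                                 stringsAsFactors = FALSE)
    } else if (all(v > threshold)) {
      retained <- c(retained, g)
      values[[g]] <- v
    } else {
      removed[[g]] <- data.frame(gene = g, status = "BELOW_BACKGROUND",
                                 reason = sprintf("abundance not above background %g", threshold),
                                 stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(removed)) do.call(rbind, c(removed, make.row.names = FALSE)) else
    data.frame(gene = character(0), status = character(0), reason = character(0))
  list(retained = retained, removed = removed, values = values)
}

#' Filter genes by nonzero across-strain variation
#'
#' Retains genes whose abundance CV exceeds \code{tolerance}.  The default
#' tolerance is an exact-zero test with a small numerical guard: a flat
#' profile (identical abundances in every strain) is removed, anything else
#' is kept.
#'
#' @param values named list of per-strain abundance vectors (as produced by
#'   \code{\link{filter_by_background}}).
#' @param tolerance minimum CV percent (default \code{1e-9}).
#' @return list with \code{retained}, \code{removed} (data.frame
#'   gene/status/reason) and \code{cv} (named numeric, full precision, all
#'   genes).
#' @export
filter_by_cv <- function(values, tolerance = 1e-9) {
  cv <- vapply(values, coefficient_of_variation, numeric(1))
  keep <- cv > tolerance
  rem <- as.character(names(values)[!keep])
  list(
    retained = as.character(names(values)[keep]),
    removed = data.frame(
      gene = rem, status = rep("ZERO_CV", length(rem)),
      reason = sprintf("coefficient of variation %.3f not above %g",
                       round_half_away(cv[!keep]), tolerance),
      stringsAsFactors = FALSE),
    cv = cv
  )
}
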