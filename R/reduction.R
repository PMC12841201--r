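# The study phenotype: percent reduction in ethanol-induced cell death,
# computed per strain, brain region and choline dose from litter-level
# TUNEL cell-death means.  With CE = mean of the choline+ethanol group,
# E0 = mean of the ethanol/no-choline group and MD = pooled maltose-dextrin
# control mean, the ratio is rho = (CE - MD) / (E0 - MD).  The REMAINING
# convention reports 100*rho (the literal printed formula: the fraction of
# ethanol-induced death still present); REDUCTION reports 100*(1 - rho).

#' Aggregate litter means to strain-condition means
#'
#' The litter is the unit of analysis: litter means are averaged within each
#' distinct (strain, region, treatment, dose) group.
#'
#' @param obs a \code{\link{celldeath_obs}} data.frame.
#' @return data.frame with columns strain, region, treatment, choline_dose,
#'   mean_cell_death, n_litters.
#' @export
litter_to_strain_means <- function(obs) {
  obs <- as.data.frame(obs)
  if (nrow(obs) == 0L) validation_error("no observations to aggregate")
  agg <- stats::aggregate(litter_mean ~ strain + region + treatment + choline_dose,
                          data = obs, FUN = mean)
  n <- stats::aggregate(litter_mean ~ strain + region + treatment + choline_dose,
                        data = obs, FUN = length)
  out <- agg
  names(out)[names(out) == "litter_mean"] <- "mean_cell_death"
  out$n_litters <- n$litter_mean
  out <- out[order(out$strain, out$region, out$treatment, out$choline_dose), ]
  rownames(out) <- NULL
  out
}

#' Pool maltose-dextrin control groups
#'
#' The caloric-control (MD) groups at all choline doses are combined into one
#' control mean per strain and region, weighted by litter count (the litter is
#' the unit of analysis, so pooling is over litters, not over group means).
#'
#' @param means output of \code{\link{litter_to_strain_means}}.
#' @param strain,region the cell to pool for.
#' @return the pooled MD mean (scalar).
#' @export
pool_controls <- function(means, strain, region) {
  md <- means[means$strain == strain & means$region == region &
                means$treatment == "MD", , drop = FALSE]
  if (nrow(md) == 0L) {
    abort(sprintf("no maltose-dextrin control data for %s/%s", strain, region),
          "missing_group_error", strain = strain, region = region)
  }
  sum(md$mean_cell_death * md$n_litters) / sum(md$n_litters)
}

#' Percent reduction in ethanol-induced cell death
#'
#' @param CE mean cell death of the choline + ethanol group.
#' @param E0 mean cell death of the ethanol, no-choline group.
#' @param MD pooled maltose-dextrin control mean.
#' @param convention \code{"REMAINING"} returns \code{100 * rho} with
#'   \code{rho = (CE - MD) / (E0 - MD)} (the formula exactly as printed);
#'   \code{"REDUCTION"} returns \code{100 * (1 - rho)}.  The two always sum
#'   to 100.  Values are not clamped: rescue beyond control gives a negative
#'   REMAINING, enhancement beyond ethanol-alone gives REMAINING above 100.
#' @return percent (dimensionless, x100 scale).
#' @export
percent_reduction <- function(CE, E0, MD, convention = c("REMAINING", "REDUCTION")) {
  convention <- match.arg(convention)
  if (isTRUE(all.equal(E0, MD, tolerance = 0))) {
    abort("E0 equals MD: no ethanol-induced cell death to reduce",
          "degenerate_denominator_error")
  }
  rho <- (CE - MD) / (E0 - MD)
  remaining <- 100 * rho
  if (convention == "REMAINING") remaining else 100 - remaining
}

#' Build the strain x condition reduction matrix
#'
#' For every strain and region with a complete design (an ethanol group at the
#' choline dose, an ethanol/no-choline group, and at least one MD control
#' group), computes the percent-reduction statistic at choline doses 100 and
#' 250 mg/kg.  Strains lacking a required group get \code{NA} in the affected
#' cells, with the reason recorded in \code{attr(, "dropped")}.
#'
#' @param obs a \code{\link{celldeath_obs}} data.frame.
#' @param convention see \code{\link{percent_reduction}}.
#' @return numeric matrix (strains x \code{<region>_<dose>} columns) of class
#'   \code{"reduction_matrix"}, with attributes \code{convention} and
#'   \code{dropped} (data.frame of strain/region/reason).
#' @export
build_reduction_matrix <- function(obs, convention = c("REMAINING", "REDUCTION")) {
  convention <- match.arg(convention)
  means <- litter_to_strain_means(obs)
  strains <- sort(unique(means$strain))
  regions <- c("forebrain", "brainstem")
  doses <- c(100, 250)
  cols <- as.vector(outer(regions, doses, paste, sep = "_"))
  m <- matrix(NA_real_, nrow = length(strains), ncol = length(cols),
              dimnames = list(strains, cols))
  dropped <- list()
  note <- function(strain, region, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(
      strain = strain, region = region, reason = reason, stringsAsFactors = FALSE)
  }
  for (s in strains) {
    for (rg in regions) {
      md <- tryCatch(pool_controls(means, s, rg), missing_group_error = function(e) NULL)
      if (is.null(md)) { note(s, rg, "no MD control group"); next }
      e0row <- means[means$strain == s & means$region == rg &
                       means$treatment == "ETOH" & means$choline_dose == 0, , drop = FALSE]
      if (nrow(e0row) == 0L) { note(s, rg, "no ethanol/no-choline group"); next }
      E0 <- e0row$mean_cell_death
      for (d in doses) {
        cerow <- means[means$strain == s & means$region == rg &
                         means$treatment == "ETOH" & means$choline_dose == d, , drop = FALSE]
        if (nrow(cerow) == 0L) {
          note(s, rg, sprintf("no ethanol group at choline dose %g", d))
          next
        }
        val <- tryCatch(
          percent_reduction(cerow$mean_cell_death, E0, md, convention),
          degenerate_denominator_error = function(e) {
            abort(sprintf("E0 equals MD for %s/%s: no ethanol-induced cell death",
                          s, rg),
                  "degenerate_denominator_error", strain = s, region = rg)
          })
        m[s, paste(rg, d, sep = "_")] <- val
      }
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(strain = character(0), region = character(0), reason = character(0))
  structure(m, convention = convention, dropped = dropped,
            class = c("reduction_matrix", class(m)))
}

#' Write a reduction matrix as TSV (strains as rows)
#' @param m a \code{"reduction_matrix"}.
#' @param path output file path.
#' @export
write_reduction_matrix <- function(m, path) {
  header <- paste(c("strain", colnames(m)), collapse = "\t")
  body <- paste(rownames(m),
                apply(format(unclass(m), trim = TRUE), 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(sprintf("# convention: %s", attr(m, "convention")), header, body),
             path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.reduction_matrix <- function(x, ...) {
  cat(sprintf("Percent %s in ethanol-induced cell death (%d strains):\n",
              tolower(attr(x, "convention")), nrow(x)))
  print(unclass(x)[, , drop = FALSE])
  dr <- attr(x, "dropped")
  if (nrow(dr)) cat(sprintf("%d strain/region cells dropped (see attr 'dropped')\n", nrow(dr)))
  invisible(x)
}
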