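# Funnel stage 3: strain-level Pearson correlation between liver protein
# abundance and the percent-reduction phenotype, one coefficient per gene x
# brain region x choline dose, with a "strong in at least 3 of the 4
# conditions" selection rule at the conventional r > 0.7 cutoff.

#' Screen configuration
#'
#' Collects the tunable thresholds of the funnel in one validated object.
#'
#' @param r_threshold Pearson cutoff for a "strong" correlation (default 0.7,
#'   strict: a coefficient of exactly 0.7 does not count).
#' @param min_conditions minimum number of strong conditions for selection
#'   (default 3).
#' @param n_conditions number of conditions per gene (default 4: two regions
#'   x two choline doses).
#' @param use_absolute_r if TRUE, |r| is compared to the threshold so strong
#'   negative trends also count (default FALSE: signed r).
#' @param background_threshold proteome detection cutoff (default 7, log2).
#' @param cv_tolerance minimum CV percent for stage 2 (default 1e-9).
#' @param p_max association p-value cutoff for the SNP stage (default 0.05;
#'   records strictly over it are excluded).
#' @param convention phenotype convention, \code{"REMAINING"} or
#'   \code{"REDUCTION"} (see \code{\link{percent_reduction}}).
#' @return object of class \code{"screen_config"}.
#' @export
screen_config <- function(r_threshold = 0.7, min_conditions = 3, n_conditions = 4,
                          use_absolute_r = FALSE, background_threshold = 7,
                          cv_tolerance = 1e-9, p_max = 0.05,
                          convention = c("REMAINING", "REDUCTION")) {
  convention <- match.arg(convention)
  if (!(r_threshold > 0 && r_threshold < 1)) {
    validation_error("r_threshold must lie in (0, 1)")
  }
  if (min_conditions > n_conditions) {
    validation_error("min_conditions cannot exceed n_conditions")
  }
  if (!(p_max > 0 && p_max < 1)) validation_error("p_max must lie in (0, 1)")
  structure(list(r_threshold = r_threshold, min_conditions = min_conditions,
                 n_conditions = n_conditions, use_absolute_r = use_absolute_r,
                 background_threshold = background_threshold,
                 cv_tolerance = cv_tolerance, p_max = p_max,
                 convention = convention),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen configuration:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Plain product-moment coefficient with explicit degenerate-variance
#' handling: a constant vector on either side is an error, never a silent
#' \code{NA}.  Duplicated values short of full constancy are legal.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) validation_error("x and y must have equal length")
  if (length(x) < 3L) validation_error("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    validation_error("x and y must be finite")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("zero variance: correlation undefined", "degenerate_variance_error")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Two-sided p-value for a Pearson coefficient
#'
#' Standard t transform: \code{t = r * sqrt((n-2) / (1-r^2))} on \code{n-2}
#' degrees of freedom.  With strain-level data the sample sizes here are tiny
#' (n = 3 gives 1 df), so these p-values are informational output for the
#' report, not a selection criterion.
#'
#' @param r Pearson coefficient.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value; exactly 0 when |r| = 1 (degenerate limit).
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3L) validation_error("need n >= 3 for a correlation p-value")
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# Apply the m-of-k selection rule to a long-form grid (gene, region, dose, r).
select_from_grid <- function(grid, cfg) {
  genes <- unique(grid$gene)
  strong <- if (isTRUE(cfg$use_absolute_r)) abs(grid$r) > cfg$r_threshold
            else grid$r > cfg$r_threshold
  hits <- tapply(strong, factor(grid$gene, levels = genes), sum)
  genes[!is.na(hits) & hits >= cfg$min_conditions]
}

#' Correlate protein abundance with the reduction phenotype and select genes
#'
#' For each candidate gene, Pearson-correlates its per-strain abundance with
#' the reduction statistic in each of the four conditions (two regions x two
#' choline doses).  Strains missing either the protein value or the phenotype
#' cell are dropped for that gene (recorded in \code{attr(, "dropped_strains")});
#' at least 3 common strains are required.  A gene is selected when the
#' threshold rule holds in at least \code{min_conditions} conditions.
#'
#' @param proteome a \code{\link{proteome_table}}.
#' @param reductions a \code{"reduction_matrix"} from
#'   \code{\link{build_reduction_matrix}}.
#' @param genes candidate genes (matched case-insensitively).
#' @param cfg a \code{\link{screen_config}}.
#' @return list with \code{grid} (data.frame gene/region/dose/r/n/p) and
#'   \code{selected} (character vector).
#' @export
screen_correlations <- function(proteome, reductions, genes,
                                cfg = screen_config()) {
  cells <- list()
  dropped <- list()
  for (g in genes) {
    row <- match_gene(g, rownames(proteome))
    if (is.na(row)) {
      abort(sprintf("gene %s has no proteome row", g), "key_error", gene = g)
    }
    x_all <- unclass(proteome)[row, ]
    for (cond in colnames(reductions)) {
      parts <- strsplit(cond, "_", fixed = TRUE)[[1L]]
      common <- intersect(names(x_all)[is.finite(x_all)],
                          rownames(reductions)[is.finite(reductions[, cond])])
      lost <- setdiff(union(names(x_all), rownames(reductions)), common)
      if (length(lost)) {
        dropped[[paste(g, cond)]] <- data.frame(
          gene = g, condition = cond, strain = lost,
          reason = "missing protein or phenotype value", stringsAsFactors = FALSE)
      }
      if (length(common) < 3L) {
        abort(sprintf("fewer than 3 strains with both protein and phenotype data for %s (%s)",
                      g, cond),
              "insufficient_strains_error", gene = g, condition = cond)
      }
      x <- x_all[common]
      y <- reductions[common, cond]
      r <- pearson_r(x, y)
      cells[[paste(g, cond)]] <- data.frame(
        gene = g, region = parts[1L], dose = as.numeric(parts[2L]),
        r = r, n = length(common), p = correlation_pvalue(r, length(common)),
        stringsAsFactors = FALSE)
    }
  }
  grid <- if (length(cells)) do.call(rbind, c(cells, make.row.names = FALSE)) else
    data.frame(gene = character(0), region = character(0), dose = numeric(0),
               r = numeric(0), n = integer(0), p = numeric(0))
  structure(list(grid = grid, selected = select_from_grid(grid, cfg)),
            dropped_strains = if (length(dropped))
              do.call(rbind, c(dropped, make.row.names = FALSE)) else NULL)
}
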