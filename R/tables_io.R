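# Readers, writers and bundled fixtures for the four tabular inputs:
# gene x strain haplotype calls, gene x strain liver protein abundances,
# litter-level cell-death observations, and SNP-phenotype association rows.

HAPLOTYPE_CODES <- c("B6", "D2", "H", "R", "NV")

#' Construct a haplotype call table
#'
#' A gene-by-strain character matrix of parental-origin calls for a
#' recombinant-inbred panel.  Valid calls are \code{B6}, \code{D2}, \code{H}
#' (heterozygous), \code{R} (recombinant) and \code{NV} (gene-level flag: no
#' variation across the panel).  \code{NV} is all-or-none within a gene row.
#'
#' @param calls character matrix with genes as rownames and strains as
#'   colnames.
#' @return an object of class \code{"haplotype_table"}.
#' @export
haplotype_table <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  genes <- rownames(calls)
  strains <- colnames(calls)
  if (is.null(strains) || anyDuplicated(strains)) {
    validation_error("strain identifiers must be present and unique")
  }
  if (nrow(calls) > 0L) {
    if (is.null(genes) || anyDuplicated(tolower(genes))) {
      validation_error("gene symbols must be present and unique")
    }
    bad <- matrix(!(calls %in% HAPLOTYPE_CODES), nrow = nrow(calls))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      validation_error(sprintf(
        "unknown haplotype code '%s' for gene %s, strain %s",
        calls[idx[1L], idx[2L]], genes[idx[1L]], strains[idx[2L]]),
        gene = genes[idx[1L]], strain = strains[idx[2L]])
    }
    nv_mixed <- apply(calls, 1L, function(row) any(row == "NV") && !all(row == "NV"))
    if (any(nv_mixed)) {
      validation_error(sprintf(
        "gene %s mixes NV with per-strain calls; NV is a gene-level flag",
        genes[which(nv_mixed)[1L]]))
    }
  }
  structure(calls, class = c("haplotype_table", class(calls)))
}

#' Read a haplotype call table
#'
#' Expects a header row naming the strain columns; the first column holds gene
#' symbols.  Calls outside \code{B6/D2/H/R/NV} are rejected.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return a \code{\link{haplotype_table}}.
#' @export
read_haplotype_table <- function(path, dialect = c("tsv", "csv")) {
  df <- read_delim_chr(path, dialect_sep(dialect))
  if (ncol(df) < 2L) {
    format_error(sprintf("%s: need a gene column plus at least one strain column", path))
  }
  calls <- as.matrix(df[, -1L, drop = FALSE])
  rownames(calls) <- df[[1L]]
  haplotype_table(calls)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d genes x %d strains (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Construct a liver proteome abundance table
#'
#' Gene-by-strain numeric matrix of log2-scale protein abundances
#' (a difference of 1.0 is a two-fold expression difference).  \code{NA}
#' marks a missing cell; a gene with no row at all is distinct from a gene
#' present with missing cells.
#'
#' @param abundance numeric matrix, genes as rownames, strains as colnames.
#' @return an object of class \code{"proteome_table"}.
#' @export
proteome_table <- function(abundance) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(colnames(abundance)) || anyDuplicated(colnames(abundance))) {
    validation_error("strain identifiers must be present and unique")
  }
  if (nrow(abundance) > 0L &&
      (is.null(rownames(abundance)) || anyDuplicated(tolower(rownames(abundance))))) {
    validation_error("gene symbols must be present and unique")
  }
  if (any(is.infinite(abundance) | is.nan(abundance))) {
    validation_error("abundance values must be finite where present")
  }
  structure(abundance, class = c("proteome_table", class(abundance)))
}

#' Read a liver proteome abundance table
#'
#' Cells are period-decimal numerics or the missing token \code{"n/a"}
#' (case-insensitive; empty cells also count as missing).  Any other
#' non-numeric cell is a format error reported with its row and column.
#'
#' @inheritParams read_haplotype_table
#' @return a \code{\link{proteome_table}}.
#' @export
read_proteome_table <- function(path, dialect = c("tsv", "csv")) {
  df <- read_delim_chr(path, dialect_sep(dialect))
  if (ncol(df) < 2L) {
    format_error(sprintf("%s: need a gene column plus at least one strain column", path))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing <- tolower(trimws(raw)) %in% c("n/a", "na", "") | is.na(raw)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- !missing & is.na(vals)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(raw)), arr.ind = TRUE)[1L, ]
    format_error(sprintf("%s: non-numeric cell '%s' at row %d (gene %s), column %s",
                         path, raw[idx[1L], idx[2L]], idx[1L],
                         df[[1L]][idx[1L]], colnames(raw)[idx[2L]]))
  }
  vals[missing] <- NA_real_
  m <- matrix(vals, nrow = nrow(raw), ncol = ncol(raw),
              dimnames = list(df[[1L]], colnames(raw)))
  proteome_table(m)
}

#' @export
print.proteome_table <- function(x, ...) {
  cat(sprintf("Proteome table: %d genes x %d strains, log2 scale (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(unclass(x))
  invisible(x)
}

#' Read litter-level cell-death observations
#'
#' One row per litter: columns \code{strain}, \code{region}
#' (forebrain/brainstem), \code{treatment} (ETOH/MD), \code{choline_dose}
#' (mg/kg), \code{litter_id}, \code{litter_mean} (mean cell death over the
#' embryos of the litter; the litter is the unit of analysis).  Doses outside
#' the study's 0/100/250 design are allowed but flagged with a message.
#'
#' @inheritParams read_haplotype_table
#' @return a data.frame of class \code{"celldeath_obs"}.
#' @export
read_celldeath_table <- function(path, dialect = c("tsv", "csv")) {
  df <- read_delim_chr(path, dialect_sep(dialect))
  needed <- c("strain", "region", "treatment", "choline_dose", "litter_id", "litter_mean")
  miss <- setdiff(needed, colnames(df))
  if (length(miss)) {
    format_error(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  df <- df[, needed]
  df$choline_dose <- suppressWarnings(as.numeric(df$choline_dose))
  df$litter_mean <- suppressWarnings(as.numeric(df$litter_mean))
  celldeath_obs(df)
}

#' Validate a data.frame of cell-death observations
#'
#' @param df data.frame with columns strain, region, treatment, choline_dose,
#'   litter_id, litter_mean.
#' @return the validated data.frame, classed \code{"celldeath_obs"}.
#' @export
celldeath_obs <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$region <- tolower(df$region)
  df$treatment <- toupper(df$treatment)
  if (!all(df$region %in% c("forebrain", "brainstem"))) {
    validation_error("region must be 'forebrain' or 'brainstem'")
  }
  if (!all(df$treatment %in% c("ETOH", "MD"))) {
    validation_error("treatment must be 'ETOH' or 'MD'")
  }
  if (any(is.na(df$litter_mean)) || any(df$litter_mean < 0)) {
    validation_error("litter_mean must be numeric and non-negative")
  }
  if (any(is.na(df$choline_dose))) {
    validation_error("choline_dose must be numeric")
  }
  key <- do.call(paste, c(df[c("strain", "region", "treatment", "choline_dose",
                               "litter_id")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    validation_error(sprintf(
      "duplicate observation key: %s/%s/%s/dose %s/litter %s",
      dup$strain, dup$region, dup$treatment, dup$choline_dose, dup$litter_id))
  }
  odd <- setdiff(unique(df$choline_dose), c(0, 100, 250))
  if (length(odd)) {
    message("note: choline dose(s) outside the 0/100/250 design: ",
            paste(odd, collapse = ", "))
  }
  class(df) <- c("celldeath_obs", "data.frame")
  df
}

#' Read a GWAS SNP-association table
#'
#' Three columns: variant id, phenotype label, p-value.  P-values may use the
#' typeset \code{"3.01 x 10^-2^"} notation (with the typographic minus and
#' multiplication sign); these are ASCII-normalized by
#' \code{\link{normalize_scientific}} before parsing.  Records come back with
#' \code{category = "UNASSIGNED"}; only \code{\link{categorize_records}}
#' assigns categories.
#'
#' @inheritParams read_haplotype_table
#' @return a data.frame of class \code{"snp_records"} with columns
#'   \code{variant_id}, \code{phenotype}, \code{p_value}, \code{category}.
#' @export
read_gwas_table <- function(path, dialect = c("tsv", "csv")) {
  df <- read_delim_chr(path, dialect_sep(dialect))
  if (ncol(df) != 3L) {
    format_error(sprintf("%s: expected 3 columns (variant, phenotype, p), got %d",
                         path, ncol(df)))
  }
  colnames(df) <- c("variant_id", "phenotype", "p_value")
  p <- suppressWarnings(as.numeric(normalize_scientific(df$p_value)))
  if (any(is.na(p))) {
    i <- which(is.na(p))[1L]
    format_error(sprintf("%s: unparseable p-value '%s' at row %d", path,
                         df$p_value[i], i))
  }
  snp_records(data.frame(variant_id = df$variant_id, phenotype = df$phenotype,
                         p_value = p, stringsAsFactors = FALSE))
}

#' Validate SNP association records
#'
#' @param df data.frame with columns variant_id, phenotype, p_value and
#'   optionally category.
#' @return the validated data.frame, classed \code{"snp_records"}.
#' @export
snp_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(is.na(df$p_value)) || any(df$p_value <= 0 | df$p_value > 1)) {
    i <- which(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)[1L]
    validation_error(sprintf("p-value out of (0, 1] for variant %s: %s",
                             df$variant_id[i], format(df$p_value[i])))
  }
  if (is.null(df$category)) df$category <- "UNASSIGNED"
  class(df) <- c("snp_records", "data.frame")
  df
}

# ---- writers (round-trip counterparts of the readers) ----------------------

write_matrix_table <- function(m, path, sep, na_token = "n/a") {
  mm <- unclass(m)
  header <- paste(c("gene", colnames(mm)), collapse = sep)
  body <- character(0)
  if (nrow(mm) > 0L) {
    # cell-wise formatting: no column-width padding, NA becomes the token
    cells <- matrix(vapply(mm, function(v) {
      if (is.na(v)) na_token
      else if (is.numeric(v)) trimws(format(v, scientific = FALSE, digits = 15))
      else as.character(v)
    }, character(1)), nrow = nrow(mm))
    body <- paste(rownames(mm), apply(cells, 1L, paste, collapse = sep), sep = sep)
  }
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a haplotype table
#' @param table a \code{\link{haplotype_table}}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_haplotype_table <- function(table, path, dialect = c("tsv", "csv")) {
  write_matrix_table(table, path, dialect_sep(dialect))
}

#' Write a proteome table (missing cells become \code{"n/a"})
#' @inheritParams write_haplotype_table
#' @param table a \code{\link{proteome_table}}.
#' @export
write_proteome_table <- function(table, path, dialect = c("tsv", "csv")) {
  write_matrix_table(table, path, dialect_sep(dialect))
}

#' Write cell-death observations
#' @param obs a \code{\link{celldeath_obs}} data.frame.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_celldeath_table <- function(obs, path, dialect = c("tsv", "csv")) {
  sep <- dialect_sep(dialect)
  utils::write.table(as.data.frame(obs), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write SNP association records
#' @param records a \code{\link{snp_records}} data.frame.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_gwas_table <- function(records, path, dialect = c("tsv", "csv")) {
  sep <- dialect_sep(dialect)
  df <- as.data.frame(records)[, c("variant_id", "phenotype", "p_value")]
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a precomputed correlation grid
#'
#' A wide gene-by-condition table with columns
#' \code{<region>_<dose>} (e.g. \code{brainstem_100}), as the published
#' Pearson-coefficient table is laid out.  Returned in long form.
#'
#' @inheritParams read_haplotype_table
#' @return data.frame with columns gene, region, dose, r.
#' @export
read_correlation_grid <- function(path, dialect = c("tsv", "csv")) {
  df <- read_delim_chr(path, dialect_sep(dialect))
  conds <- colnames(df)[-1L]
  parsed <- regmatches(conds, regexec("^(forebrain|brainstem)_([0-9]+)$", conds))
  if (any(lengths(parsed) != 3L)) {
    format_error(sprintf("%s: condition columns must be <region>_<dose>", path))
  }
  long <- do.call(rbind, lapply(seq_along(conds), function(j) {
    data.frame(gene = df[[1L]],
               region = parsed[[j]][2L],
               dose = as.numeric(parsed[[j]][3L]),
               r = suppressWarnings(as.numeric(df[[conds[j]]])),
               stringsAsFactors = FALSE)
  }))
  if (any(is.na(long$r))) format_error(sprintf("%s: non-numeric correlation cell", path))
  if (any(abs(long$r) > 1)) validation_error("correlation coefficients must lie in [-1, 1]")
  long[order(match(long$gene, df[[1L]])), c("gene", "region", "dose", "r")]
}

#' Load the bundled published tables
#'
#' Returns the study's printed tables, transcribed cell-for-cell into
#' plain-text fixtures shipped with the package: the 22-gene haplotype table,
#' the 5-gene liver proteome table, the Pearson-coefficient grid, and the two
#' per-gene SNP association tables.
#'
#' @return a list with elements \code{haplotypes}, \code{proteome},
#'   \code{correlations} (long-form grid) and \code{snps} (named list of
#'   \code{snp_records} for Cept1 and Slc44a1).
#' @export
load_published_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "cholscreen", mustWork = TRUE)
  list(
    haplotypes = read_haplotype_table(ext("haplotype_calls.tsv")),
    proteome = read_proteome_table(ext("liver_proteome.tsv")),
    correlations = read_correlation_grid(ext("correlation_grid.tsv")),
    snps = list(
      Cept1 = read_gwas_table(ext("cept1_snp_associations.tsv")),
      Slc44a1 = read_gwas_table(ext("slc44a1_snp_associations.tsv"))
    )
  )
}
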