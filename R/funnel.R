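# End-to-end funnel: haplotype variability -> proteome background -> CV ->
# correlation screen -> SNP annotation of the survivors.  Each stage records
# the genes it removed and why; retained sets are nested by construction.

#' Run the candidate-gene screening funnel
#'
#' Stages execute strictly in order; every elimination is recorded with its
#' stage and reason, and the survivors of each stage feed the next.  The
#' correlation stage accepts either litter-level cell-death observations (the
#' reduction matrix is computed internally) or a precomputed long-form
#' correlation grid; the published Pearson grid is consumed via the second
#' route because the underlying cell-death values are not printed.  If a
#' stage fails, the partial report (stages completed so far, failed stage
#' marked \code{ABORTED}) is returned with \code{status = "aborted"}.
#'
#' @param haplotypes a \code{\link{haplotype_table}} or path.
#' @param proteome a \code{\link{proteome_table}} or path.
#' @param celldeath optional \code{\link{celldeath_obs}} or path.
#' @param correlations optional long-form grid (gene/region/dose/r) or path;
#'   exactly one of \code{celldeath}/\code{correlations} must be given.
#' @param gwas named list (gene -> \code{\link{snp_records}} or path) of
#'   association tables for the SNP annotation stage; genes without a table
#'   are annotated \code{NA}.
#' @param config a \code{\link{screen_config}}.
#' @param panel strain ids for the haplotype stage (default: all strains of
#'   the haplotype table).
#' @param mapping a \code{\link{category_mapping}} for the SNP stage.
#' @return object of class \code{"funnel_report"}.
#' @export
run_funnel <- function(haplotypes, proteome, celldeath = NULL,
                       correlations = NULL, gwas = list(),
                       config = screen_config(),
                       panel = NULL, mapping = default_category_mapping()) {
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(dim(x))
  if (is_path(haplotypes)) haplotypes <- read_haplotype_table(haplotypes)
  if (is_path(proteome)) proteome <- read_proteome_table(proteome)
  if (is_path(celldeath)) celldeath <- read_celldeath_table(celldeath)
  if (is_path(correlations)) correlations <- read_correlation_grid(correlations)
  if (is.null(celldeath) == is.null(correlations)) {
    validation_error("supply exactly one of celldeath observations or a correlation grid")
  }
  gwas <- lapply(gwas, function(g) if (is_path(g)) read_gwas_table(g) else g)
  if (is.null(panel)) panel <- colnames(haplotypes)

  stages <- list()
  current <- rownames(haplotypes)
  if (is.null(current)) current <- character(0)
  add_stage <- function(name, criterion, retained, removed) {
    stages[[length(stages) + 1L]] <<- list(
      name = name, criterion = criterion,
      input = current, retained = retained, removed = removed)
    current <<- retained
  }
  fail <- function(name, cond) {
    stages[[length(stages) + 1L]] <- list(
      name = name, criterion = "ABORTED", input = current,
      retained = character(0),
      removed = data.frame(gene = character(0), reason = character(0)),
      error = conditionMessage(cond))
    funnel_report(stages, final_candidates = character(0), config = config,
                  status = "aborted", aborted_stage = name)
  }

  # stage 1: haplotype variability
  res <- tryCatch(
    if (length(current)) filter_by_haplotype(haplotypes, panel)
    else list(retained = character(0),
              removed = data.frame(gene = character(0), reason = character(0))),
    cholscreen_error = function(e) e)
  if (inherits(res, "condition")) return(fail("haplotype_variability", res))
  add_stage("haplotype_variability",
            sprintf("at least one haplotypic difference (B6/D2/H/R) across panel {%s}",
                    paste(panel, collapse = ", ")),
            res$retained, res$removed)

  # stage 2: proteome detection above background
  res <- tryCatch(
    filter_by_background(proteome, genes = current,
                         threshold = config$background_threshold),
    cholscreen_error = function(e) e)
  if (inherits(res, "condition")) return(fail("proteome_background", res))
  bg_values <- res$values
  add_stage("proteome_background",
            sprintf("proteome row present and all abundances > %g (log2)",
                    config$background_threshold),
            res$retained, res$removed[, c("gene", "reason")])

  # stage 3: nonzero abundance variation
  cvres <- filter_by_cv(bg_values[current], tolerance = config$cv_tolerance)
  add_stage("proteome_cv",
            sprintf("across-strain coefficient of variation > %g%%", config$cv_tolerance),
            cvres$retained, cvres$removed[, c("gene", "reason")])
  cv_full <- cvres$cv

  # stage 4: correlation screen
  if (!is.null(celldeath)) {
    res <- tryCatch({
      reductions <- build_reduction_matrix(celldeath, convention = config$convention)
      screen_correlations(proteome, reductions, current, config)
    }, cholscreen_error = function(e) e)
  } else {
    res <- tryCatch({
      grid <- correlations[!is.na(match_gene_vec(correlations$gene, current)), ,
                           drop = FALSE]
      list(grid = grid, selected = select_from_grid(grid, config))
    }, cholscreen_error = function(e) e)
  }
  if (inherits(res, "condition")) return(fail("correlation_screen", res))
  grid <- res$grid
  sel <- current[!is.na(match(tolower(current), tolower(res$selected)))]
  rule <- if (isTRUE(config$use_absolute_r)) "|r|" else "r"
  add_stage("correlation_screen",
            sprintf("%s > %g in at least %d of %d region x dose conditions",
                    rule, config$r_threshold, config$min_conditions,
                    config$n_conditions),
            sel,
            {
              lost <- setdiff(current, sel)
              data.frame(gene = lost,
                         reason = rep(sprintf("fewer than %d conditions with %s > %g",
                                              config$min_conditions, rule,
                                              config$r_threshold), length(lost)),
                         stringsAsFactors = FALSE)
            })

  # stage 5 (annotation, no elimination): SNP category counts for survivors
  snp_counts <- list()
  for (g in current) {
    key <- match_gene(g, names(gwas))
    if (is.na(key)) next
    tab <- gwas[[key]]
    if (is.null(tab)) next
    kept <- filter_by_pvalue(tab, config$p_max)
    kept <- categorize_records(kept, mapping)
    snp_counts[[g]] <- count_categories(kept, gene = g)
  }

  funnel_report(stages, final_candidates = current, config = config,
                snp_counts = snp_counts, correlation_grid = grid,
                cv = cv_full)
}

match_gene_vec <- function(x, table) match(tolower(x), tolower(table))

#' Construct a funnel report
#'
#' Validates the partition and nesting invariants: within every stage the
#' retained and removed sets are disjoint and together equal the stage input,
#' and each stage's input is the previous stage's retained set.
#'
#' @param stages list of stage records (name, criterion, input, retained,
#'   removed).
#' @param final_candidates character vector.
#' @param config the \code{\link{screen_config}} used.
#' @param snp_counts optional named list from \code{\link{count_categories}}.
#' @param correlation_grid optional long-form grid kept for rendering.
#' @param cv optional named numeric of stage-3 CVs.
#' @param status \code{"complete"} or \code{"aborted"}.
#' @param aborted_stage stage name when aborted.
#' @return object of class \code{"funnel_report"}.
#' @export
funnel_report <- function(stages, final_candidates, config,
                          snp_counts = list(), correlation_grid = NULL,
                          cv = NULL, status = "complete", aborted_stage = NULL) {
  prev <- NULL
  for (st in stages) {
    if (!is.null(st$error)) next
    both <- intersect(st$retained, st$removed$gene)
    if (length(both)) {
      validation_error(sprintf("stage %s: genes both retained and removed", st$name))
    }
    if (!setequal(c(st$retained, st$removed$gene), st$input)) {
      validation_error(sprintf("stage %s: retained + removed != input", st$name))
    }
    if (!is.null(prev) && !setequal(st$input, prev)) {
      validation_error(sprintf("stage %s: input is not the previous retained set", st$name))
    }
    prev <- st$retained
  }
  structure(list(stages = stages, final_candidates = final_candidates,
                 config = config, snp_counts = snp_counts,
                 correlation_grid = correlation_grid, cv = cv,
                 status = status, aborted_stage = aborted_stage),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate-gene screening funnel\n")
  for (st in x$stages) {
    if (!is.null(st$error)) {
      cat(sprintf("  stage %s: ABORTED (%s)\n", st$name, st$error))
    } else {
      cat(sprintf("  stage %s: retained %d, removed %d\n",
                  st$name, length(st$retained), nrow(st$removed)))
    }
  }
  if (identical(x$status, "complete")) {
    cat(sprintf("  final candidates: %s\n",
                if (length(x$final_candidates))
                  paste(x$final_candidates, collapse = ", ") else "(none)"))
  } else {
    cat(sprintf("  run aborted at stage %s\n", x$aborted_stage))
  }
  invisible(x)
}

# Serializable summary shared by the JSON / TSV / Markdown renderers.
report_payload <- function(report) {
  list(
    status = report$status,
    config = unclass(report$config),
    stages = lapply(report$stages, function(st) {
      out <- list(name = st$name, criterion = st$criterion,
                  n_input = length(st$input),
                  n_retained = length(st$retained),
                  n_removed = nrow(st$removed),
                  retained = st$retained,
                  removed = st$removed)
      if (!is.null(st$error)) out$error <- st$error
      out
    }),
    final_candidates = report$final_candidates,
    snp_counts = lapply(report$snp_counts, function(sc)
      list(gene = sc$gene, counts = as.list(sc$counts),
           total_rows = sc$total_rows))
  )
}

#' Render a funnel report to text
#'
#' @param report a \code{\link{funnel_report}}.
#' @param format \code{"tsv"}, \code{"json"} or \code{"markdown"}.
#' @return character vector of lines (one JSON string for \code{"json"}).
#' @export
render_report <- function(report, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  pl <- report_payload(report)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(pl, auto_unbox = TRUE, pretty = TRUE,
                                         digits = NA)))
  }
  if (format == "tsv") {
    lines <- c("stage\tcriterion\tn_input\tn_retained\tn_removed\tretained\tremoved")
    for (st in pl$stages) {
      lines <- c(lines, paste(
        st$name, st$criterion, st$n_input, st$n_retained, st$n_removed,
        paste(st$retained, collapse = ","),
        paste(sprintf("%s[%s]", st$removed$gene, st$removed$reason), collapse = ","),
        sep = "\t"))
    }
    lines <- c(lines, sprintf("final_candidates\t\t\t%d\t\t%s\t",
                              length(pl$final_candidates),
                              paste(pl$final_candidates, collapse = ",")))
    for (sc in pl$snp_counts) {
      lines <- c(lines, sprintf("snp_counts:%s\t\t\t\t\t%s\t", sc$gene,
                                paste(sprintf("%s=%d", names(sc$counts),
                                              unlist(sc$counts)), collapse = ",")))
    }
    return(lines)
  }
  # markdown
  lines <- c("# Candidate-gene screening funnel", "",
             sprintf("Status: %s", pl$status), "")
  for (st in pl$stages) {
    lines <- c(lines, sprintf("## Stage %s", st$name),
               sprintf("Criterion: %s", st$criterion),
               if (!is.null(st$error)) sprintf("**ABORTED**: %s", st$error)
               else sprintf("retained %d, removed %d", st$n_retained, st$n_removed),
               sprintf("- retained: %s", paste(st$retained, collapse = ", ")),
               "")
    if (nrow(st$removed)) {
      lines <- c(lines, sprintf("- removed %s (%s)", st$removed$gene,
                                st$removed$reason), "")
    }
  }
  lines <- c(lines, "## Final candidates",
             paste(pl$final_candidates, collapse = ", "), "")
  for (sc in pl$snp_counts) {
    lines <- c(lines, sprintf("- %s SNP rows: %s", sc$gene,
                              paste(sprintf("%s %d", names(sc$counts),
                                            unlist(sc$counts)), collapse = ", ")))
  }
  lines
}

#' Write a funnel report to disk
#'
#' Output is deterministic for a fixed report: gene lists keep input order
#' and the same report written twice yields byte-identical files.
#'
#' @param report a \code{\link{funnel_report}}.
#' @param path output file path.
#' @param format \code{"tsv"}, \code{"json"} or \code{"markdown"}; default
#'   inferred from the file extension (falling back to TSV).
#' @export
write_funnel_report <- function(report, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", md = "markdown", markdown = "markdown",
                     "tsv")
  }
  lines <- render_report(report, format)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(sprintf("cannot write %s", path), "io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
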