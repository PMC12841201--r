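# Seeded generators for the four input tables, with a planted linear
# protein -> phenotype link so the whole funnel can be exercised against a
# known ground truth.  Defaults mirror the study design: a 22-gene candidate
# list over a 4-strain panel, liver proteome data for 3 of the 4 strains,
# two brain regions, choline at 0/100/250 mg/kg crossed with ethanol or
# maltose-dextrin control, and 5-8 litters per treatment group.

#' Simulation parameters
#'
#' @param n_genes number of candidate genes (default 22, the size of the
#'   study's literature-derived list).
#' @param n_strains panel size (default 4).
#' @param p_variable probability a gene's haplotype varies across the panel
#'   (default 12/22, the study's observed fraction).
#' @param p_nv probability an invariant gene is recorded as the gene-level
#'   NV flag rather than a uniform parental call (default 0.7, mirroring the
#'   7-of-10 split among the study's invariant genes).
#' @param p_het,p_recomb per-strain probabilities of an H or R call within a
#'   variable gene (defaults 0.05 each; sparse, as in the published calls).
#' @param p_measured probability a gene has a liver proteome row (default
#'   5/12, the study's coverage of its variable genes).
#' @param n_proteome_strains how many panel strains the proteome covers
#'   (default \code{n_strains - 1}: the remaining strains are all-missing
#'   columns, as BXD2 is in the published dataset).
#' @param proteome_mean,strain_sd mean and across-strain SD of log2 abundance
#'   (defaults 16 and 0.2; the published abundances span ~12.6-22 with
#'   across-strain SDs near 0.15-0.2).
#' @param md_mean baseline cell death of the maltose-dextrin controls
#'   (arbitrary TUNEL units, default 20).
#' @param ethanol_effect added cell death in the ethanol/no-choline group
#'   (default 20, i.e. a doubling; must be nonzero).
#' @param rho_base baseline remaining fraction of ethanol-induced death under
#'   choline (default 0.4, i.e. a 60 percent reduction).
#' @param planted_genes character vector of genes whose protein level drives
#'   the phenotype (default: one gene, \code{"g01"}).
#' @param beta_forebrain,beta_brainstem planted slopes, in reduction percent
#'   per log2-unit protein (defaults 100 and 100; the two regions can be set
#'   independently to exercise the 3-of-4 rule).
#' @param noise_sd litter-mean noise SD in cell-death units (default 2).
#' @param litters_min,litters_max litters per treatment group, drawn
#'   uniformly (defaults 5 and 8, the study's range).
#' @param seed RNG seed.
#' @return object of class \code{"sim_params"}.
#' @export
sim_params <- function(n_genes = 22, n_strains = 4, p_variable = 12 / 22,
                       p_nv = 0.7, p_het = 0.05, p_recomb = 0.05,
                       p_measured = 5 / 12, n_proteome_strains = n_strains - 1,
                       proteome_mean = 16, strain_sd = 0.2,
                       md_mean = 20, ethanol_effect = 20, rho_base = 0.4,
                       planted_genes = "g01",
                       beta_forebrain = 100, beta_brainstem = 100,
                       noise_sd = 2, litters_min = 5, litters_max = 8,
                       seed = 1L) {
  probs <- c(p_variable, p_nv, p_het, p_recomb, p_measured)
  if (any(probs < 0 | probs > 1)) validation_error("probabilities must lie in [0, 1]")
  if (ethanol_effect == 0) validation_error("ethanol_effect must be nonzero")
  if (litters_min < 1 || litters_max < litters_min) {
    validation_error("litters per group must satisfy 1 <= min <= max")
  }
  if (n_proteome_strains < 1 || n_proteome_strains > n_strains) {
    validation_error("n_proteome_strains must lie in [1, n_strains]")
  }
  structure(as.list(environment())[setdiff(names(formals(sim_params)), "probs")],
            class = "sim_params")
}

# Run fn with the RNG seeded from (seed, offset), restoring the caller's RNG
# state afterwards so the generators behave as pure functions of their
# arguments.
with_sim_seed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  fn()
}

sim_gene_names <- function(n) sprintf("g%02d", seq_len(n))
sim_strain_names <- function(n) c("B6", sprintf("BXD%02d", seq_len(n - 1L)))

#' Simulate a haplotype table, proteome table and ground-truth record
#'
#' Variable genes receive at least two distinct calls across the panel by
#' construction (a D2 block on a random nonempty proper subset of strains,
#' with sparse H/R calls sprinkled in); invariant genes are written either as
#' the gene-level NV flag or as a uniform parental call.  Proteome rows exist
#' for a random subset of genes (always including the planted genes) and
#' cover the first \code{n_proteome_strains} strains; the remaining strains
#' are all-missing, mirroring a strain absent from the reference dataset.
#'
#' @param params a \code{\link{sim_params}}.
#' @return list with \code{haplotypes}, \code{proteome} and \code{truth}
#'   (list: planted genes and slopes, variable genes, measured genes,
#'   baseline parameters).
#' @export
simulate_panel <- function(params) {
  with_sim_seed(params$seed, 0L, function() {
    genes <- sim_gene_names(params$n_genes)
    strains <- sim_strain_names(params$n_strains)
    ns <- params$n_strains

    calls <- matrix("B6", params$n_genes, ns, dimnames = list(genes, strains))
    variable <- stats::runif(params$n_genes) < params$p_variable
    for (i in seq_len(params$n_genes)) {
      if (variable[i]) {
        k <- sample(ns - 1L, 1L)            # D2 block: proper nonempty subset
        calls[i, sample(ns, k)] <- "D2"
        extra <- stats::runif(ns)
        calls[i, extra < params$p_het] <- "H"
        calls[i, extra >= params$p_het &
                   extra < params$p_het + params$p_recomb] <- "R"
        if (length(unique(calls[i, ])) < 2L) {       # H/R overwrite collapsed it
          calls[i, sample(ns, 1L)] <- setdiff(c("B6", "D2"), calls[i, 1L])[1L]
        }
      } else if (stats::runif(1) < params$p_nv) {
        calls[i, ] <- "NV"
      } else {
        calls[i, ] <- sample(c("B6", "D2"), 1L)
      }
    }

    measured <- stats::runif(params$n_genes) < params$p_measured
    measured[genes %in% params$planted_genes] <- TRUE
    prot_strains <- strains[seq_len(params$n_proteome_strains)]
    ab <- matrix(NA_real_, sum(measured), ns,
                 dimnames = list(genes[measured], strains))
    for (g in rownames(ab)) {
      gene_mean <- stats::rnorm(1, params$proteome_mean, 2)
      ab[g, prot_strains] <- stats::rnorm(length(prot_strains), gene_mean,
                                          params$strain_sd)
    }

    list(
      haplotypes = haplotype_table(calls),
      proteome = proteome_table(ab),
      truth = list(planted = params$planted_genes,
                   beta_forebrain = params$beta_forebrain,
                   beta_brainstem = params$beta_brainstem,
                   variable_genes = genes[variable],
                   measured_genes = genes[measured],
                   proteome_strains = prot_strains,
                   rho_base = params$rho_base)
    )
  })
}

#' Simulate litter-level cell-death observations
#'
#' Per strain, region, treatment and dose, litter means are drawn normal
#' around a group mean.  Controls (MD) sit at \code{md_mean} regardless of
#' dose; the ethanol/no-choline group at \code{md_mean + ethanol_effect}; and
#' the choline+ethanol groups at the level implied by a target percent
#' reduction of \code{100 * (1 - rho_base)} shifted linearly, for planted
#' genes, by the strain's centered protein abundance times the region's
#' slope.  With \code{noise_sd = 0} and a single planted gene the planted
#' protein-reduction relationship is exactly linear, so its Pearson
#' coefficients are exactly +/-1.
#'
#' @param params a \code{\link{sim_params}}.
#' @param proteome the \code{\link{proteome_table}} from
#'   \code{\link{simulate_panel}} (planted genes must have rows).
#' @return a \code{\link{celldeath_obs}} data.frame.
#' @export
simulate_celldeath <- function(params, proteome) {
  planted <- params$planted_genes[params$planted_genes %in% rownames(proteome)]
  if (length(planted) < length(params$planted_genes)) {
    validation_error("planted genes must be present in the proteome table")
  }
  with_sim_seed(params$seed, 1L, function() {
    strains <- colnames(proteome)
    regions <- c("forebrain", "brainstem")
    base_reduction <- 100 * (1 - params$rho_base)
    # centered planted-protein signal per strain (0 where unmeasured)
    signal <- rep(0, length(strains)); names(signal) <- strains
    for (g in planted) {
      v <- unclass(proteome)[match_gene(g, rownames(proteome)), ]
      ok <- is.finite(v)
      signal[ok] <- signal[ok] + (v[ok] - mean(v[ok]))
    }
    beta <- c(forebrain = params$beta_forebrain, brainstem = params$beta_brainstem)

    rows <- list()
    litter_range <- seq(params$litters_min, params$litters_max)
    emit <- function(strain, region, treatment, dose, group_mean) {
      n <- litter_range[sample.int(length(litter_range), 1L)]
      mu <- stats::rnorm(n, group_mean, params$noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        strain = strain, region = region, treatment = treatment,
        choline_dose = dose, litter_id = sprintf("L%02d", seq_len(n)),
        litter_mean = pmax(mu, 0), stringsAsFactors = FALSE)
    }
    for (s in strains) {
      for (rg in regions) {
        for (d in c(0, 100, 250)) emit(s, rg, "MD", d, params$md_mean)
        emit(s, rg, "ETOH", 0, params$md_mean + params$ethanol_effect)
        reduction <- base_reduction + beta[rg] * signal[s]
        rho <- 1 - reduction / 100
        ce <- params$md_mean + rho * params$ethanol_effect
        for (d in c(100, 250)) emit(s, rg, "ETOH", d, ce)
      }
    }
    celldeath_obs(do.call(rbind, rows))
  })
}

#' Simulate GWAS SNP-association rows
#'
#' Phenotype labels are drawn from per-category pools (including ICD-style
#' K70/F10-prefixed labels, so the default ordered mapping is exercised) with
#' the given category weights.  P-values are log-uniform on
#' \code{[1e-8, 0.05]}, except a configurable fraction drawn uniformly above
#' 0.05 to exercise the p-filter.
#'
#' @param params a \code{\link{sim_params}} (supplies the seed).
#' @param n_rows number of association rows.
#' @param category_weights numeric length 3 (alcohol, liver, developmental),
#'   summing to 1.
#' @param fraction_above_p_max expected fraction of rows with p over 0.05
#'   (default 0).
#' @return a \code{\link{snp_records}} data.frame (categories UNASSIGNED).
#' @export
simulate_gwas <- function(params, n_rows = 100,
                          category_weights = c(0.6, 0.2, 0.2),
                          fraction_above_p_max = 0) {
  if (abs(sum(category_weights) - 1) > 1e-8) {
    validation_error("category_weights must sum to 1")
  }
  pools <- list(
    alcohol = c("K70 Alcoholic liver disease",
                "F10 Mental and behavioral disorders due to use of alcohol",
                "Alcoholism", "alcohol-related disorders"),
    liver = c("gamma glutamyltransferase activity", "Total cholesterol levels",
              "Triglyceride levels", "Disorders of lipid metabolism",
              "Liver abscess and sequelae of chronic liver disease"),
    developmental = c("height", "Lack of normal physiological development",
                      "Dementia with cerebral degenerations", "Depression",
                      "Psychogenic Disorders")
  )
  with_sim_seed(params$seed, 2L, function() {
    cat_idx <- sample(3L, n_rows, replace = TRUE, prob = category_weights)
    phenotype <- vapply(cat_idx, function(k) sample(pools[[k]], 1L), character(1))
    above <- stats::runif(n_rows) < fraction_above_p_max
    p <- ifelse(above,
                stats::runif(n_rows, 0.05 + 1e-6, 1),
                10^stats::runif(n_rows, -8, log10(0.05)))
    snp_records(data.frame(
      variant_id = sprintf("rs%07d", sample(1e7 - 1L, n_rows)),
      phenotype = phenotype, p_value = p, stringsAsFactors = FALSE))
  })
}
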