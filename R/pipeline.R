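# Configuration-driven orchestration of the full analysis:
# simulate/load -> preprocess -> differential abundance -> direction ->
# enrichment -> Fisher integration -> cohort screen.

#' Pipeline configuration
#'
#' Collects the analysis thresholds (all overridable), the input source
#' (either a [sim_config()] or a set of file paths), the seed, and an
#' optional output directory. Exactly one of `sim` / `paths` must be given.
#'
#' @param sim A `SimConfig` for a synthetic study, or `NULL`.
#' @param paths Named list of input files (`matrices`: named list of TSVs,
#'   `gmt`, optional `cohort_intensities`, `cohort_traits`), or `NULL`.
#' @param arms Named character vector condition -> arm; defaults to the
#'   simulation's arms or `"cell"` for every loaded matrix.
#' @param fc_threshold,fdr Differential-expression calling thresholds.
#' @param protein_alpha Per-condition significance for direction
#'   classification.
#' @param pathway_alpha Enrichment significance level (reported, not used
#'   as a filter before integration).
#' @param z_threshold Convergence-selection combined-z cutoff.
#' @param corr_alpha Correlation-screen two-sided level.
#' @param missing_threshold Group missing-fraction filter cutoff.
#' @param knn_k Imputation neighbour count.
#' @param seed Integer seed (required).
#' @param outdir Output directory, or `NULL` to keep results in memory.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, arms = NULL,
                            fc_threshold = 1.5, fdr = 0.05,
                            protein_alpha = 0.01, pathway_alpha = 0.05,
                            z_threshold = 4, corr_alpha = 0.05,
                            missing_threshold = 0.60, knn_k = 5,
                            seed = NULL, outdir = NULL) {
  if (is.null(seed)) stop("validation error: required field 'seed' is missing")
  if (is.null(sim) == is.null(paths)) {
    stop("validation error: exactly one of 'sim' or 'paths' must be provided")
  }
  for (thr in c(fdr, protein_alpha, pathway_alpha, corr_alpha)) {
    if (thr <= 0 || thr >= 1) stop("validation error: alpha/FDR thresholds must be in (0, 1)")
  }
  if (fc_threshold <= 1) stop("validation error: 'fc_threshold' must be > 1")
  if (missing_threshold <= 0 || missing_threshold > 1) {
    stop("validation error: 'missing_threshold' must be in (0, 1]")
  }
  structure(list(sim = sim, paths = paths, arms = arms,
                 fc_threshold = fc_threshold, fdr = fdr,
                 protein_alpha = protein_alpha,
                 pathway_alpha = pathway_alpha, z_threshold = z_threshold,
                 corr_alpha = corr_alpha,
                 missing_threshold = missing_threshold,
                 knn_k = as.integer(knn_k), seed = as.integer(seed),
                 outdir = outdir), class = "PipelineConfig")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    study <- simulate_proteome_panel(sim)
    cohort <- simulate_clinical_cohort(sim)
    list(matrices = study$matrices, sets = study$sets, arms = study$arms,
         cohort = cohort, truth = list(truth_de = study$truth_de,
                                       truth_pathway = study$truth_pathway))
  } else {
    p <- config$paths
    if (is.null(p$matrices) || is.null(p$gmt)) {
      stop("validation error: 'paths' needs 'matrices' and 'gmt'")
    }
    matrices <- lapply(p$matrices, read_expression_tsv)
    sets <- read_gmt(p$gmt)
    cohort <- NULL
    if (!is.null(p$cohort_intensities)) {
      traits <- utils::read.delim(p$cohort_traits, row.names = 1L,
                                  check.names = FALSE)
      cohort <- list(intensities = read_expression_tsv(p$cohort_intensities),
                     traits = traits)
    }
    arms <- config$arms %||%
      stats::setNames(rep("cell", length(matrices)), names(matrices))
    list(matrices = matrices, sets = sets, arms = arms, cohort = cohort,
         truth = NULL)
  }
}

#' Run the full convergence-analysis pipeline
#'
#' Stages, per condition contrast: group-wise missing-value filtering, KNN
#' imputation, empirical-Bayes moderated t-test with BH FDR and
#' fold-change calling, t-to-z transformation; then across conditions:
#' per-arm direction analysis, per-condition mean-rank pathway enrichment
#' on log2 fold changes, Fisher combination into per-arm combined z-scores
#' and convergence selection; and, when a cohort is present,
#' stable-reference normalisation, relative ratios, per-sample pathway
#' scores and the pathway-phenotype correlation screen with a
#' tertile-stratified trait comparison.
#'
#' @param config A [pipeline_config()].
#' @return List of class `PipelineResult`: `de` (per-condition DE tables),
#'   `direction` (per-arm tables), `enrichment` (per-condition tables),
#'   `combined` (per-arm combined z tables), `convergence` (selection),
#'   `cohort_screen`, `cohort_stratified`, `report` (per-stage counts,
#'   thresholds, seed). With `outdir` set, every table is also written as
#'   TSV plus a `run_report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  inputs <- load_pipeline_inputs(config)
  report <- list(seed = config$seed,
                 thresholds = config[c("fc_threshold", "fdr",
                                       "protein_alpha", "pathway_alpha",
                                       "z_threshold", "corr_alpha",
                                       "missing_threshold", "knn_k")],
                 stages = list())
  de <- list(); z_cols <- list(); enr <- list()
  for (cond in names(inputs$matrices)) {
    m <- inputs$matrices[[cond]]
    mf <- filter_group_missing(m, threshold = config$missing_threshold)
    mi <- knn_impute(mf, k = config$knn_k)
    res <- moderated_t_test(mi, c("treated", "control"))
    res <- call_de(res, config$fc_threshold, config$fdr)
    res$z <- t_to_z(res$t_mod, res$df_total)
    de[[cond]] <- res
    enr[[cond]] <- enrich_collection(
      stats::setNames(res$log_fc, res$feature_id), inputs$sets)
    report$stages[[cond]] <- list(
      n_input = nrow(m$values), n_removed = attr(mf, "n_removed"),
      n_imputed = attr(mi, "n_imputed"), n_de = sum(res$is_de))
  }
  # per-arm direction analysis on the shared feature universe
  arms <- inputs$arms
  direction <- list()
  for (arm in unique(arms)) {
    conds <- names(arms)[arms == arm]
    if (length(conds) < 2L) next
    shared <- Reduce(intersect, lapply(de[conds], `[[`, "feature_id"))
    z_mat <- sapply(conds, function(cn) {
      tab <- de[[cn]]
      tab$z[match(shared, tab$feature_id)]
    })
    p_mat <- sapply(conds, function(cn) {
      tab <- de[[cn]]
      tab$p[match(shared, tab$feature_id)]
    })
    rownames(z_mat) <- rownames(p_mat) <- shared
    direction[[arm]] <- direction_analysis(z_mat, p_mat,
                                           alpha = config$protein_alpha)
  }
  # Fisher integration per arm
  combined <- list()
  for (arm in unique(arms)) {
    conds <- names(arms)[arms == arm]
    p_mat <- sapply(conds, function(cn) {
      stats::setNames(enr[[cn]]$p, enr[[cn]]$set_name)
    })
    p_mat <- matrix(p_mat, ncol = length(conds),
                    dimnames = list(enr[[conds[1L]]]$set_name, conds))
    combined[[arm]] <- combine_pathway_scores(p_mat)
  }
  convergence <- NULL
  if (all(c("cell", "tissue") %in% names(combined))) {
    convergence <- convergence_select(combined$cell, combined$tissue,
                                      z_threshold = config$z_threshold)
  }
  # cohort stage
  cohort_screen <- NULL; cohort_strat <- NULL
  if (!is.null(inputs$cohort)) {
    norm <- stable_reference_normalise(inputs$cohort$intensities,
                                       log2_input = TRUE)
    rel <- relative_ratios(norm)
    scores <- pathway_sample_score(rel, inputs$sets)
    traits <- inputs$cohort$traits
    cohort_screen <- correlation_screen(scores, traits,
                                        alpha = config$corr_alpha)
    strat_trait <- colnames(traits)[1L]
    cohort_strat <- stratified_comparison(traits[[strat_trait]], traits)
    report$stages$cohort <- list(
      n_subjects = ncol(scores), reference = attr(norm, "reference"),
      n_significant = sum(cohort_screen$significant, na.rm = TRUE),
      stratified_by = strat_trait)
  }
  result <- structure(list(de = de, direction = direction,
                           enrichment = enr, combined = combined,
                           convergence = convergence,
                           cohort_screen = cohort_screen,
                           cohort_stratified = cohort_strat,
                           truth = inputs$truth, report = report),
                      class = "PipelineResult")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, fn) {
    utils::write.table(df, file.path(outdir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (cond in names(result$de)) wt(result$de[[cond]],
                                    sprintf("de_%s.tsv", cond))
  for (arm in names(result$direction)) wt(result$direction[[arm]],
                                          sprintf("direction_%s.tsv", arm))
  for (cond in names(result$enrichment)) wt(result$enrichment[[cond]],
                                            sprintf("enrichment_%s.tsv", cond))
  for (arm in names(result$combined)) wt(result$combined[[arm]],
                                         sprintf("combined_%s.tsv", arm))
  if (!is.null(result$convergence)) wt(result$convergence$table,
                                       "convergence.tsv")
  if (!is.null(result$cohort_screen)) wt(result$cohort_screen,
                                         "cohort_screen.tsv")
  if (!is.null(result$cohort_stratified)) wt(result$cohort_stratified,
                                             "cohort_stratified.tsv")
  jsonlite::write_json(result$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  for (cond in names(x$de)) {
    cat(sprintf("  %s: %d features, %d DE\n", cond, nrow(x$de[[cond]]),
                sum(x$de[[cond]]$is_de)))
  }
  if (!is.null(x$convergence)) {
    cat("  convergent pathways:",
        if (length(x$convergence$selected))
          paste(x$convergence$selected, collapse = ", ") else "(none)",
        "\n")
  }
  invisible(x)
}
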