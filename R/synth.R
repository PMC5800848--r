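# Seeded synthetic multi-condition proteome studies and clinical cohorts
# with known ground truth. The generator mirrors the structure of a
# multi-model insulin-resistance study: three cell-culture contrasts and two
# diet time-point contrasts, each a two-group replicate design, plus a
# clamp-phenotyped human-like cohort. Per-feature variances are drawn from a
# scaled inverse-chi-square prior so the moderated-t variance model is
# exactly correct on these data, which makes prior recovery a meaningful
# check rather than an approximation.

#' Configuration for a synthetic study
#'
#' Defaults define the reference study: 3000 proteins; five condition
#' contrasts in two arms (three cell models, two tissue time points); four
#' replicates per group; a 192-set pathway collection with one 20-member
#' set planted at +1.0 log2 in every condition; residual variances from a
#' scaled inverse-chi-square prior with d0 = 4 and s0^2 = 0.04 (sd 0.2
#' log2 units, a typical isotope-label ratio replicate spread); 5% missing completely
#' at random plus censoring below the 3% per-sample intensity quantile; and
#' a 22-subject cohort whose planted pathway score correlates with an
#' insulin-sensitivity-like trait at rho = 0.7.
#'
#' @param n_proteins Number of proteins.
#' @param conditions Named character vector: condition label -> arm label.
#' @param n_replicates_per_arm Replicates per group within each contrast.
#' @param pathway_sets Named list of member protein IDs, or `NULL` to
#'   generate `n_sets` random sets (plus the planted set) from the seed.
#' @param n_sets,set_size_range Collection size and per-set size range used
#'   when `pathway_sets` is `NULL`.
#' @param planted_sets Named list: set name -> member IDs, inserted into the
#'   collection and carrying the planted effects.
#' @param planted_effects Named list: set name -> named numeric vector of
#'   log2 effects per condition (or a single number for all conditions).
#' @param noise_sd Subject-level protein noise sd for the cohort (log2).
#' @param prior_d0,prior_s0_sq Variance-prior degrees of freedom and scale.
#' @param missing_rate_mcar Missing-completely-at-random cell rate.
#' @param mnar_intensity_quantile Per-sample quantile below which values are
#'   censored (0 disables).
#' @param phenotype_rho Planted pathway-trait correlation, |rho| < 1.
#' @param n_subjects Cohort size (>= 4).
#' @param baseline_mean,baseline_sd Log2 baseline abundance distribution.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_proteins = 3000,
                       conditions = c(CI = "cell", Dex = "cell",
                                      TNF = "cell", HFHSD_5d = "tissue",
                                      HFHSD_14d = "tissue"),
                       n_replicates_per_arm = 4,
                       pathway_sets = NULL,
                       n_sets = 192,
                       set_size_range = c(10, 60),
                       planted_sets = NULL,
                       planted_effects = NULL,
                       noise_sd = 0.2,
                       prior_d0 = 4,
                       prior_s0_sq = 0.04,
                       missing_rate_mcar = 0.05,
                       mnar_intensity_quantile = 0.03,
                       phenotype_rho = 0.7,
                       n_subjects = 22,
                       baseline_mean = 22,
                       baseline_sd = 1.5,
                       seed = 1L) {
  if (n_proteins < 1 || n_replicates_per_arm < 2 || n_subjects < 4) {
    stop("counts out of range: need n_proteins >= 1, replicates >= 2, subjects >= 4")
  }
  if (missing_rate_mcar < 0 || missing_rate_mcar > 1 ||
      mnar_intensity_quantile < 0 || mnar_intensity_quantile > 1) {
    stop("rates must be in [0, 1]")
  }
  if (abs(phenotype_rho) >= 1) stop("|phenotype_rho| must be < 1")
  if (prior_d0 <= 0 || prior_s0_sq <= 0) stop("variance prior must be positive")
  if (is.null(names(conditions))) stop("'conditions' must be named (label -> arm)")
  protein_ids <- sprintf("P%04d", seq_len(n_proteins))
  if (is.null(planted_sets)) {
    planted_sets <- list(planted_pathway = protein_ids[seq_len(min(20, n_proteins))])
  }
  if (is.null(planted_effects)) {
    planted_effects <- stats::setNames(
      rep(list(1.0), length(planted_sets)), names(planted_sets))
  }
  # per-condition effect vectors, filled out from scalars
  planted_effects <- lapply(planted_effects, function(e) {
    if (length(e) == 1L && is.null(names(e))) {
      e <- stats::setNames(rep(as.numeric(e), length(conditions)),
                           names(conditions))
    }
    if (!all(names(e) %in% names(conditions))) {
      stop("planted effect names a condition absent from 'conditions'")
    }
    e
  })
  if (!all(names(planted_effects) %in% names(planted_sets)) &&
      !is.null(pathway_sets)) {
    if (!all(names(planted_effects) %in% names(pathway_sets))) {
      stop("planted effect references an unknown set")
    }
  }
  unknown <- setdiff(unique(unlist(c(pathway_sets, planted_sets))),
                     protein_ids)
  if (length(unknown)) {
    stop("pathway set references unknown protein ID: ", unknown[1L])
  }
  structure(list(
    n_proteins = n_proteins, protein_ids = protein_ids,
    conditions = conditions,
    n_replicates_per_arm = as.integer(n_replicates_per_arm),
    pathway_sets = pathway_sets, n_sets = n_sets,
    set_size_range = set_size_range,
    planted_sets = planted_sets, planted_effects = planted_effects,
    noise_sd = noise_sd, prior_d0 = prior_d0, prior_s0_sq = prior_s0_sq,
    missing_rate_mcar = missing_rate_mcar,
    mnar_intensity_quantile = mnar_intensity_quantile,
    phenotype_rho = phenotype_rho, n_subjects = as.integer(n_subjects),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)), class = "SimConfig")
}

# Sub-stream seeds: one global seed per study, fixed offsets per component.
sub_seed <- function(config, offset) {
  (config$seed + offset) %% .Machine$integer.max
}

# Random pathway collection: the planted sets first, then sets drawn
# uniformly from the protein universe.
make_pathway_collection <- function(config) {
  if (!is.null(config$pathway_sets)) {
    sets <- config$pathway_sets
    for (nm in names(config$planted_sets)) {
      if (is.null(sets[[nm]])) sets[[nm]] <- config$planted_sets[[nm]]
    }
    return(sets)
  }
  set.seed(sub_seed(config, 500L))
  n_random <- max(0L, config$n_sets - length(config$planted_sets))
  sizes <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                  n_random, replace = TRUE)
  sizes <- pmin(sizes, config$n_proteins - 1L)
  random_sets <- lapply(sizes, function(sz) {
    sort(sample(config$protein_ids, sz))
  })
  names(random_sets) <- sprintf("set_%03d", seq_len(n_random))
  c(config$planted_sets, random_sets)
}

# Per-protein planted log2 effect for one condition.
condition_effects <- function(config, condition) {
  eff <- stats::setNames(numeric(config$n_proteins), config$protein_ids)
  for (nm in names(config$planted_effects)) {
    e <- config$planted_effects[[nm]][condition]
    if (!is.na(e) && e != 0) {
      members <- config$planted_sets[[nm]] %||%
        config$pathway_sets[[nm]]
      eff[members] <- eff[members] + e
    }
  }
  eff
}

#' Simulate a multi-condition proteome panel with planted effects
#'
#' For each condition contrast, control and treated replicate columns are
#' drawn as Normal(baseline + effect, sigma_g) with per-protein variances
#' sigma_g^2 ~ d0 * s0^2 / chisq(d0) (scaled inverse-chi-square). Members of
#' planted sets share the configured coherent effect in the treated group.
#' Missingness is then applied: censoring below the per-sample intensity
#' quantile (a detection-limit stand-in), then missing-completely-at-random
#' at the configured rate.
#'
#' @param config A [sim_config()].
#' @return A list of class `SimStudy`: `matrices` (one `ExpressionMatrix`
#'   per condition, groups `control`/`treated`), `sets` (pathway
#'   collection), `truth_de` (proteins x conditions matrix of true log2
#'   effects), `truth_pathway` (planted set names), `arms` (condition ->
#'   arm), `config`.
#' @export
simulate_proteome_panel <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sets <- make_pathway_collection(config)
  G <- config$n_proteins
  nrep <- config$n_replicates_per_arm
  set.seed(sub_seed(config, 100L))
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  names(baseline) <- config$protein_ids
  matrices <- list()
  truth_de <- matrix(0, G, length(config$conditions),
                     dimnames = list(config$protein_ids,
                                     names(config$conditions)))
  for (i in seq_along(config$conditions)) {
    cond <- names(config$conditions)[i]
    set.seed(sub_seed(config, 1000L + i))
    sigma_sq <- config$prior_d0 * config$prior_s0_sq /
      stats::rchisq(G, df = config$prior_d0)
    eff <- condition_effects(config, cond)
    truth_de[, cond] <- eff
    n_col <- 2L * nrep
    vals <- matrix(stats::rnorm(G * n_col), G, n_col) * sqrt(sigma_sq) +
      baseline
    vals[, (nrep + 1L):n_col] <- vals[, (nrep + 1L):n_col] + eff
    colnames(vals) <- c(sprintf("%s_ctrl_%d", cond, seq_len(nrep)),
                        sprintf("%s_trt_%d", cond, seq_len(nrep)))
    rownames(vals) <- config$protein_ids
    # MNAR: censor below the per-sample intensity quantile
    if (config$mnar_intensity_quantile > 0) {
      for (j in seq_len(n_col)) {
        cut <- stats::quantile(vals[, j], config$mnar_intensity_quantile)
        vals[vals[, j] < cut, j] <- NA
      }
    }
    # MCAR on top
    if (config$missing_rate_mcar > 0) {
      drop <- matrix(stats::runif(G * n_col) < config$missing_rate_mcar,
                     G, n_col)
      vals[drop] <- NA
    }
    matrices[[cond]] <- expression_matrix(
      vals, rep(c("control", "treated"), each = nrep))
  }
  structure(list(matrices = matrices, sets = sets, truth_de = truth_de,
                 truth_pathway = names(config$planted_sets),
                 arms = config$conditions, config = config),
            class = "SimStudy")
}

#' Simulate a clinical cohort with a planted pathway-trait correlation
#'
#' Subjects carry a latent insulin-sensitivity factor f ~ N(0, 1). Proteins
#' in the (first) planted set load on f with a coefficient chosen so that
#' the pathway score (sum of relative ratios over the set's members)
#' correlates with f — and hence with any trait affine in f — at the
#' configured rho in expectation. The trait table contains an
#' f-derived insulin-sensitivity trait (`NEFA_suppression_pct`) plus null
#' traits (`age_years`, `BMI_kg_m2`) independent of f. One designated
#' low-noise protein (`P_REF`, sd 0.01) emulates a highly rank-stable
#' housekeeping reference so reference normalisation has a well-defined
#' target.
#'
#' @param config A [sim_config()].
#' @return List of class `SimCohort`: `intensities` (an `ExpressionMatrix`
#'   of log2 intensities, proteins x subjects, including `P_REF`), `traits`
#'   (subjects x traits data.frame), `truth_rho` (named planted correlation
#'   per trait), `latent` (the factor f), `planted_set` (member IDs).
#' @export
simulate_clinical_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(sub_seed(config, 2000L))
  n <- config$n_subjects
  G <- config$n_proteins
  subj <- sprintf("S%02d", seq_len(n))
  f <- stats::rnorm(n)
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  planted <- config$planted_sets[[1L]]
  m <- length(planted)
  rho <- config$phenotype_rho
  sigma <- config$noise_sd
  # loading such that cor(pathway sum, f) = rho in expectation
  load_c <- sign(rho) * (sigma / sqrt(m)) * abs(rho) / sqrt(1 - rho^2)
  loads <- stats::setNames(numeric(G), config$protein_ids)
  loads[planted] <- load_c
  vals <- baseline + outer(loads, f) +
    matrix(stats::rnorm(G * n, sd = sigma), G, n)
  rownames(vals) <- config$protein_ids
  # Low-noise housekeeping reference protein, placed above the abundance
  # range so its within-sample rank is constant and it wins the
  # higher-median-intensity tie-break among rank-stable candidates.
  ref_row <- matrix(config$baseline_mean + 8 * config$baseline_sd +
                      stats::rnorm(n, sd = 0.01), 1L, n)
  vals <- rbind(vals, ref_row)
  rownames(vals)[G + 1L] <- "P_REF"
  colnames(vals) <- subj
  intensities <- expression_matrix(vals, rep("cohort", n))
  traits <- data.frame(
    row.names = subj,
    NEFA_suppression_pct = 88 + 6 * f,
    age_years = round(50 + 8 * stats::rnorm(n)),
    BMI_kg_m2 = 34 + 3 * stats::rnorm(n)
  )
  structure(list(intensities = intensities, traits = traits,
                 truth_rho = c(NEFA_suppression_pct = rho,
                               age_years = 0, BMI_kg_m2 = 0),
                 latent = stats::setNames(f, subj),
                 planted_set = planted),
            class = "SimCohort")
}

#' Write a simulated study to disk and read it back
#'
#' Writes each condition matrix as TSV, the pathway collection as GMT, the
#' cohort intensity and trait tables as TSV, the ground truth as JSON, and
#' a JSON manifest listing every file.
#'
#' @param study A `SimStudy` ([simulate_proteome_panel()]).
#' @param directory Output directory (created if needed).
#' @param cohort Optional `SimCohort` to include.
#' @return The manifest (named list of relative paths), invisibly written as
#'   `manifest.json`.
#' @export
write_fixture_set <- function(study, directory, cohort = NULL) {
  stopifnot(inherits(study, "SimStudy"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  manifest <- list(matrices = list(), sets = "sets.gmt",
                   truth = "truth.json")
  for (cond in names(study$matrices)) {
    fn <- sprintf("matrix_%s.tsv", cond)
    write_expression_tsv(study$matrices[[cond]], file.path(directory, fn))
    manifest$matrices[[cond]] <- fn
  }
  write_gmt(study$sets, file.path(directory, "sets.gmt"))
  truth <- list(truth_pathway = study$truth_pathway,
                arms = as.list(study$arms),
                truth_de = as.data.frame(study$truth_de))
  if (!is.null(cohort)) {
    write_expression_tsv(cohort$intensities,
                         file.path(directory, "cohort_intensities.tsv"))
    utils::write.table(
      cbind(subject_id = rownames(cohort$traits), cohort$traits),
      file.path(directory, "cohort_traits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$cohort_intensities <- "cohort_intensities.tsv"
    manifest$cohort_traits <- "cohort_traits.tsv"
    truth$truth_rho <- as.list(cohort$truth_rho)
  }
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
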