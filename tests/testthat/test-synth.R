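test_that("identical config and seed give identical studies and cohorts", {
  cfg <- sim_config(n_proteins = 300, seed = 5,
                    planted_sets = list(pp = sprintf("P%04d", 1:10)))
  s1 <- simulate_proteome_panel(cfg)
  s2 <- simulate_proteome_panel(cfg)
  expect_identical(s1$matrices, s2$matrices)
  expect_identical(s1$truth_de, s2$truth_de)
  expect_identical(s1$sets, s2$sets)
  c1 <- simulate_clinical_cohort(cfg)
  c2 <- simulate_clinical_cohort(cfg)
  expect_identical(c1$intensities$values, c2$intensities$values)
  expect_identical(c1$traits, c2$traits)
  # a different seed changes the data
  cfg2 <- sim_config(n_proteins = 300, seed = 6,
                     planted_sets = list(pp = sprintf("P%04d", 1:10)))
  expect_false(identical(simulate_proteome_panel(cfg2)$matrices,
                         s1$matrices))
})

test_that("configuration errors are caught up front", {
  expect_error(sim_config(planted_sets = list(pp = c("P0001", "NOPE"))),
               "unknown protein")
  expect_error(sim_config(phenotype_rho = 1), "phenotype_rho")
  expect_error(sim_config(missing_rate_mcar = 1.4), "rates")
  expect_error(sim_config(n_subjects = 2), "counts")
  expect_error(sim_config(conditions = c("cell", "cell")), "named")
})

test_that("planted effects land on the planted members and nowhere else", {
  members <- sprintf("P%04d", 11:25)
  cfg <- sim_config(n_proteins = 200, seed = 9,
                    planted_sets = list(pp = members),
                    planted_effects = list(pp = c(CI = 0.8, Dex = -0.5)),
                    missing_rate_mcar = 0, mnar_intensity_quantile = 0)
  study <- simulate_proteome_panel(cfg)
  expect_equal(unname(study$truth_de[members, "CI"]), rep(0.8, 15))
  expect_equal(unname(study$truth_de[members, "Dex"]), rep(-0.5, 15))
  expect_true(all(study$truth_de[members, "TNF"] == 0))
  expect_true(all(study$truth_de[!rownames(study$truth_de) %in% members, ]
                  == 0))
  # the treated-minus-control means reflect the planted effect
  m <- study$matrices$CI
  fc <- rowMeans(m$values[, m$groups == "treated"]) -
    rowMeans(m$values[, m$groups == "control"])
  expect_equal(mean(fc[members]), 0.8, tolerance = 0.15)
  expect_equal(mean(fc[!names(fc) %in% members]), 0, tolerance = 0.05)
})

test_that("marginal missingness matches the configured MCAR rate", {
  cfg <- sim_config(n_proteins = 2000, seed = 21,
                    missing_rate_mcar = 0.10,
                    mnar_intensity_quantile = 0)
  study <- simulate_proteome_panel(cfg)
  rate <- mean(sapply(study$matrices,
                      function(m) mean(is.na(m$values))))
  expect_lt(abs(rate - 0.10), 0.01)
  # censoring removes the low-intensity tail
  cfg2 <- sim_config(n_proteins = 2000, seed = 21,
                     missing_rate_mcar = 0, mnar_intensity_quantile = 0.05)
  m2 <- simulate_proteome_panel(cfg2)$matrices[[1]]
  expect_equal(mean(is.na(m2$values)), 0.05, tolerance = 0.005)
  # censoring is bottom-of-column: within each sample, every missing row
  # sits below every observed one is not checkable post hoc, but each
  # column must lose close to its configured quantile
  col_rate <- colMeans(is.na(m2$values))
  expect_true(all(abs(col_rate - 0.05) < 0.01))
})

test_that("null panels yield uniform moderated-t p-values", {
  cfg <- null_config(n_proteins = 2000, seed = 31)
  study <- simulate_proteome_panel(cfg)
  res <- moderated_t_test(study$matrices[[1]], c("treated", "control"))
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("the planted cohort correlation is realised near the configured rho", {
  # median observed |r| across seeds clears the n = 22 critical value
  rs <- sapply(1:60, function(s) {
    cfg <- sim_config(n_proteins = 150, seed = 1000 + s,
                      phenotype_rho = 0.8,
                      planted_sets = list(pp = sprintf("P%04d", 1:20)))
    co <- simulate_clinical_cohort(cfg)
    rel <- relative_ratios(co$intensities)
    sc <- pathway_sample_score(rel, list(pp = co$planted_set))
    cor(sc["pp", ], co$traits$NEFA_suppression_pct)
  })
  expect_gt(median(abs(rs)), critical_r(22, 0.05))
  expect_equal(median(rs), 0.8, tolerance = 0.15)
})

test_that("fixture sets round-trip through disk", {
  cfg <- sim_config(n_proteins = 120, seed = 77, n_sets = 8,
                    planted_sets = list(pp = sprintf("P%04d", 1:12)),
                    n_subjects = 8)
  study <- simulate_proteome_panel(cfg)
  cohort <- simulate_clinical_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(study, dir, cohort = cohort)
  expect_length(manifest$matrices, length(study$matrices))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # matrices read back bit-identically (values, NA pattern, groups)
  for (cond in names(study$matrices)) {
    back <- read_expression_tsv(file.path(dir, manifest$matrices[[cond]]))
    expect_equal(back$values, study$matrices[[cond]]$values,
                 tolerance = 1e-12)
    expect_identical(back$groups, study$matrices[[cond]]$groups)
  }
  # GMT read-back reproduces the pathway sets exactly
  back_sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_equal(unclass(back_sets)[names(study$sets)], study$sets,
               ignore_attr = TRUE)
  # truth JSON records the planted set
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$truth_pathway, "pp")
  # writing the same study twice gives byte-identical files
  dir2 <- withr::local_tempdir()
  write_fixture_set(study, dir2, cohort = cohort)
  for (fn in c("matrix_CI.tsv", "sets.gmt")) {
    expect_identical(readLines(file.path(dir, fn)),
                     readLines(file.path(dir2, fn)))
  }
})
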