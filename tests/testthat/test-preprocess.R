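test_that("group-missing filter removes a feature only when every group crosses the threshold", {
  vals <- rbind(
    all_bad   = c(NA, NA, NA, 1, 2, NA, NA, NA, 1, 2),  # 60% missing in both
    one_good  = c(NA, NA, NA, 1, 2, 1, 2, 3, 4, 5),     # 60% in g1 only
    forty_pct = c(NA, NA, 1, 2, 3, NA, NA, 1, 2, 3),    # 40% in both
    complete  = rnorm(10)
  )
  colnames(vals) <- sprintf("s%d", 1:10)
  m <- expression_matrix(vals, rep(c("g1", "g2"), each = 5))

  out <- filter_group_missing(m, threshold = 0.60)
  expect_setequal(rownames(out$values), c("one_good", "forty_pct", "complete"))
  expect_equal(attr(out, "n_removed"), 1L)
  # retained rows are unchanged
  expect_identical(out$values["complete", ], vals["complete", ])

  # strict any-group mode also drops the feature bad in one group
  out_any <- filter_group_missing(m, threshold = 0.60, mode = "any")
  expect_setequal(rownames(out_any$values), c("forty_pct", "complete"))

  expect_error(filter_group_missing(m, threshold = 1.2), "threshold")
  expect_error(
    filter_group_missing(expression_matrix(vals[0, , drop = FALSE],
                                           m$groups)),
    "empty")
})

test_that("filter is monotone in the threshold", {
  set.seed(11)
  vals <- matrix(rnorm(600), 60, 10,
                 dimnames = list(sprintf("F%02d", 1:60),
                                 sprintf("s%d", 1:10)))
  vals[runif(600) < 0.45] <- NA
  vals[rowSums(!is.na(vals)) == 0, 1] <- 0   # keep at least one value per row
  m <- expression_matrix(vals, rep(c("a", "b"), each = 5))
  kept <- lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    rownames(filter_group_missing(m, threshold = th)$values)
  })
  # raising the threshold only ever retains more features
  for (i in seq_len(length(kept) - 1L)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1L]]))
  }
})

test_that("KNN imputation averages the k nearest co-observed rows", {
  # hand example: B and C are at distance 0 from A; D is far
  vals <- rbind(A = c(1, 2, NA), B = c(1, 2, 4), C = c(1, 2, 6),
                D = c(9, 9, 9))
  colnames(vals) <- sprintf("s%d", 1:3)
  m <- expression_matrix(vals, rep("g", 3))
  out <- knn_impute(m, k = 2)
  expect_equal(out$values["A", "s3"], 5)
  expect_equal(attr(out, "n_imputed"), 1L)
  # observed cells untouched
  expect_identical(out$values[-1, ], vals[-1, ])

  # a zero-distance duplicate with k = 1 copies the duplicate's value
  out1 <- knn_impute(m, k = 1)
  expect_true(out1$values["A", "s3"] %in% c(4, 6))

  # complete matrix passes through unchanged (idempotence)
  cm <- tiny_matrix()
  expect_identical(knn_impute(cm, k = 5)$values, cm$values)

  bad <- rbind(A = c(NA_real_, NA_real_), B = c(1, 2))
  colnames(bad) <- c("s1", "s2")
  expect_error(knn_impute(expression_matrix(bad, c("g", "g"))),
               "all-missing")
})

test_that("imputed values lie within the neighbours' range", {
  set.seed(7)
  vals <- matrix(rnorm(400, 20), 40, 10,
                 dimnames = list(sprintf("F%02d", 1:40),
                                 sprintf("s%d", 1:10)))
  miss <- matrix(runif(400) < 0.15, 40, 10)
  vals_na <- vals; vals_na[miss] <- NA
  m <- expression_matrix(vals_na, rep(c("a", "b"), each = 5))
  out <- knn_impute(m, k = 5)
  expect_false(anyNA(out$values))
  # every imputed value is inside the observed range of its column
  for (j in seq_len(10)) {
    obs_rng <- range(vals_na[, j], na.rm = TRUE)
    imp <- out$values[miss[, j], j]
    expect_true(all(imp >= obs_rng[1] & imp <= obs_rng[2]))
  }
})

test_that("stable-reference normalisation zeroes the most rank-stable feature", {
  set.seed(5)
  n <- 6
  vals <- rbind(
    noisy1 = 2^(20 + rnorm(n, sd = 0.8)),
    ref    = 2^(24 + rnorm(n, sd = 0.001)),   # constant top rank
    noisy2 = 2^(19 + rnorm(n, sd = 0.8)),
    noisy3 = 2^(21 + rnorm(n, sd = 0.8))
  )
  colnames(vals) <- sprintf("s%d", seq_len(n))
  m <- expression_matrix(vals, rep("g", n))
  out <- stable_reference_normalise(m)
  expect_identical(attr(out, "reference"), "ref")
  expect_equal(unname(out$values["ref", ]), rep(0, n))
  # within-sample ordering is preserved (monotone per-sample transform)
  for (j in seq_len(n)) {
    expect_identical(order(vals[, j]), order(out$values[, j]))
  }
})

test_that("reference ties break by higher median intensity then feature ID", {
  # two rows hold perfectly stable ranks; the more intense one wins
  vals <- rbind(low = c(2, 2, 2), high = c(8, 8, 8), mid = c(4, 4, 4))
  colnames(vals) <- sprintf("s%d", 1:3)
  m <- expression_matrix(vals, rep("g", 3))
  expect_identical(attr(stable_reference_normalise(m), "reference"), "high")
  # equal medians too: lexical feature ID decides
  vals2 <- rbind(bb = c(4, 4, 4), aa = c(4, 4, 4), cc = c(2, 2, 2))
  colnames(vals2) <- sprintf("s%d", 1:3)
  m2 <- expression_matrix(vals2, rep("g", 3))
  expect_identical(attr(stable_reference_normalise(m2), "reference"), "aa")

  na_vals <- vals; na_vals[cbind(1:3, 1:3)] <- NA
  expect_error(stable_reference_normalise(
    expression_matrix(na_vals, rep("g", 3))), "fully observed")
})

test_that("relative ratios centre every row exactly", {
  vals <- rbind(a = c(4, 6), b = c(5, 5), c = c(-1, 3))
  colnames(vals) <- c("s1", "s2")
  m <- expression_matrix(vals, c("g", "g"))
  out <- relative_ratios(m)
  expect_equal(unname(out$values["a", ]), c(-1, 1))
  expect_equal(unname(out$values["b", ]), c(0, 0))
  expect_true(all(abs(rowSums(out$values)) < 1e-9))
  vals[1, 1] <- NA
  expect_error(relative_ratios(expression_matrix(vals, c("g", "g"))),
               "impute")
})
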