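test_that("a degenerate spread of variances gives an infinite-shrinkage prior", {
  pr <- estimate_prior(rep(0.3, 50), df = 4)
  expect_equal(pr$d0, 1e6)
  expect_equal(pr$s0_sq, 0.3)
  expect_error(estimate_prior(rep(0, 10), df = 4), "zero")
})

test_that("prior estimation recovers (d0, s0_sq) from variances drawn from the prior", {
  set.seed(301)
  G <- 5000; d0 <- 4; s0 <- 1; dg <- 4
  sigma_sq <- d0 * s0 / rchisq(G, df = d0)       # scaled inverse-chi-square
  s_sq <- sigma_sq * rchisq(G, df = dg) / dg     # sampling layer
  pr <- estimate_prior(s_sq, df = dg)
  expect_lt(abs(pr$d0 - d0) / d0, 0.20)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)
})

test_that("dispersed variances give a finite d0 matching a brute-force moment solve", {
  s_sq <- c(0.1, 10); dg <- 4
  pr <- estimate_prior(s_sq, df = dg)
  expect_true(is.finite(pr$d0) && pr$d0 < 1e6 && pr$d0 > 0)
  # independent 1-D search on the trigamma moment equation
  e <- log(s_sq) - digamma(dg / 2) + log(dg / 2)
  evar <- sum((e - mean(e))^2) / 1 - trigamma(dg / 2)
  obj <- function(d0) (trigamma(d0 / 2) - evar)^2
  d0_grid <- 10^seq(-3, 2, length.out = 200001)
  d0_brute <- d0_grid[which.min(obj(d0_grid))]
  expect_equal(pr$d0, d0_brute, tolerance = 1e-3)
})

test_that("moderated t with d0 = 0 reproduces the classical pooled t by hand", {
  vals <- rbind(f1 = c(1, 2, 3, 3, 4, 5))
  colnames(vals) <- sprintf("s%d", 1:6)
  m <- expression_matrix(vals, rep(c("ctrl", "trt"), each = 3))
  res <- moderated_t_test(m, c("ctrl", "trt"),
                          prior = list(d0 = 0, s0_sq = 1))
  expect_equal(res$log_fc, -2)
  expect_equal(res$s_sq, 1)
  expect_equal(res$t_mod, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df_total, 4)
})

test_that("moderated t with d0 = 0 equals the classical pooled two-sample t", {
  set.seed(77)
  for (i in 1:500) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    vals <- matrix(c(a, b), 1,
                   dimnames = list("f1", sprintf("s%d", seq_len(n1 + n2))))
    m <- expression_matrix(vals, rep(c("g1", "g2"), c(n1, n2)))
    res <- moderated_t_test(m, c("g1", "g2"),
                            prior = list(d0 = 0, s0_sq = 1))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t_mod, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(88)
  m <- tiny_matrix(n_features = 200, n_per_group = 4)
  design <- cbind(1, as.integer(m$groups == "treated"))
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  res <- moderated_t_test(m, c("treated", "control"))
  pr <- attr(res, "prior")
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("shrinkage behaves at the limits and in between", {
  m <- tiny_matrix(n_features = 50, n_per_group = 4)
  # infinite shrinkage: every posterior variance is the prior scale
  res_inf <- moderated_t_test(m, c("treated", "control"),
                              prior = list(d0 = 1e6, s0_sq = 0.25))
  expect_true(all(abs(res_inf$s_tilde_sq - 0.25) < 1e-4))
  # equal group means give t = 0, p = 1
  vals <- rbind(f1 = c(1, 2, 3, 2, 1, 3))
  colnames(vals) <- sprintf("s%d", 1:6)
  mm <- expression_matrix(vals, rep(c("a", "b"), each = 3))
  res0 <- moderated_t_test(mm, c("a", "b"), prior = list(d0 = 2, s0_sq = 1))
  expect_equal(res0$t_mod, 0)
  expect_equal(res0$p, 1)
  # posterior variance lies between the sample variance and the prior scale
  res <- moderated_t_test(m, c("treated", "control"),
                          prior = list(d0 = 3, s0_sq = 0.1))
  lo <- pmin(res$s_sq, 0.1); hi <- pmax(res$s_sq, 0.1)
  expect_true(all(res$s_tilde_sq >= lo - 1e-12 &
                    res$s_tilde_sq <= hi + 1e-12))
  expect_error(moderated_t_test(
    expression_matrix(matrix(rnorm(3), 1,
                             dimnames = list("f", c("a", "b", "c"))),
    c("g1", "g1", "g2")), ">= 2 samples"))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(9)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE calls require both the fold-change and the FDR threshold", {
  res <- data.frame(log_fc = c(0.7, 0.5, 1.0, -0.8),
                    adj_p = c(0.03, 0.001, 0.06, 0.04))
  out <- call_de(res)
  expect_identical(out$is_de, c(TRUE, FALSE, FALSE, TRUE))
})
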