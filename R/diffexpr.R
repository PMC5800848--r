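# Empirical-Bayes moderated t-tests for two-group contrasts.
#
# The variance model: per-feature true variances sigma_g^2 follow a scaled
# inverse-chi-square prior with d0 degrees of freedom and scale s0^2; the
# observed residual variance s_g^2 is then scaled chi-square about sigma_g^2
# with d_g degrees of freedom. Moment matching on log s_g^2 via
# digamma/trigamma identities yields (d0, s0^2); the posterior variance
# shrinks each s_g^2 toward s0^2 and buys d0 extra degrees of freedom.

# d0 at or above this cap is treated as infinite shrinkage.
D0_CAP <- 1e6

# Invert the trigamma function by Newton iteration.
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y <= 0) stop("trigamma is positive; cannot invert non-positive value")
  if (y > 1e7) return(1 / sqrt(y))        # trigamma(x) ~ 1/x^2 for small x
  if (y < 1e-6) return(1 / y)             # trigamma(x) ~ 1/x   for large x
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Fits a scaled inverse-chi-square prior (d0 degrees of freedom, scale s0^2)
#' to per-feature residual sample variances, matching the mean and spread of
#' log s_g^2 using digamma/trigamma identities and inverting the trigamma
#' equation numerically. When the empirical spread of log variances does not
#' exceed what chi-square sampling alone implies, the prior is degenerate:
#' d0 is capped at 1e6 (treated as infinite) and s0^2 is the pooled variance.
#'
#' @param s_sq Per-feature residual sample variances.
#' @param df Residual degrees of freedom, length 1 or same length as `s_sq`.
#' @return List with elements `d0` and `s0_sq` (class `EBayesParams`).
#' @export
estimate_prior <- function(s_sq, df) {
  if (length(df) == 1L) df <- rep(df, length(s_sq))
  stopifnot(length(df) == length(s_sq))
  keep <- is.finite(s_sq) & s_sq > 0 & df >= 1
  if (sum(s_sq[is.finite(s_sq)], na.rm = TRUE) == 0) {
    stop("all variances are zero")
  }
  if (sum(keep) < 2L) stop("need at least 2 positive variances with df >= 1")
  s2 <- s_sq[keep]
  d  <- df[keep]
  # e_g is an unbiased estimate of log(sigma_g^2) plus the prior offset
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  e_bar <- mean(e)
  G <- length(e)
  evar <- sum((e - e_bar)^2) / (G - 1L) - mean(trigamma(d / 2))
  if (evar <= 0) {
    d0 <- D0_CAP
    s0_sq <- sum(d * s2) / sum(d)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 >= D0_CAP) {
      d0 <- D0_CAP
      s0_sq <- sum(d * s2) / sum(d)
    } else {
      s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "EBayesParams")
}

#' Moderated two-group t-test
#'
#' For each feature, the two-group log2 fold change (treated minus control)
#' is tested with the pooled residual variance shrunk toward the prior:
#' s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), t = log_fc /
#' (s_tilde * sqrt(1/n1 + 1/n2)), two-sided p from the t distribution on
#' d0 + d_g degrees of freedom. With `prior = NULL` the prior is estimated
#' from the data; with d0 = 0 the test reduces to the classical pooled
#' two-sample t.
#'
#' @param m An `ExpressionMatrix` (complete for the two groups tested).
#' @param contrast Character vector `c(treated, control)` naming two groups.
#' @param prior An `EBayesParams` list, or `NULL` to estimate from the data.
#' @return A data.frame (one row per feature): `feature_id`, `log_fc`,
#'   `s_sq`, `df_residual`, `s_tilde_sq`, `t_mod`, `df_total`, `p`, `adj_p`,
#'   `is_de` (the last two `NA` until [bh_adjust()] / [call_de()] run; this
#'   function fills `adj_p` for convenience).
#' @export
moderated_t_test <- function(m, contrast, prior = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(contrast) == 2L)
  g1 <- m$groups == contrast[1L]   # treated
  g2 <- m$groups == contrast[2L]   # control
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) {
    stop("both contrast groups need >= 2 samples")
  }
  x1 <- m$values[, g1, drop = FALSE]
  x2 <- m$values[, g2, drop = FALSE]
  if (anyNA(x1) || anyNA(x2)) stop("missing values present; impute first")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log_fc <- m1 - m2
  df_res <- n1 + n2 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s_sq <- ss / df_res
  if (is.null(prior)) prior <- estimate_prior(s_sq, df_res)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (d0 > 0) {
    s_tilde_sq <- (d0 * s0_sq + df_res * s_sq) / (d0 + df_res)
  } else {
    s_tilde_sq <- s_sq
  }
  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- log_fc / se
  undefined <- se == 0
  t_mod[undefined & log_fc == 0] <- 0
  df_total <- min(d0, D0_CAP) + df_res
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  res <- data.frame(
    feature_id = rownames(m$values),
    log_fc = log_fc,
    s_sq = s_sq,
    df_residual = df_res,
    s_tilde_sq = s_tilde_sq,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    adj_p = bh_adjust(p),
    is_de = NA,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "prior") <- prior
  attr(res, "contrast") <- sprintf("log_fc = mean(%s) - mean(%s)",
                                   contrast[1L], contrast[2L])
  if (any(undefined & log_fc != 0)) {
    attr(res, "undefined_t") <- which(undefined & log_fc != 0)
  }
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression by fold change and FDR
#'
#' A feature is differentially expressed when its absolute linear fold
#' change exceeds `fc_threshold` and its BH-adjusted p-value is below `fdr`.
#'
#' @param results Data.frame from [moderated_t_test()] with `adj_p` filled.
#' @param fc_threshold Linear fold-change cutoff (default 1.5, i.e. |log2
#'   FC| > log2(1.5)).
#' @param fdr FDR cutoff (default 0.05).
#' @return `results` with the logical `is_de` column populated.
#' @export
call_de <- function(results, fc_threshold = 1.5, fdr = 0.05) {
  stopifnot(is.data.frame(results), all(c("log_fc", "adj_p") %in%
                                          names(results)))
  results$is_de <- (2^abs(results$log_fc) > fc_threshold) &
    (results$adj_p < fdr)
  results
}
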