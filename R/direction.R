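# Direction analysis: per-condition moderated t-statistics are mapped to
# z-scores by quantile matching and a vector of z-scores across conditions
# is tested against a specified direction (e.g. "up in all models") by
# projection. Under the global null with independent conditions the
# projected statistic is standard normal.

#' Transform t-statistics to z-scores by quantile matching
#'
#' z = Phi^-1(F_t(t; df)), computed tail-stably on the log scale so extreme
#' statistics keep their ordering, then clamped at +/- 8.2 where the normal
#' quantile saturates in double precision.
#'
#' @param t_mod Moderated t-statistics (finite).
#' @param df_total Degrees of freedom (> 0), scalar or per-statistic.
#' @return z-scores, sign-preserving and monotone in `t_mod`.
#' @export
t_to_z <- function(t_mod, df_total) {
  if (any(!is.finite(t_mod))) stop("non-finite t statistic")
  if (any(df_total <= 0)) stop("df_total must be > 0")
  # work in the upper tail of |t| for numerical stability
  log_upper <- stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE,
                         log.p = TRUE)
  z <- qnorm_upper_log(log_upper)
  clamp_z(sign(t_mod) * z)
}

#' Project a z-score vector onto a direction
#'
#' The combination rule is the Stouffer-type projection `stat = sum(z * d)`
#' for a unit direction `d`; under the global null with independent
#' conditions the statistic is standard normal and the one-sided p-value is
#' its upper-tail probability.
#'
#' @param z Numeric vector of per-condition z-scores.
#' @param d Direction vector, same length; normalised to unit length
#'   internally (a zero vector is an error).
#' @return List with `stat` (projection) and `p_one_sided`.
#' @export
direction_test <- function(z, d) {
  stopifnot(length(z) == length(d))
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("direction vector must be non-zero")
  d <- d / nd
  stat <- sum(z * d)
  list(stat = stat,
       p_one_sided = stats::pnorm(stat, lower.tail = FALSE))
}

#' Classify per-feature regulation across conditions
#'
#' A condition counts as significant when its two-sided p-value is below
#' `alpha`. A feature is "up" when at least `min_models` conditions are
#' significant and all significant ones have positive z; "down"
#' symmetrically; "mixed" when at least `min_models` are significant with
#' discordant signs; "unchanged" otherwise. Invariant to condition order.
#'
#' @param z Per-condition z-scores for one feature.
#' @param per_condition_p Per-condition two-sided p-values.
#' @param alpha Per-condition significance level (0.01 for proteins, 0.001
#'   for transcripts in the intended designs).
#' @param min_models Minimum number of significant conditions (default 2).
#' @return One of `"up"`, `"down"`, `"mixed"`, `"unchanged"`.
#' @export
classify_regulation <- function(z, per_condition_p, alpha = 0.01,
                                min_models = 2L) {
  stopifnot(length(z) == length(per_condition_p),
            alpha > 0, alpha < 1)
  sig <- per_condition_p < alpha
  if (sum(sig) < min_models) return("unchanged")
  signs <- sign(z[sig])
  if (all(signs > 0)) "up"
  else if (all(signs < 0)) "down"
  else "mixed"
}

#' Direction analysis over a matrix of z-scores
#'
#' Convenience wrapper applying [direction_test()] (against the all-up
#' diagonal by default) and [classify_regulation()] to every feature.
#'
#' @param z_mat Features x conditions matrix of z-scores.
#' @param p_mat Matching matrix of per-condition two-sided p-values; derived
#'   from `z_mat` if omitted.
#' @param d Direction vector (default the all-ones diagonal, normalised).
#' @param alpha Per-condition significance level for classification.
#' @param min_models Minimum significant conditions for a coherent call.
#' @return Data.frame: `feature_id`, one `z_<condition>` column per
#'   condition, `stat`, `p_one_sided`, `reg_class`.
#' @export
direction_analysis <- function(z_mat, p_mat = NULL, d = NULL, alpha = 0.01,
                               min_models = 2L) {
  stopifnot(is.matrix(z_mat), ncol(z_mat) >= 2L)
  if (is.null(p_mat)) {
    p_mat <- 2 * stats::pnorm(abs(z_mat), lower.tail = FALSE)
  }
  if (is.null(d)) d <- rep(1, ncol(z_mat))
  d <- d / sqrt(sum(d^2))
  stat <- as.vector(z_mat %*% d)
  reg <- vapply(seq_len(nrow(z_mat)), function(i) {
    classify_regulation(z_mat[i, ], p_mat[i, ], alpha = alpha,
                        min_models = min_models)
  }, character(1))
  out <- data.frame(
    feature_id = rownames(z_mat) %||% as.character(seq_len(nrow(z_mat))),
    z_mat,
    stat = stat,
    p_one_sided = stats::pnorm(stat, lower.tail = FALSE),
    reg_class = reg,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  names(out)[seq_len(ncol(z_mat)) + 1L] <-
    paste0("z_", colnames(z_mat) %||% seq_len(ncol(z_mat)))
  out
}
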