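#' Remove features with too many missing values per group
#'
#' A feature is removed when its fraction of missing values reaches
#' `threshold` within experimental groups. Two readings of "within each
#' group" are supported: `mode = "all"` (default) removes a feature only if
#' the missing fraction is >= `threshold` in every group, so a feature well
#' observed in at least one group survives; `mode = "any"` removes it as soon
#' as a single group crosses the threshold.
#'
#' @param m An [expression_matrix()].
#' @param threshold Missing-fraction cutoff in (0, 1]; the conventional
#'   proteomics value is 0.60.
#' @param mode `"all"` or `"any"`; which groups must cross the threshold for
#'   removal.
#' @return The filtered `ExpressionMatrix`; retained rows are unchanged.
#'   Attribute `n_removed` records the count removed.
#' @export
filter_group_missing <- function(m, threshold = 0.60,
                                 mode = c("all", "any")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]")
  }
  if (nrow(m$values) == 0L) stop("empty matrix")
  groups <- unique(m$groups)
  miss_frac <- sapply(groups, function(g) {
    cols <- m$groups == g
    rowMeans(is.na(m$values[, cols, drop = FALSE]))
  })
  miss_frac <- matrix(miss_frac, nrow = nrow(m$values),
                      dimnames = list(rownames(m$values), groups))
  hit <- miss_frac >= threshold
  remove <- if (mode == "all") apply(hit, 1L, all) else apply(hit, 1L, any)
  out <- expression_matrix(m$values[!remove, , drop = FALSE], m$groups)
  attr(out, "n_removed") <- sum(remove)
  out
}

#' K-nearest-neighbour imputation of missing values
#'
#' Each missing cell is replaced by the mean of the k nearest features'
#' observed values in that sample. Nearness between two feature rows is the
#' mean squared difference over their co-observed samples, so features with
#' different missingness patterns are comparable. Neighbours must be
#' observed in the sample being imputed. Features with no co-observed
#' samples against any candidate neighbour fall back to their own row mean.
#'
#' @param m An `ExpressionMatrix`, already filtered so no row is entirely
#'   missing.
#' @param k Number of neighbours (default 5).
#' @return The imputed `ExpressionMatrix` (complete). Attribute `n_imputed`
#'   records the number of cells filled.
#' @export
knn_impute <- function(m, k = 5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  x <- m$values
  if (!anyNA(x)) {
    out <- m
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("all-missing feature present; filter before imputing")
  }
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # Pairwise mean squared difference over co-observed samples, computed with
  # matrix products: sum (a-b)^2 = sum a^2 + sum b^2 - 2 sum ab, each sum
  # restricted to co-observed columns.
  need <- which(rowSums(!obs) > 0L)
  sq <- x0^2
  co_obs  <- obs[need, , drop = FALSE] %*% t(obs)              # counts
  cross   <- x0[need, , drop = FALSE] %*% t(x0)
  a2      <- sq[need, , drop = FALSE] %*% t(obs)
  b2      <- obs[need, , drop = FALSE] %*% t(sq)
  d2 <- (a2 + b2 - 2 * cross) / co_obs
  d2[co_obs == 0] <- Inf
  row_mean <- rowMeans(x, na.rm = TRUE)
  n_imputed <- 0L
  for (ii in seq_along(need)) {
    i <- need[ii]
    dist_i <- d2[ii, ]
    dist_i[i] <- Inf                       # a row is not its own neighbour
    ord <- order(dist_i)                   # one sort per row, reused per cell
    ord <- ord[is.finite(dist_i[ord])]
    for (j in which(!obs[i, ])) {
      nb <- ord[obs[ord, j]]
      if (length(nb) == 0L) {
        x[i, j] <- row_mean[i]
      } else {
        x[i, j] <- mean(x[nb[seq_len(min(k, length(nb)))], j])
      }
      n_imputed <- n_imputed + 1L
    }
  }
  out <- expression_matrix(x, m$groups)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Normalise intensities against the most rank-stable feature
#'
#' Within each sample, features are ranked by intensity (ascending, average
#' ranks for ties). The reference is the fully observed feature whose
#' within-sample rank varies least across samples (population variance of
#' ranks); ties are broken by higher median intensity, then by lexical
#' feature ID. Output values are log2 ratios of each feature to the
#' reference within each sample, so the reference row is exactly zero.
#'
#' @param m An `ExpressionMatrix` of raw (linear-scale) intensities, or of
#'   log2 intensities with `log2_input = TRUE`.
#' @param log2_input Are values already log2? If so the ratio is a
#'   subtraction.
#' @return An `ExpressionMatrix` of log2 ratios relative to the reference.
#'   Attribute `reference` names the chosen feature.
#' @export
stable_reference_normalise <- function(m, log2_input = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- m$values
  complete <- rowSums(is.na(x)) == 0L
  if (!any(complete)) stop("no fully observed feature to use as reference")
  rk <- apply(x, 2L, rank, ties.method = "average", na.last = "keep")
  pop_var <- function(v) mean((v - mean(v))^2)
  rank_var <- apply(rk, 1L, pop_var)
  rank_var[!complete] <- Inf
  med_int <- apply(x, 1L, stats::median, na.rm = TRUE)
  ord <- order(rank_var, -med_int, rownames(x))
  ref <- rownames(x)[ord[1L]]
  ref_vals <- x[ref, ]
  out_vals <- if (log2_input) {
    sweep(x, 2L, ref_vals, "-")
  } else {
    if (any(x <= 0, na.rm = TRUE) || any(ref_vals <= 0)) {
      stop("linear intensities must be positive; use log2_input = TRUE for log data")
    }
    sweep(log2(x), 2L, log2(ref_vals), "-")
  }
  out <- expression_matrix(out_vals, m$groups)
  attr(out, "reference") <- ref
  out
}

#' Centre each feature on its across-sample mean
#'
#' Converts normalised ratios to relative ratios: each row minus its mean
#' across all samples. Downstream pathway scores sum these per sample.
#'
#' @param m A complete `ExpressionMatrix` (impute first).
#' @return The row-centred `ExpressionMatrix`.
#' @export
relative_ratios <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (anyNA(m$values)) stop("missing values present; impute first")
  expression_matrix(m$values - rowMeans(m$values), m$groups)
}
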