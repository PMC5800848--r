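# Fisher's-method integration of per-condition pathway p-values into
# combined z-scores, and selection of pathways convergent across the cell
# and tissue arms.

#' Combine p-values by Fisher's method into a z-score
#'
#' X = -2 * sum(log p_i) follows chi-square with 2k degrees of freedom under
#' the null; the combined p-value is its upper tail and the combined z-score
#' is the upper-tail standard-normal quantile of that p, clamped at +/- 8.2.
#' Zero p-values are floored at 1e-300 with a warning.
#'
#' @param p_list Per-condition p-values in (0, 1].
#' @return List: `k`, `p_list`, `X`, `p_comb`, `z_comb`.
#' @export
fisher_combine_z <- function(p_list) {
  p <- as.numeric(p_list)
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p > 1)) stop("p-values must be in (0, 1]")
  if (any(p == 0)) {
    warning("zero p-value floored at 1e-300")
    p[p == 0] <- 1e-300
  }
  if (any(p < 0)) stop("p-values must be in (0, 1]")
  k <- length(p)
  X <- -2 * sum(log(p))
  log_p_comb <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE,
                              log.p = TRUE)
  p_comb <- exp(log_p_comb)
  z_comb <- clamp_z(qnorm_upper_log(log_p_comb))
  list(k = k, p_list = p, X = X, p_comb = p_comb, z_comb = z_comb)
}

#' Combined z-scores for a table of per-condition pathway p-values
#'
#' @param p_mat Sets x conditions matrix of enrichment p-values; rows with
#'   any `NA` get `NA` scores.
#' @return Data.frame: `set_name`, `k`, `X`, `p_comb`, `z_comb`.
#' @export
combine_pathway_scores <- function(p_mat) {
  stopifnot(is.matrix(p_mat), !is.null(rownames(p_mat)))
  rows <- lapply(seq_len(nrow(p_mat)), function(i) {
    p <- p_mat[i, ]
    if (anyNA(p)) {
      return(data.frame(set_name = rownames(p_mat)[i], k = NA_integer_,
                        X = NA_real_, p_comb = NA_real_, z_comb = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fc <- fisher_combine_z(p)
    data.frame(set_name = rownames(p_mat)[i], k = fc$k, X = fc$X,
               p_comb = fc$p_comb, z_comb = fc$z_comb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select pathways convergent across cell and tissue arms
#'
#' A pathway is selected when its combined z-score exceeds `z_threshold` in
#' both arms. The full pair table is returned for plotting (the z-z scatter
#' of pathways across arms).
#'
#' @param cell_scores,tissue_scores Data.frames with `set_name` and
#'   `z_comb` ([combine_pathway_scores()]), scored on a shared set universe.
#' @param z_threshold Combined z-score cutoff (default 4).
#' @return List: `selected` (set names, ordered by decreasing
#'   `min(z_cell, z_tissue)`) and `table` (data.frame `set_name`, `z_cell`,
#'   `z_tissue`, `min_z`, `selected`).
#' @export
convergence_select <- function(cell_scores, tissue_scores, z_threshold = 4) {
  shared <- intersect(cell_scores$set_name, tissue_scores$set_name)
  if (length(shared) == 0L &&
      (nrow(cell_scores) > 0L || nrow(tissue_scores) > 0L)) {
    stop("cell and tissue arms share no pathway (disjoint set universes)")
  }
  zc <- cell_scores$z_comb[match(shared, cell_scores$set_name)]
  zt <- tissue_scores$z_comb[match(shared, tissue_scores$set_name)]
  tab <- data.frame(set_name = shared, z_cell = zc, z_tissue = zt,
                    min_z = pmin(zc, zt),
                    selected = !is.na(zc) & !is.na(zt) &
                      zc > z_threshold & zt > z_threshold,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$min_z, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  list(selected = tab$set_name[tab$selected], table = tab)
}
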