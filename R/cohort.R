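# Cohort association stage: per-sample pathway scores, Pearson correlation
# screening against clinical phenotypes with an analytic significance
# threshold, tertile stratification, and Mann-Whitney group comparison.

#' Per-sample pathway scores from relative ratios
#'
#' For each pathway, the per-sample score is the sum of the relative ratios
#' (row-centred values) of all measured member proteins. Since each row sums
#' to zero across samples, so does each pathway score.
#'
#' @param relative An `ExpressionMatrix` of relative ratios
#'   ([relative_ratios()]).
#' @param sets Named list of member-ID vectors.
#' @return Sets x samples numeric matrix; a set with no measured members
#'   gets a row of `NA`. Attribute `coverage` gives measured-member counts.
#' @export
pathway_sample_score <- function(relative, sets) {
  stopifnot(inherits(relative, "ExpressionMatrix"))
  if (anyNA(relative$values)) stop("relative ratios must be complete")
  if (max(abs(rowMeans(relative$values))) > 1e-6) {
    stop("rows are not centred; call relative_ratios() first")
  }
  ids <- rownames(relative$values)
  scores <- t(vapply(sets, function(members) {
    hit <- ids %in% members
    if (!any(hit)) return(rep(NA_real_, ncol(relative$values)))
    colSums(relative$values[hit, , drop = FALSE])
  }, numeric(ncol(relative$values))))
  colnames(scores) <- colnames(relative$values)
  attr(scores, "coverage") <-
    vapply(sets, function(members) sum(ids %in% members), integer(1))
  scores
}

#' Critical Pearson correlation at a given significance level
#'
#' The two-sided critical value r* = t* / sqrt(t*^2 + n - 2) where t* is the
#' two-sided alpha critical value of the t distribution on n - 2 degrees of
#' freedom: |r| > r* is equivalent to the Pearson correlation test rejecting
#' at level alpha. For n = 22 subjects at alpha = 0.05 this gives 0.423.
#'
#' @param n Number of paired observations (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |r| threshold in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 4)) stop("need n >= 4")
  t_star <- stats::qt(1 - alpha / 2, df = n - 2)
  t_star / sqrt(t_star^2 + n - 2)
}

#' Pearson correlation screen between a measure and a phenotype
#'
#' Pairwise-complete Pearson correlation with the analytic significance
#' threshold [critical_r()] evaluated at the number of complete pairs.
#'
#' @param x,y Per-subject numeric vectors, aligned.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List: `n` (complete pairs), `r`, `critical_r`, `significant`.
#'   `r` is `NA` (flagged `significant = NA`) when either vector is
#'   constant over the complete pairs.
#' @export
phenotype_correlate <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4L) stop("need >= 4 complete pairs")
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(n = n, r = NA_real_, critical_r = critical_r(n, alpha),
                significant = NA))
  }
  r <- stats::cor(xs, ys)
  rc <- critical_r(n, alpha)
  list(n = n, r = r, critical_r = rc, significant = abs(r) > rc)
}

#' Correlation screen of every pathway score against every trait
#'
#' @param scores Sets x subjects matrix ([pathway_sample_score()]).
#' @param traits Subjects x traits data.frame or matrix, columns named.
#' @param alpha Two-sided level for the per-pair critical r.
#' @return Data.frame: `target`, `trait`, `n`, `r`, `critical_r`,
#'   `significant`.
#' @export
correlation_screen <- function(scores, traits, alpha = 0.05) {
  traits <- as.data.frame(traits)
  rows <- list()
  for (s in rownames(scores)) {
    for (tr in colnames(traits)) {
      res <- phenotype_correlate(scores[s, ], traits[[tr]], alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        target = s, trait = tr, n = res$n, r = res$r,
        critical_r = res$critical_r, significant = res$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Split subjects into an upper tertile and the lower two tertiles
#'
#' The high group is the top ceiling(n/3) subjects by value, so 33 subjects
#' split 11 high / 22 low. Ties spanning the boundary are resolved by stable
#' subject order (earlier subjects win the high slot), making the split
#' deterministic.
#'
#' @param values Named (or unnamed) per-subject measure, n >= 3.
#' @return List of index vectors `high` and `low` (positions in `values`).
#' @export
tertile_stratify <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(values))) stop("values must be finite")
  n_high <- ceiling(n / 3)
  # order by decreasing value; ties keep original (stable) subject order
  ord <- order(-values, seq_len(n))
  high <- sort(ord[seq_len(n_high)])
  low <- sort(ord[-seq_len(n_high)])
  list(high = high, low = low)
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings:
# p = 2 * min(one-sided tails) capped at 1.
mann_whitney_exact <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled, ties.method = "average")
  na <- length(a)
  Ra <- sum(rk[seq_len(na)])
  sums <- utils::combn(rk, na, sum)
  p_low <- mean(sums <= Ra + 1e-9)
  p_high <- mean(sums >= Ra - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

#' Mann-Whitney (Wilcoxon rank-sum) two-group comparison
#'
#' Exact p by full enumeration of labelings when the pooled size is at most
#' `exact_max` (default 16); normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param a,b Group value vectors (non-empty).
#' @param exact_max Pooled-size limit for the exact path.
#' @return List: `U` (Mann-Whitney U for group `a`), `p_two_sided`,
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 16L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b), ties.method = "average")
  Ra <- sum(rk[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  if (na + nb <= exact_max) {
    p <- mann_whitney_exact(a, b)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(rk)
    n <- na + nb
    v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      zz <- (abs(U - mu) - 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(zz, lower.tail = FALSE))
    }
    method <- "normal"
  }
  list(U = U, p_two_sided = p, method = method)
}

#' Tertile-stratified comparison of traits between high and low groups
#'
#' Stratifies subjects by `strat_values` ([tertile_stratify()]) and compares
#' every trait between the two groups by [mann_whitney()] — the cohort-table
#' analogue of a clinical characteristics table.
#'
#' @param strat_values Per-subject stratifying measure.
#' @param traits Subjects x traits data.frame.
#' @return Data.frame: `trait`, `mean_high`, `mean_low`, `p`.
#' @export
stratified_comparison <- function(strat_values, traits) {
  traits <- as.data.frame(traits)
  st <- tertile_stratify(strat_values)
  rows <- lapply(colnames(traits), function(tr) {
    v <- traits[[tr]]
    mw <- mann_whitney(v[st$high], v[st$low])
    data.frame(trait = tr,
               mean_high = mean(v[st$high]), mean_low = mean(v[st$low]),
               p = mw$p_two_sided, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
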