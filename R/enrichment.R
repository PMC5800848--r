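# Mean-rank (Wilcoxon rank-sum) competitive gene-set enrichment, with GMT
# collection I/O. The feature statistic is typically the per-condition log2
# fold change from the differential-abundance stage.

#' Read a gene-set collection from a GMT file
#'
#' GMT: one set per line, tab-separated fields `name`, `description`,
#' then member IDs. Duplicate members within a set are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `GeneSetCollection`);
#'   attribute `description` holds the per-set description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", bad[1L]))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    u <- unique(members)
    if (length(u) < length(members)) {
      warning(sprintf("duplicate members de-duplicated in set '%s'", p[[1L]]))
    }
    u
  })
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc, class = "GeneSetCollection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of member-ID vectors.
#' @param path Output path.
#' @param description Optional per-set description (defaults to the set
#'   name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description") %||% names(sets)
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# One-sided upper-tail p for a rank-sum W by exhaustive enumeration over all
# size-m subsets of the observed rank vector.
rank_sum_exact_p <- function(ranks, m, W, upper = TRUE) {
  n <- length(ranks)
  sums <- utils::combn(ranks, m, sum)
  if (upper) mean(sums >= W - 1e-9) else mean(sums <= W + 1e-9)
}

#' Mean-rank gene-set enrichment test
#'
#' Ranks all measured features by the statistic (ascending; the `"mixed"`
#' alternative ranks by absolute value) and sums the set members' ranks.
#' For small universes (n <= `exact_n`) the p-value is exact by full subset
#' enumeration; otherwise the Wilcoxon rank-sum normal approximation with
#' tie correction and 0.5 continuity correction is used. `"up"` asks whether
#' set members sit high in the ranking, `"down"` low, `"mixed"` high by
#' magnitude regardless of sign.
#'
#' @param stats Named numeric vector of per-feature statistics (e.g. log2
#'   fold changes); names are feature IDs.
#' @param set Member feature IDs; members not measured are ignored.
#' @param alternative `"up"`, `"down"` or `"mixed"`.
#' @param exact_n Universe size at or below which the exact enumeration path
#'   is used (default 12).
#' @return List: `set_size` (members measured, m), `n` (measured features),
#'   `W` (rank sum), `direction`, `p`, `method` ("exact" or "normal"), and
#'   `testable` (FALSE when no member is measured).
#' @export
mean_rank_test <- function(stats, set, alternative = c("up", "down", "mixed"),
                           exact_n = 12L) {
  alternative <- match.arg(alternative)
  if (is.null(names(stats))) stop("'stats' must be named by feature ID")
  idx <- names(stats) %in% set
  m <- sum(idx)
  n <- length(stats)
  if (m == 0L) {
    return(list(set_size = 0L, n = n, W = NA_real_,
                direction = alternative, p = NA_real_,
                method = "none", testable = FALSE))
  }
  if (m == n) stop("set covers all measured features (empty complement)")
  s <- if (alternative == "mixed") abs(stats) else stats
  rk <- rank(s, ties.method = "average")
  W <- sum(rk[idx])
  upper <- alternative != "down"
  if (n <= exact_n) {
    p <- rank_sum_exact_p(rk, m, W, upper = upper)
    method <- "exact"
  } else {
    mu <- m * (n + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- m * (n - m) / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else if (upper) {
      p <- stats::pnorm((W - 0.5 - mu) / sqrt(v), lower.tail = FALSE)
    } else {
      p <- stats::pnorm((W + 0.5 - mu) / sqrt(v))
    }
    method <- "normal"
  }
  list(set_size = m, n = n, W = W, direction = alternative,
       p = min(max(p, .Machine$double.xmin), 1), method = method,
       testable = TRUE)
}

#' Enrichment of every set in a collection for one condition
#'
#' Runs [mean_rank_test()] up and down for each set and reduces the two
#' one-sided p-values to one per set as `min(1, 2 * min(p_up, p_down))`
#' (the two-sided convention); both one-sided values are retained.
#'
#' @param stats Named per-feature statistic vector (log2 fold changes).
#' @param collection Named list of sets ([read_gmt()]).
#' @param exact_n Passed to [mean_rank_test()].
#' @return Data.frame: `set_name`, `m`, `n`, `W`, `p_up`, `p_down`,
#'   `direction` (side with smaller p), `p` (reduced two-sided),
#'   `testable`.
#' @export
enrich_collection <- function(stats, collection, exact_n = 12L) {
  if (is.null(names(stats))) stop("'stats' must be named by feature ID")
  n <- length(stats)
  if (n <= exact_n) {
    # small universes take the exact path through mean_rank_test
    rows <- lapply(names(collection), function(nm) {
      up <- mean_rank_test(stats, collection[[nm]], "up", exact_n = exact_n)
      if (!up$testable) {
        return(data.frame(set_name = nm, m = 0L, n = up$n, W = NA_real_,
                          p_up = NA_real_, p_down = NA_real_,
                          direction = NA_character_, p = NA_real_,
                          testable = FALSE, stringsAsFactors = FALSE))
      }
      dn <- mean_rank_test(stats, collection[[nm]], "down",
                           exact_n = exact_n)
      data.frame(set_name = nm, m = up$set_size, n = up$n, W = up$W,
                 p_up = up$p, p_down = dn$p,
                 direction = if (up$p <= dn$p) "up" else "down",
                 p = min(1, 2 * min(up$p, dn$p)),
                 testable = TRUE, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  # large universes: rank once, apply the normal approximation to all sets
  rk <- rank(stats, ties.method = "average")
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  m <- vapply(collection, function(set) sum(names(stats) %in% set),
              integer(1))
  W <- vapply(collection, function(set) sum(rk[names(stats) %in% set]),
              numeric(1))
  if (any(m == n)) stop("set covers all measured features (empty complement)")
  mu <- m * (n + 1) / 2
  v <- m * (n - m) / 12 * ((n + 1) - tie_term)
  sdv <- sqrt(pmax(v, 0))
  p_up <- ifelse(v <= 0, 1,
                 stats::pnorm((W - 0.5 - mu) / sdv, lower.tail = FALSE))
  p_down <- ifelse(v <= 0, 1, stats::pnorm((W + 0.5 - mu) / sdv))
  testable <- m > 0L
  out <- data.frame(
    set_name = names(collection), m = m, n = n, W = W,
    p_up = p_up, p_down = p_down,
    direction = ifelse(p_up <= p_down, "up", "down"),
    p = pmin(1, 2 * pmin(p_up, p_down)),
    testable = testable, row.names = NULL, stringsAsFactors = FALSE)
  out$W[!testable] <- NA_real_
  out$p_up[!testable] <- NA_real_
  out$p_down[!testable] <- NA_real_
  out$direction[!testable] <- NA_character_
  out$p[!testable] <- NA_real_
  out
}
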