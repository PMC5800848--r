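#' Expression matrix with group design
#'
#' Lightweight container for a features x samples matrix of log2 abundances
#' (or log2 ratios) together with the group label of each sample. Missing
#' values are `NA`. This is the object every preprocessing and testing stage
#' consumes and returns.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Rownames are feature IDs, colnames are sample IDs; both must be unique.
#' @param groups Character vector of group labels, one per sample (column),
#'   or a named vector whose names are the sample IDs.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (named character vector,
#'   sample -> group).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0L) {
    rownames(values) <- character(0)
  } else if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("'values' must have unique rownames (feature IDs)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("'values' must have unique colnames (sample IDs)")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("'groups' must have one label per sample")
  }
  if (any(is.na(groups)) || any(groups == "")) {
    stop("group labels must be non-missing and non-empty")
  }
  if (any(is.infinite(values), na.rm = TRUE)) {
    stop("values must be finite where present")
  }
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  n_na <- sum(is.na(x$values))
  cat(sprintf("missing cells: %d (%.1f%%)\n", n_na,
              100 * n_na / length(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Write / read an expression matrix as TSV
#'
#' The TSV layout is: header row of sample IDs with a leading `feature_id`
#' column; one row per feature; empty cells are missing values. Group labels
#' travel in a one-line `#groups=` comment so a written matrix reads back
#' identically.
#'
#' @param m An `ExpressionMatrix`.
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#groups=", paste(m$groups, collapse = "\t")), con,
             sep = "\n")
  header <- paste(c("feature_id", colnames(m$values)), collapse = "\t")
  writeLines(header, con, sep = "\n")
  vals <- format(m$values, trim = TRUE, digits = 15, scientific = FALSE)
  vals[is.na(m$values)] <- ""
  lines <- paste(rownames(m$values),
                 apply(vals, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  groups <- NULL
  skip <- 0L
  if (startsWith(first, "#groups=")) {
    groups <- strsplit(sub("^#groups=", "", first), "\t", fixed = TRUE)[[1]]
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df[[1]]
  if (is.null(groups)) groups <- rep("all", ncol(vals))
  expression_matrix(vals, groups)
}
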