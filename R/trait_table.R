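#' Construct and validate a trait table
#'
#' A trait table is a numeric matrix of standardized phenotypes with one row
#' per unit (mutant line or natural strain) and one column per trait. Row
#' names are unit identifiers, column names are trait identifiers; both must
#' be unique, and the matrix must hold at least 2 units and 2 traits.
#'
#' @param values numeric matrix (units x traits) with row and column names.
#' @param allow_missing logical; if `FALSE` (default) any non-finite cell is
#'   an error. Missing cells are tolerated only where a downstream function
#'   documents how it drops them.
#' @return the validated matrix, invisibly classed as `trait_table`.
#' @export
trait_table <- function(values, allow_missing = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("trait table needs row names (unit IDs) and column names (trait IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate unit IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate trait IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("trait table needs at least 2 units and 2 traits")
  if (!allow_missing && !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at unit '%s', trait '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  class(values) <- c("trait_table", class(unclass(values)))
  invisible(values)
}

#' Read a phenotype table from TSV
#'
#' Expects a header row of trait IDs and a first column of unit IDs.
#'
#' @param path file path.
#' @param allow_missing passed to [trait_table()].
#' @return a `trait_table` matrix.
#' @export
read_trait_table <- function(path, allow_missing = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  trait_table(m, allow_missing = allow_missing)
}

#' Write a phenotype table to TSV
#'
#' @param table trait table matrix.
#' @param path output file path.
#' @param id_column name for the unit-ID column (default `"unit"`).
#' @export
write_trait_table <- function(table, path, id_column = "unit") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a square trait-by-trait matrix (correlation or covariance)
#'
#' TSV with trait IDs as both the header row and the first column.
#'
#' @param path file path.
#' @return numeric matrix with matching row/column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (!identical(rownames(m), colnames(m)))
    stop("matrix file must have identical row and column trait IDs")
  m
}

#' @rdname read_matrix_tsv
#' @param m square matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(trait = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Validate a covariance matrix: symmetric, non-negative diagonal, PSD up to
# round-off (eigenvalues >= -1e-8 on the unit-trace scale).
check_covariance <- function(m, what = "covariance matrix") {
  if (!isSymmetric(unclass(m), tol = 1e-10))
    stop(what, " must be symmetric")
  if (any(diag(m) < 0)) stop(what, " has negative diagonal entries")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-8 * scale)
    stop(what, " is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(m)
}

check_correlation <- function(m, what = "correlation matrix") {
  if (!isSymmetric(unclass(m), tol = 1e-10)) stop(what, " must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-10)) stop(what, " must have unit diagonal")
  if (any(m < -1 - 1e-10 | m > 1 + 1e-10))
    stop(what, " entries must lie in [-1, 1]")
  invisible(m)
}
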