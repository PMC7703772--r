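#' Construct a validated genes-by-cells count matrix
#'
#' Counts are stored genes in rows, cells in columns. Entries must be
#' non-negative and integer-valued (storage may be double); gene and cell IDs
#' must be unique and match the matrix dimensions. An optional vector of group
#' (condition/batch) labels can be attached, one per cell, and is carried
#' through downstream operations that support "local" (per-group) priors.
#'
#' @param values numeric matrix (or `Matrix` sparse matrix), genes x cells.
#' @param gene_ids character vector of row IDs; defaults to `rownames(values)`.
#' @param cell_ids character vector of column IDs; defaults to
#'   `colnames(values)`.
#' @param groups optional per-cell labels (condition/batch), length
#'   `ncol(values)`.
#' @return a base matrix of class `count_matrix` with dimnames set and an
#'   optional `groups` attribute.
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2), gene_ids = c("g1", "g2"),
#'                   cell_ids = c("c1", "c2"))
#' cell_groups(m) <- c("A", "B")
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), groups = NULL) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("count matrix must have at least one gene and one cell")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    abort("length of `gene_ids` does not match the number of rows")
  }
  if (length(cell_ids) != ncol(values)) {
    abort("length of `cell_ids` does not match the number of columns")
  }
  if (anyDuplicated(gene_ids)) abort("duplicate gene IDs")
  if (anyDuplicated(cell_ids)) abort("duplicate cell IDs")
  validate_count_values(values)
  dimnames(values) <- list(gene_ids, cell_ids)
  class(values) <- c("count_matrix", class(values))
  if (!is.null(groups)) cell_groups(values) <- groups
  values
}

validate_count_values <- function(values) {
  v <- if (isS4(values)) values@x else as.vector(values)
  if (anyNA(v)) abort("counts contain missing values")
  if (any(v < 0)) abort("negative count entries are not allowed")
  if (any(v != floor(v))) abort("non-integer count entries are not allowed")
  invisible(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Get or set per-cell group labels on a count matrix
#'
#' @param x a `count_matrix` (or any matrix with a `groups` attribute).
#' @param value character/factor vector of length `ncol(x)`.
#' @return `cell_groups()` returns the label vector (or `NULL`).
#' @export
cell_groups <- function(x) attr(x, "groups", exact = TRUE)

#' @rdname cell_groups
#' @export
`cell_groups<-` <- function(x, value) {
  if (is.null(value)) {
    attr(x, "groups") <- NULL
    return(x)
  }
  value <- as.character(value)
  if (length(value) != ncol(x)) {
    abort("`groups` must supply exactly one label per cell")
  }
  if (anyNA(value)) abort("group labels must not be missing")
  attr(x, "groups") <- value
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n", nrow(x), ncol(x)))
  g <- cell_groups(x)
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  zero_frac <- mean(x == 0)
  cat(sprintf("zero fraction: %.3f; total counts: %s\n", zero_frac,
              format(sum(x), big.mark = ",")))
  invisible(x)
}

# strip class/groups for internal numeric work
as_base_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  attr(x, "groups") <- NULL
  attr(x, "class") <- NULL
  x
}
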