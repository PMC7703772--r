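#' Read a genes-by-cells count matrix from disk
#'
#' Two on-disk layouts are supported: MatrixMarket coordinate format (`.mtx`)
#' with plain-text sidecar files listing gene and cell IDs (one per line, in
#' matrix order), and dense TSV/CSV with a header row of cell IDs and the
#' first column holding gene IDs. Counts are validated on read: negative,
#' missing or non-integer entries, duplicate IDs and ID/dimension mismatches
#' are errors, never silently repaired.
#'
#' @param path path to the matrix file.
#' @param format `"mtx"`, `"tsv"` or `"csv"`; `"auto"` picks by extension.
#' @param genes_file,cells_file sidecar ID files for MTX input; default to
#'   `genes.tsv` and `barcodes.tsv` next to `path`.
#' @param transposed set `TRUE` if an MTX file stores cells in rows; the
#'   matrix is never transposed by guessing.
#' @return a [count_matrix()].
#' @seealso [write_recovered()], [read_groups()]
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                        genes_file = NULL, cells_file = NULL,
                        transposed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     txt = "tsv",
                     abort(paste0("cannot infer format from extension: ", ext)))
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    if (transposed) m <- Matrix::t(m)
    genes_file <- genes_file %||%
      file.path(dirname(path), "genes.tsv")
    cells_file <- cells_file %||%
      file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genes_file)) {
      abort(paste0("gene ID sidecar not found: ", genes_file))
    }
    if (!file.exists(cells_file)) {
      abort(paste0("cell ID sidecar not found: ", cells_file))
    }
    gene_ids <- readr::read_lines(genes_file)
    cell_ids <- readr::read_lines(cells_file)
    if (length(gene_ids) != nrow(m) || length(cell_ids) != ncol(m)) {
      abort("sidecar ID counts do not match matrix dimensions")
    }
    return(count_matrix(as.matrix(m), gene_ids, cell_ids))
  }
  delim <- if (format == "csv") "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(tbl) < 2L) abort("expected a gene ID column plus >= 1 cell column")
  gene_ids <- as.character(tbl[[1L]])
  vals <- as.matrix(tbl[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric count entries")
  count_matrix(vals, gene_ids = gene_ids, cell_ids = colnames(tbl)[-1L])
}

#' Attach cell group labels from a two-column TSV
#'
#' The file must have two columns (cell ID, group label), no header, and cover
#' every cell of `cm` exactly once; labels are attached in `cm` cell order.
#'
#' @param path path to the labels TSV.
#' @param cm a [count_matrix()].
#' @return `cm` with its `groups` attribute set.
#' @export
read_groups <- function(path, cm) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, col_names = c("cell_id", "group"),
                         col_types = "cc", progress = FALSE)
  if (anyDuplicated(tbl$cell_id)) abort("duplicated cell IDs in group file")
  missing <- setdiff(colnames(cm), tbl$cell_id)
  if (length(missing)) {
    abort(paste0("group file misses cells: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  unknown <- setdiff(tbl$cell_id, colnames(cm))
  if (length(unknown)) {
    abort(paste0("group file lists unknown cells: ",
                 paste(head(unknown, 5L), collapse = ", ")))
  }
  cell_groups(cm) <- tbl$group[match(colnames(cm), tbl$cell_id)]
  cm
}

#' Write recovered counts to a directory
#'
#' Point estimates (`mean`, `map`) are written as a dense TSV
#' (`recovered_<mode>.tsv`, gene IDs in the first column, cell IDs in the
#' header); integer-valued modes are additionally written as MatrixMarket
#' (`recovered_map.mtx` with `genes.tsv`/`barcodes.tsv` sidecars). Posterior
#' samples are written as one MTX per slice (`sample_001.mtx`, ...) plus the
#' shared sidecars and a `manifest.tsv` listing the slice files. Integer
#' outputs round-trip bit-exactly through [read_counts()].
#'
#' @param rc a [recovered_counts] object (see [recover_counts()]).
#' @param out_dir output directory; created if needed.
#' @return invisibly, the character vector of files written.
#' @export
write_recovered <- function(rc, out_dir) {
  stopifnot(inherits(rc, "recovered_counts"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  written <- character()
  write_ids <- function() {
    readr::write_lines(rc$gene_ids, file.path(out_dir, "genes.tsv"))
    readr::write_lines(rc$cell_ids, file.path(out_dir, "barcodes.tsv"))
    c(file.path(out_dir, "genes.tsv"), file.path(out_dir, "barcodes.tsv"))
  }
  write_dense_tsv <- function(m, path) {
    tbl <- tibble::as_tibble(m, .name_repair = "minimal")
    tbl <- tibble::add_column(tbl, gene_id = rc$gene_ids, .before = 1L)
    readr::write_tsv(tbl, path, progress = FALSE)
    path
  }
  if (rc$mode %in% c("mean", "map")) {
    m <- rc$values
    dimnames(m) <- list(rc$gene_ids, rc$cell_ids)
    written <- c(written,
                 write_dense_tsv(m, file.path(out_dir,
                                              paste0("recovered_", rc$mode,
                                                     ".tsv"))))
    if (rc$mode == "map") {
      mtx <- file.path(out_dir, "recovered_map.mtx")
      Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
      written <- c(written, mtx, write_ids())
    }
  } else {
    s_files <- character(rc$n_samples)
    for (s in seq_len(rc$n_samples)) {
      f <- sprintf("sample_%03d.mtx", s)
      Matrix::writeMM(Matrix::Matrix(rc$values[, , s], sparse = TRUE),
                      file.path(out_dir, f))
      s_files[s] <- f
    }
    manifest <- tibble::tibble(sample = seq_len(rc$n_samples),
                               file = s_files)
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                     progress = FALSE)
    written <- c(written, file.path(out_dir, s_files),
                 file.path(out_dir, "manifest.tsv"), write_ids())
  }
  invisible(written)
}
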