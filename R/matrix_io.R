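#' Validate and coerce a genes-by-cells count matrix
#'
#' Accepts a base matrix or any Matrix-package matrix, checks that all
#' entries are nonnegative integers and that gene identifiers (rownames) are
#' present and unique, and returns a `dgCMatrix` in genes x cells
#' orientation.  Cell identifiers are generated when absent.
#'
#' @param m matrix-like, genes in rows and cells in columns.
#' @return A validated sparse `dgCMatrix` with dimnames.
#' @export
validate_counts <- function(m) {
  if (!(is.matrix(m) || is(m, "Matrix")))
    stop_validation("counts must be a matrix or Matrix object")
  if (is.matrix(m)) {
    if (!is.numeric(m)) stop_validation("counts must be numeric")
    storage.mode(m) <- "double"
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  m <- Matrix::drop0(as(as(as(m, "dMatrix"), "generalMatrix"),
                        "CsparseMatrix"))
  vals <- m@x
  if (anyNA(vals)) stop_validation("counts contain missing values")
  if (any(vals < 0)) stop_validation("counts contain negative values")
  if (any(vals != floor(vals)))
    stop_validation("counts contain non-integral values")
  ids <- rownames(m)
  if (is.null(ids)) stop_validation("gene identifiers (rownames) are required")
  if (anyDuplicated(ids)) stop_validation("duplicate gene identifiers")
  if (is.null(colnames(m)) && ncol(m) > 0L)
    colnames(m) <- paste0("cell_", seq_len(ncol(m)))
  m
}

.find_first <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a count matrix from disk
#'
#' Supports the 10x-style Matrix Market layout (a `.mtx` coordinate file
#' plus `features.tsv`/`genes.tsv` and `barcodes.tsv` sidecars) and dense
#' delimited text with gene identifiers in the first column and cell
#' identifiers in the header.  The result is always genes x cells
#' regardless of the on-disk orientation.
#'
#' @param path directory (for `mtx_dir`) or file (for `dense_delim`).
#' @param format `"mtx_dir"` or `"dense_delim"`.
#' @param orientation on-disk layout, `"genes_x_cells"` (default, the 10x
#'   convention) or `"cells_x_genes"`.
#' @return A validated `dgCMatrix`, genes in rows.
#' @examples
#' d <- tempfile()
#' sim <- simulate_background(50, 20, seed = 1)
#' write_counts_mtx(sim$counts, d)
#' m <- read_counts(d, "mtx_dir")
#' dim(m)
#' @export
read_counts <- function(path,
                        format = c("mtx_dir", "dense_delim"),
                        orientation = c("genes_x_cells", "cells_x_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input("input path does not exist: ", path)

  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop_input("not a directory: ", path)
    mtx <- .find_first(path, c("matrix.mtx", "counts.mtx"))
    if (is.null(mtx)) {
      hits <- list.files(path, pattern = "\\.mtx$", full.names = TRUE)
      if (length(hits) == 1L) mtx <- hits
    }
    if (is.null(mtx)) stop_input("no Matrix Market file found in ", path)
    genes_f <- .find_first(path, c("features.tsv", "genes.tsv",
                                   "features.txt", "genes.txt"))
    cells_f <- .find_first(path, c("barcodes.tsv", "barcodes.txt"))
    if (is.null(genes_f)) stop_input("no gene sidecar file found in ", path)
    if (is.null(cells_f)) stop_input("no barcode sidecar file found in ", path)
    m <- Matrix::readMM(mtx)
    genes <- read.delim(genes_f, header = FALSE,
                        colClasses = "character")[[1L]]
    cells <- read.delim(cells_f, header = FALSE,
                        colClasses = "character")[[1L]]
    if (orientation == "cells_x_genes") m <- Matrix::t(m)
    if (nrow(m) != length(genes))
      stop_validation("gene sidecar length (", length(genes),
                      ") does not match matrix rows (", nrow(m), ")")
    if (ncol(m) != length(cells))
      stop_validation("barcode sidecar length (", length(cells),
                      ") does not match matrix columns (", ncol(m), ")")
    dimnames(m) <- list(genes, cells)
    return(validate_counts(m))
  }

  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  if (ncol(dt) < 2L) stop_validation("dense matrix needs id column plus data")
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_validation("non-numeric entries in dense matrix")
  rownames(vals) <- ids
  if (orientation == "cells_x_genes") vals <- t(vals)
  validate_counts(vals)
}

#' Write ranked gene scores to a TSV file
#'
#' Writes one row per scored gene in rank order with columns `gene`,
#' `positive_ratio`, `mean_expr`, `fitted`, `residual`, `z_score`,
#' `outlier`, `rank`.
#'
#' @param scores a `glp_scores` table from [run_glp()].
#' @param path output file path.
#' @param top_only if `TRUE`, write only the selected top-N genes.
#' @return Invisibly, the path written.
#' @export
write_ranking <- function(scores, path, top_only = FALSE) {
  if (!inherits(scores, "glp_scores"))
    stop_validation("scores must be a glp_scores object")
  if (nrow(scores) == 0L) stop_validation("scores table is empty")
  cols <- c("gene", "positive_ratio", "mean_expr", "fitted", "residual",
            "z_score", "outlier", "rank")
  out <- as.data.frame(scores)[order(scores$rank), cols]
  if (top_only) out <- out[out$rank <= attr(scores, "n_top"), , drop = FALSE]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_input("cannot write to ", path)
  invisible(path)
}

#' Write a count matrix as Matrix Market plus sidecar files
#'
#' Produces `matrix.mtx`, `features.tsv` (two identical columns, mimicking
#' the 10x id/symbol layout) and `barcodes.tsv` in `dir`, and optionally a
#' `truth.tsv` table of simulation ground truth.
#'
#' @param counts validated genes x cells matrix.
#' @param dir output directory, created if needed.
#' @param truth optional data frame written as `truth.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_counts_mtx <- function(counts, dir, truth = NULL) {
  counts <- validate_counts(counts)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_input("cannot create directory ", dir)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(counts), rownames(counts)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(truth))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
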