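#' Per-gene mean expression and positive ratio
#'
#' For each gene j over c cells with counts X_ij, computes the mean
#' expression lambda_j = (1/c) sum_i X_ij, the positive ratio
#' f_j = (1/c) sum_i min(1, X_ij) (the fraction of cells with a nonzero
#' count), and the number of cells in which the gene is detected.
#'
#' @param m genes x cells count matrix (anything [validate_counts()]
#'   accepts).
#' @return A data frame with columns `gene`, `mean_expr`, `positive_ratio`,
#'   `n_detected`, one row per gene in input order.
#' @examples
#' m <- matrix(c(2, 1, 3, 0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), NULL))
#' compute_gene_stats(m)
#' @export
compute_gene_stats <- function(m) {
  m <- validate_counts(m)
  cc <- ncol(m)
  if (cc < 1L) stop_validation("count matrix has zero cells")
  ndet <- as.integer(tabulate(m@i + 1L, nbins = nrow(m)))
  data.frame(gene = rownames(m),
             mean_expr = as.numeric(Matrix::rowSums(m)) / cc,
             positive_ratio = ndet / cc,
             n_detected = ndet,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Drop genes detected in too few cells
#'
#' Removes genes detected (count >= 1) in fewer than `min_cells` cells;
#' such genes take no further part in fitting, scoring or ranking.
#'
#' @param stats table from [compute_gene_stats()].
#' @param min_cells minimum number of detected cells (default 3).
#' @return The filtered table, input gene order preserved.
#' @export
filter_low_detection <- function(stats, min_cells = 3L) {
  if (min_cells < 1L) stop_validation("min_cells must be >= 1")
  stats[stats$n_detected >= min_cells, , drop = FALSE]
}
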