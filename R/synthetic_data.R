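# Synthetic count-matrix generator.  Background genes follow a per-gene
# Poisson with rate spanning several orders of magnitude, so their
# (positive ratio, mean expression) points trace f = 1 - exp(-lambda);
# marker genes are expressed at a high rate in a small cell subpopulation
# and zero elsewhere, decoupling mean expression from positive ratio.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Draw a genes x cells Poisson matrix as sparse triplets, chunked by gene
# so the dense scratch stays small.
.rpois_sparse <- function(rates, n_cells, gene_ids, cell_ids) {
  n <- length(rates)
  ii <- list(); jj <- list(); xx <- list()
  chunk <- max(1L, as.integer(floor(4e6 / max(n_cells, 1L))))
  start <- 1L
  b <- 0L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    len <- end - start + 1L
    block <- matrix(rpois(len * n_cells, rates[start:end]),
                    nrow = len, ncol = n_cells)
    nz <- which(block > 0L)
    if (length(nz)) {
      b <- b + 1L
      ii[[b]] <- (nz - 1L) %% len + start
      jj[[b]] <- (nz - 1L) %/% len + 1L
      xx[[b]] <- block[nz]
    }
    start <- end + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                       x = as.numeric(unlist(xx)),
                       dims = c(n, n_cells),
                       dimnames = list(gene_ids, cell_ids))
}

.cell_ids <- function(n_cells) sprintf("cell_%05d", seq_len(n_cells))

#' Simulate background (pure Poisson) genes
#'
#' Each gene's counts across cells are i.i.d. Poisson with a rate drawn
#' log-uniformly from `rate_range`, so the gene cloud traces the curve
#' f = 1 - exp(-lambda) relating positive ratio to mean expression.  The
#' default range (0.001 to 10) spans near-undetectable to near-saturated
#' genes.
#'
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param rate_range length-2 positive `c(lo, hi)`, lo < hi.
#' @param seed RNG seed; the same seed reproduces the matrix exactly.
#' @return List with `counts` (sparse `dgCMatrix`) and `truth` (data frame
#'   `gene`, `is_marker`, `true_rate`, `expressing_fraction`).
#' @export
simulate_background <- function(n_genes, n_cells,
                                rate_range = c(0.001, 10), seed = 1L) {
  if (n_genes < 1L || n_cells < 1L)
    stop_validation("n_genes and n_cells must be >= 1")
  if (length(rate_range) != 2L || any(rate_range <= 0) ||
      rate_range[1] >= rate_range[2])
    stop_validation("rate_range must be positive with lo < hi")
  .with_seed(seed, {
    rates <- exp(runif(n_genes, log(rate_range[1]), log(rate_range[2])))
    gene_ids <- sprintf("bg_%05d", seq_len(n_genes))
    counts <- .rpois_sparse(rates, n_cells, gene_ids, .cell_ids(n_cells))
    list(counts = counts,
         truth = data.frame(gene = gene_ids, is_marker = FALSE,
                            true_rate = rates, expressing_fraction = 1,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate two-population marker genes
#'
#' Each marker is expressed (Poisson at `rate_hi`) in a fixed random subset
#' of `round(expressing_fraction * n_cells)` cells and is exactly zero
#' elsewhere.  Its expected mean expression `expressing_fraction * rate_hi`
#' then sits above the Poisson curve at its positive ratio whenever
#' `rate_hi` is large — the signature of an informative gene.
#'
#' @param n_markers number of marker genes.
#' @param n_cells number of cells.
#' @param expressing_fraction fraction of cells expressing, in (0, 1).
#' @param rate_hi within-subpopulation Poisson rate.
#' @param seed RNG seed.
#' @return List with `counts` and `truth` as in [simulate_background()].
#' @export
simulate_markers <- function(n_markers, n_cells, expressing_fraction = 0.05,
                             rate_hi = 20, seed = 1L) {
  if (n_markers < 1L || n_cells < 1L)
    stop_validation("n_markers and n_cells must be >= 1")
  if (expressing_fraction <= 0 || expressing_fraction >= 1)
    stop_validation("expressing_fraction must be in (0, 1)")
  if (rate_hi <= 0) stop_validation("rate_hi must be positive")
  n_on <- round(expressing_fraction * n_cells)
  if (n_on < 1L) stop_validation("expressing subset is empty")
  .with_seed(seed, {
    gene_ids <- sprintf("mk_%04d", seq_len(n_markers))
    ii <- list(); jj <- list(); xx <- list()
    for (g in seq_len(n_markers)) {
      cells_on <- sample.int(n_cells, n_on)
      cnt <- rpois(n_on, rate_hi)
      keep <- cnt > 0L
      ii[[g]] <- rep.int(g, sum(keep))
      jj[[g]] <- cells_on[keep]
      xx[[g]] <- cnt[keep]
    }
    counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                   x = as.numeric(unlist(xx)),
                                   dims = c(n_markers, n_cells),
                                   dimnames = list(gene_ids,
                                                   .cell_ids(n_cells)))
    list(counts = counts,
         truth = data.frame(gene = gene_ids, is_marker = TRUE,
                            true_rate = rate_hi,
                            expressing_fraction = expressing_fraction,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a combined background + marker dataset
#'
#' Stacks [simulate_background()] and [simulate_markers()] genes over the
#' same cells, giving a matrix with known ground truth for end-to-end
#' recovery experiments.
#'
#' @param n_background number of Poisson background genes.
#' @param n_markers number of marker genes (0 allowed).
#' @param n_cells number of cells.
#' @param rate_range background log-uniform rate range.
#' @param expressing_fraction marker expressing-cell fraction.
#' @param marker_rate marker within-subpopulation rate.
#' @param seed RNG seed (marker stream derived as `seed + 1`).
#' @return List with `counts` and row-aligned `truth`.
#' @export
simulate_glp_dataset <- function(n_background, n_markers, n_cells,
                                 rate_range = c(0.001, 10),
                                 expressing_fraction = 0.05,
                                 marker_rate = 20, seed = 1L) {
  bg <- simulate_background(n_background, n_cells, rate_range, seed)
  if (n_markers >= 1L) {
    mk <- simulate_markers(n_markers, n_cells, expressing_fraction,
                           marker_rate, seed + 1L)
    counts <- rbind(bg$counts, mk$counts)
    truth <- rbind(bg$truth, mk$truth)
  } else {
    counts <- bg$counts
    truth <- bg$truth
  }
  list(counts = counts, truth = truth)
}

#' Mean expression predicted from the positive ratio under Poisson sampling
#'
#' Inverts f = 1 - exp(-lambda): returns lambda = -log(1 - f).  For small
#' f this is approximately f itself (the Taylor regime).
#'
#' @param f positive ratio(s) in \[0, 1).
#' @return Predicted mean expression lambda.
#' @export
theoretical_curve <- function(f) {
  if (any(f < 0 | f >= 1)) stop_validation("f must be in [0, 1)")
  -log1p(-f)
}
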