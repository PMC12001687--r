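# Pipeline: span selection -> round-1 fit -> local-MAD outlier masking ->
# round-2 fit -> windowed residual Z-scores -> ranking.

#' Pipeline configuration
#'
#' Collects every tunable of the gene-selection pipeline with its default:
#' automatic BIC span selection over `seq(0.01, 0.1, 0.01)`, a detection
#' filter at 3 cells, outliers at 6 local MADs within a positive-ratio
#' halfwidth of 0.1, zero round-2 weight above positive ratio 0.99, a
#' 100-gene Z-score halfwindow, and 1000 selected genes.
#'
#' @param span numeric span in (0, 1] or `"auto"` for BIC selection.
#' @param span_grid candidate spans for automatic selection.
#' @param min_cells detection filter threshold (cells).
#' @param outlier_k MAD multiplier for outlier flagging.
#' @param outlier_halfwidth positive-ratio halfwidth of the MAD window.
#' @param fmax positive-ratio ceiling; genes above it get round-2 weight 0.
#' @param z_window number of f-sorted neighbour genes on either side used
#'   to standardize residuals.
#' @param n_top number of genes to select.
#' @param loess_degree local polynomial degree (0, 1 or 2).
#' @return A `glp_config` list.
#' @export
glp_config <- function(span = "auto",
                       span_grid = seq(0.01, 0.10, by = 0.01),
                       min_cells = 3L,
                       outlier_k = 6,
                       outlier_halfwidth = 0.1,
                       fmax = 0.99,
                       z_window = 100L,
                       n_top = 1000L,
                       loess_degree = 1L) {
  if (!identical(span, "auto")) {
    if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
      stop_validation("span must be 'auto' or a number in (0, 1]")
  }
  if (length(span_grid) == 0L || any(span_grid <= 0 | span_grid > 1))
    stop_validation("span_grid values must be in (0, 1]")
  if (min_cells < 1L) stop_validation("min_cells must be >= 1")
  if (outlier_k <= 0) stop_validation("outlier_k must be positive")
  if (outlier_halfwidth <= 0)
    stop_validation("outlier_halfwidth must be positive")
  if (fmax <= 0 || fmax >= 1) stop_validation("fmax must be in (0, 1)")
  if (z_window < 1L) stop_validation("z_window must be >= 1")
  if (n_top < 1L) stop_validation("n_top must be >= 1")
  if (!loess_degree %in% 0:2) stop_validation("loess_degree must be 0, 1 or 2")
  structure(list(span = span, span_grid = span_grid,
                 min_cells = as.integer(min_cells), outlier_k = outlier_k,
                 outlier_halfwidth = outlier_halfwidth, fmax = fmax,
                 z_window = as.integer(z_window), n_top = as.integer(n_top),
                 loess_degree = as.integer(loess_degree)),
            class = "glp_config")
}

#' Flag outliers by deviation from the local median residual
#'
#' A gene is flagged when its residual deviates from the median residual of
#' all genes within `halfwidth` of its positive ratio by strictly more than
#' `k` times the local (unscaled) median absolute deviation.  The deviation
#' is two-sided, protecting the refit from both inflated and deflated
#' residuals.
#'
#' @param f positive ratios.
#' @param residuals round-1 residuals, same length.
#' @param k MAD multiplier (default 6).
#' @param halfwidth positive-ratio halfwidth of the local window
#'   (default 0.1).
#' @return Logical vector of flags.
#' @export
detect_outliers <- function(f, residuals, k = 6, halfwidth = 0.1) {
  if (length(f) != length(residuals))
    stop_validation("f and residuals lengths differ")
  if (k <= 0) stop_validation("k must be positive")
  if (halfwidth <= 0) stop_validation("halfwidth must be positive")
  if (length(f) == 0L) return(logical(0))
  cpp_local_mad_flags(as.numeric(f), as.numeric(residuals), k, halfwidth)
}

#' Round-2 observation weights
#'
#' Zero weight for flagged outliers and for near-saturated genes with
#' positive ratio strictly greater than `fmax`; weight 1 otherwise.
#'
#' @param outliers logical flags from [detect_outliers()].
#' @param f positive ratios.
#' @param fmax positive-ratio ceiling (default 0.99, strict inequality).
#' @return Numeric 0/1 weight vector.
#' @export
second_round_weights <- function(outliers, f, fmax = 0.99) {
  if (length(outliers) != length(f))
    stop_validation("outliers and f lengths differ")
  w <- as.numeric(!(outliers | f > fmax))
  if (sum(w > 0) < 4L)
    stop_validation("fewer than 4 genes retain positive weight; cannot refit")
  w
}

#' Windowed residual Z-scores
#'
#' With genes sorted ascending by positive ratio, each gene's residual is
#' standardized against the mean and sample standard deviation of the
#' residuals of the `window` genes on either side of it (windows truncate
#' at the edges; the gene is included in its own window).  A zero standard
#' deviation gives Z = 0.
#'
#' @param f positive ratios, sorted ascending.
#' @param residuals round-2 residuals in the same order.
#' @param window halfwindow size in genes (default 100).
#' @return Numeric Z-score vector.
#' @export
standardize_residuals <- function(f, residuals, window = 100L) {
  n <- length(f)
  if (length(residuals) != n)
    stop_validation("f and residuals lengths differ")
  if (window < 1L) stop_validation("window must be >= 1")
  if (is.unsorted(f)) stop_validation("f must be sorted ascending")
  if (n == 0L) return(numeric(0))
  e <- residuals - mean(residuals)   # centred for cumulative-sum stability
  idx <- seq_len(n)
  lo <- pmax(1L, idx - window)
  hi <- pmin(n, idx + window)
  len <- hi - lo + 1
  cs <- cumsum(c(0, e))
  cs2 <- cumsum(c(0, e^2))
  mu <- (cs[hi + 1L] - cs[lo]) / len
  ssq <- (cs2[hi + 1L] - cs2[lo]) - len * mu^2
  var_ <- ifelse(len > 1, ssq / (len - 1), 0)
  # re-derive near-degenerate windows exactly to avoid cancellation noise
  scale <- mean(e^2) + 1e-30
  check <- which(var_ < 1e-10 * scale)
  for (j in check) {
    wvals <- e[lo[j]:hi[j]]
    mu[j] <- mean(wvals)
    var_[j] <- if (len[j] > 1) stats::var(wvals) else 0
  }
  sigma <- sqrt(pmax(var_, 0))
  ifelse(sigma > 0, (e - mu) / sigma, 0)
}

#' Rank genes by residual Z-score
#'
#' Orders genes by Z-score descending (ties: mean expression descending,
#' then gene id ascending), assigns ranks 1..n, and records the selected
#' top-N set.
#'
#' @param scores data frame with at least `gene`, `mean_expr`, `z_score`.
#' @param n_top number of genes to select (default 1000).
#' @return The table in rank order, class `glp_scores`, with attribute
#'   `n_top`; [selected_genes()] extracts the selected identifiers.
#' @export
rank_genes <- function(scores, n_top = 1000L) {
  if (n_top < 1L) stop_validation("n_top must be >= 1")
  ord <- order(-scores$z_score, -scores$mean_expr, scores$gene,
               method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_top") <- as.integer(min(n_top, nrow(out)))
  class(out) <- c("glp_scores", "data.frame")
  out
}

#' Selected gene identifiers
#'
#' @param scores a `glp_scores` table.
#' @return Character vector of the selected top-N gene ids, in rank order.
#' @export
selected_genes <- function(scores) {
  if (!inherits(scores, "glp_scores"))
    stop_validation("scores must be a glp_scores object")
  scores$gene[scores$rank <= attr(scores, "n_top")]
}

#' Run the full gene-selection pipeline
#'
#' Executes, in order: per-gene statistics; detection filter; sort by
#' positive ratio (ties by mean expression, then gene id); BIC span
#' selection (skipped when the span is fixed); round-1 LOESS fit; local-MAD
#' outlier flagging; round-2 LOESS fit with outliers and near-saturated
#' genes given zero weight; windowed residual Z-scores from the round-2
#' residuals of every gene (masked genes are still predicted and scored);
#' ranking.  The pipeline is fully deterministic.
#'
#' @param counts genes x cells count matrix.
#' @param config a [glp_config()] list.
#' @return A `glp_scores` data frame in rank order with columns `gene`,
#'   `positive_ratio`, `mean_expr`, `fitted`, `residual`, `z_score`,
#'   `outlier`, `rank`, plus attributes `span`, `bic_table`, `n_top`,
#'   `config`, `n_genes_input`, `n_filtered_out`, `n_outliers`,
#'   `n_zero_weight`.
#' @examples
#' sim <- simulate_glp_dataset(n_background = 300, n_markers = 10,
#'                             n_cells = 200, seed = 1)
#' sc <- run_glp(sim$counts, glp_config(span = 0.1, n_top = 50))
#' head(selected_genes(sc))
#' @export
run_glp <- function(counts, config = glp_config()) {
  if (!inherits(config, "glp_config"))
    stop_validation("config must come from glp_config()")
  stats <- compute_gene_stats(counts)
  n_input <- nrow(stats)
  stats <- filter_low_detection(stats, config$min_cells)
  if (nrow(stats) < 4L)
    stop_validation("fewer than 4 genes pass the detection filter (",
                    nrow(stats), " of ", n_input,
                    "); cannot fit the regression")
  ord <- order(stats$positive_ratio, stats$mean_expr, stats$gene,
               method = "radix")
  s <- stats[ord, , drop = FALSE]
  x <- s$positive_ratio
  y <- s$mean_expr

  if (identical(config$span, "auto")) {
    span <- select_span(x, y, config$span_grid, degree = config$loess_degree)
    bic_table <- attr(span, "bic_table")
    span <- as.numeric(span)
  } else {
    span <- config$span
    bic_table <- NULL
  }

  fit1 <- loess_fit(x, y, span, degree = config$loess_degree)
  outl <- detect_outliers(x, fit1$residuals, config$outlier_k,
                          config$outlier_halfwidth)
  w2 <- second_round_weights(outl, x, config$fmax)
  fit2 <- loess_fit(x, y, span, obs_weights = w2,
                    degree = config$loess_degree)
  z <- standardize_residuals(x, fit2$residuals, config$z_window)

  out <- data.frame(gene = s$gene,
                    positive_ratio = x,
                    mean_expr = y,
                    fitted = fit2$fitted,
                    residual = fit2$residuals,
                    z_score = z,
                    outlier = as.logical(outl),
                    n_detected = s$n_detected,
                    stringsAsFactors = FALSE)
  out <- rank_genes(out, config$n_top)
  attr(out, "span") <- span
  attr(out, "bic_table") <- bic_table
  attr(out, "config") <- config
  attr(out, "n_genes_input") <- n_input
  attr(out, "n_filtered_out") <- n_input - nrow(out)
  attr(out, "n_outliers") <- sum(outl)
  attr(out, "n_zero_weight") <- sum(w2 == 0)
  out
}
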