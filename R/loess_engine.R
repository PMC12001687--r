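# Local regression engine: windowed weighted least squares with a tricube
# kernel, equivalent degrees of freedom from the smoother trace, and BIC for
# span selection.  The per-point arithmetic lives in src/loess.cpp.

#' Local regression window
#'
#' Returns the q nearest points to `x[j]` with q = max(ceil(span * n), 4),
#' ties broken toward the lower index, together with the window bandwidth
#' (the largest distance within the window).
#'
#' @param x numeric vector sorted ascending.
#' @param j index of the query point.
#' @param span fraction of points per window, in (0, 1].
#' @return A list with `indices` (integer vector) and `bandwidth`.
#' @export
local_window <- function(x, j, span) {
  n <- length(x)
  if (n < 4L) stop_validation("need at least 4 points for local regression")
  if (is.unsorted(x)) stop_validation("x must be sorted ascending")
  if (span <= 0 || span > 1) stop_validation("span must be in (0, 1]")
  if (j < 1L || j > n) stop_validation("index out of range")
  q <- min(max(ceiling(span * n), 4L), n)
  # contiguous block of the q smallest distances ...
  lo <- hi <- j
  while (hi - lo + 1L < q) {
    dl <- if (lo > 1L) x[j] - x[lo - 1L] else Inf
    dr <- if (hi < n) x[hi + 1L] - x[j] else Inf
    if (dl <= dr) lo <- lo - 1L else hi <- hi + 1L
  }
  h <- max(x[j] - x[lo], x[hi] - x[j])
  # ... then points at the boundary distance resolve by lowest index
  d <- abs(x - x[j])
  inner <- which(d < h)
  ties <- which(d == h)
  idx <- sort(c(inner, ties[seq_len(q - length(inner))]))
  list(indices = idx, bandwidth = h)
}

#' Tricube kernel weight
#'
#' `(1 - (d/h)^3)^3` for distances `d < h`, zero beyond the bandwidth.
#'
#' @param distance nonnegative distance(s).
#' @param bandwidth positive bandwidth.
#' @return Weight(s) in \[0, 1\].
#' @export
tricube_weight <- function(distance, bandwidth) {
  if (any(bandwidth <= 0)) stop_validation("bandwidth must be positive")
  u <- pmin(distance / bandwidth, 1)
  (1 - u^3)^3
}

#' Fit a weighted LOESS smoother
#'
#' Fits, at every point, a weighted polynomial (default degree 1) over the
#' point's local window, with weights = tricube kernel x observation
#' weight, and evaluates it at the point.  Zero-weight observations are
#' still predicted (their own y never enters any fit) but contribute
#' nothing to the residual sum of squares or the equivalent degrees of
#' freedom; edf is the trace of the smoother matrix over positively
#' weighted points.
#'
#' @param x covariate, sorted ascending (here: positive ratios).
#' @param y response (here: mean expression).
#' @param span window fraction in (0, 1].
#' @param obs_weights nonnegative observation weights (default all 1).
#' @param degree local polynomial degree, 0, 1 or 2 (default 1).
#' @return An object of class `loess_fit`: list with `span`, `x`, `y`,
#'   `obs_weights`, `fitted`, `residuals`, `rss`, `edf`, `n_obs`, `bic`
#'   (`NA` when `rss` is 0).
#' @export
loess_fit <- function(x, y, span, obs_weights = NULL, degree = 1L) {
  n <- length(x)
  if (length(y) != n) stop_validation("x and y lengths differ")
  if (is.null(obs_weights)) obs_weights <- rep(1, n)
  if (length(obs_weights) != n) stop_validation("weights length differs")
  if (any(obs_weights < 0)) stop_validation("negative observation weights")
  if (is.unsorted(x)) stop_validation("x must be sorted ascending")
  if (span <= 0 || span > 1) stop_validation("span must be in (0, 1]")
  if (!degree %in% 0:2) stop_validation("degree must be 0, 1 or 2")
  pos <- obs_weights > 0
  if (sum(pos) < 4L)
    stop_validation("need at least 4 positively weighted observations")

  res <- cpp_loess_fit(as.numeric(x), as.numeric(y),
                       as.numeric(obs_weights), span, as.integer(degree))
  fitted <- res$fitted
  residuals <- y - fitted
  rss <- sum(residuals[pos]^2)
  edf <- sum(res$hat[pos])
  n_obs <- sum(pos)
  bic <- if (rss > 0) .bic_formula(n_obs, rss, edf) else NA_real_
  structure(list(span = span, x = x, y = y, obs_weights = obs_weights,
                 fitted = fitted, residuals = residuals, hat = res$hat,
                 rss = rss, edf = edf, n_obs = n_obs, bic = bic),
            class = "loess_fit")
}

.bic_formula <- function(n_obs, rss, edf) {
  n_obs * log(rss / n_obs) + edf * log(n_obs)
}

#' Bayesian Information Criterion of a smoother fit
#'
#' `BIC = n ln(RSS/n) + k ln(n)` where n is the number of positively
#' weighted observations and k the equivalent degrees of freedom (trace of
#' the smoother matrix).
#'
#' @param fit a `loess_fit` object.
#' @return The BIC value.
#' @export
compute_bic <- function(fit) {
  if (!inherits(fit, "loess_fit")) stop_validation("fit must be a loess_fit")
  if (fit$n_obs < 2L) stop_numerical("need at least 2 observations for BIC")
  if (fit$rss <= 0)
    stop_numerical("zero residual sum of squares: degenerate (overfit) span")
  .bic_formula(fit$n_obs, fit$rss, fit$edf)
}

#' Select the LOESS span by BIC
#'
#' Fits an unweighted smoother at every span on the grid and returns the
#' span minimizing BIC; ties (and near-ties at machine precision) resolve
#' toward the larger, smoother span.  Degenerate fits (zero RSS) are
#' excluded.
#'
#' @param x sorted covariate.
#' @param y response.
#' @param grid candidate spans, default `seq(0.01, 0.10, by = 0.01)`.
#' @param degree local polynomial degree.
#' @return The selected span, with attribute `bic_table` (data frame of
#'   span, bic, rss, edf).
#' @export
select_span <- function(x, y, grid = seq(0.01, 0.10, by = 0.01),
                        degree = 1L) {
  if (length(grid) == 0L) stop_validation("span grid is empty")
  if (any(grid <= 0 | grid > 1)) stop_validation("grid spans must be in (0, 1]")
  grid <- sort(grid)
  tab <- data.frame(span = grid, bic = NA_real_, rss = NA_real_,
                    edf = NA_real_)
  for (i in seq_along(grid)) {
    fit <- loess_fit(x, y, grid[i], degree = degree)
    tab$bic[i] <- fit$bic
    tab$rss[i] <- fit$rss
    tab$edf[i] <- fit$edf
  }
  if (all(is.na(tab$bic)))
    stop_numerical("all candidate spans give degenerate fits")
  best <- NA_real_
  best_bic <- Inf
  for (i in seq_along(grid)) {     # ascending grid: '<=' keeps larger span
    if (!is.na(tab$bic[i]) && tab$bic[i] <= best_bic) {
      best <- grid[i]
      best_bic <- tab$bic[i]
    }
  }
  structure(best, bic_table = tab)
}
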