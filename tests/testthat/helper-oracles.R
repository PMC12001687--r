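# Independent brute-force oracles.  These deliberately avoid the package's
# code paths: windows come from a full distance sort, local fits from
# lm.wfit, medians and window statistics from explicit slices.

oracle_window <- function(x, j, span) {
  n <- length(x)
  q <- min(max(ceiling(span * n), 4L), n)
  ord <- order(abs(x - x[j]), seq_along(x))
  idx <- sort(ord[seq_len(q)])
  list(indices = idx, bandwidth = max(abs(x[idx] - x[j])))
}

# Per-point weighted least squares: tricube * observation weight, local line
# evaluated at x[j].
oracle_wls_fitted <- function(x, y, span, w = rep(1, length(x))) {
  vapply(seq_along(x), function(j) {
    win <- oracle_window(x, j, span)
    idx <- win$indices
    h <- win$bandwidth
    d <- abs(x[idx] - x[j])
    kw <- if (h > 0) (1 - pmin(d / h, 1)^3)^3 * w[idx] else w[idx]
    if (sum(kw > 0) == 0) return(NA_real_)
    fit <- stats::lm.wfit(cbind(1, x[idx] - x[j]), y[idx], kw)
    unname(fit$coefficients[1])
  }, numeric(1))
}

oracle_mad_flags <- function(f, e, k = 6, halfwidth = 0.1) {
  vapply(seq_along(f), function(j) {
    w <- which(abs(f - f[j]) <= halfwidth)
    med <- stats::median(e[w])
    mad <- stats::median(abs(e[w] - med))
    abs(e[j] - med) > k * mad
  }, logical(1))
}

oracle_window_z <- function(e, window = 100L) {
  n <- length(e)
  vapply(seq_len(n), function(j) {
    w <- e[max(1L, j - window):min(n, j + window)]
    s <- stats::sd(w)
    if (is.na(s) || s == 0) 0 else (e[j] - mean(w)) / s
  }, numeric(1))
}

oracle_best_span <- function(x, y, grid) {
  best <- NA_real_
  best_bic <- Inf
  for (sp in sort(grid)) {
    fit <- loess_fit(x, y, sp)
    if (fit$rss <= 0) next
    bic <- fit$n_obs * log(fit$rss / fit$n_obs) + fit$edf * log(fit$n_obs)
    if (bic <= best_bic) {   # ties resolve to the larger span
      best <- sp
      best_bic <- bic
    }
  }
  best
}

# Small deterministic count matrix with named genes/cells.
random_counts <- function(n_genes, n_cells, seed, lambda = 0.8) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  m
}
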