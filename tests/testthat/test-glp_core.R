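test_that("outlier flagging implements the strict local 6xMAD rule", {
  # constant residuals: deviations are all zero, nothing exceeds anything
  f <- seq(0, 1, length.out = 20)
  expect_false(any(detect_outliers(f, rep(0.3, 20))))

  # deviation exactly equal to k * MAD is NOT an outlier ("exceeding")
  f5 <- rep(0.5, 5)
  e_edge <- c(-1, -1, 1, 1, 13)     # med 1, MAD 2, |13 - 1| == 6 * 2
  expect_false(detect_outliers(f5, e_edge)[5])
  e_over <- c(-1, -1, 1, 1, 13.0001)
  expect_true(detect_outliers(f5, e_over)[5])
})

test_that("a single spiked residual among a tight cloud is flagged", {
  set.seed(131)
  n <- 1000
  f <- sort(runif(n))
  e <- rnorm(n, sd = 0.01)
  e[500] <- 5
  flags <- detect_outliers(f, e)
  expect_true(flags[500])
  expect_equal(as.logical(flags), oracle_mad_flags(f, e))
})

test_that("outlier flags equal the double-loop local-MAD oracle", {
  for (seed in c(141, 142, 143)) {
    set.seed(seed)
    n <- sample(100:400, 1)
    f <- runif(n)                      # deliberately unsorted
    e <- rnorm(n, sd = 0.05) + rbinom(n, 1, 0.02) * 3
    expect_equal(as.logical(detect_outliers(f, e)), oracle_mad_flags(f, e))
    hw <- 0.25
    expect_equal(as.logical(detect_outliers(f, e, halfwidth = hw)),
                 oracle_mad_flags(f, e, halfwidth = hw))
  }
})

test_that("round-2 weights zero out outliers and near-saturated genes only", {
  f <- c(0.5, 0.2, 0.995, 0.99, 0.7, 0.1)
  outl <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  w <- second_round_weights(outl, f)
  expect_equal(w, c(0, 1, 0, 1, 1, 1))   # f = 0.99 exactly keeps weight 1
  expect_error(second_round_weights(rep(TRUE, 6), f),
               class = "glp_validation_error")
})

test_that("windowed Z-scores match explicit slicing and handle sigma = 0", {
  n <- 10000
  set.seed(151)
  f <- sort(runif(n))
  e <- rnorm(n)
  # position 150 (1-based 151) spans sorted positions 51..251
  z <- standardize_residuals(f, e, window = 100L)
  w <- e[51:251]
  expect_equal(z[151], (e[151] - mean(w)) / sd(w), tolerance = 1e-9)

  expect_equal(standardize_residuals(seq(0, 1, length.out = 10),
                                     rep(0.5, 10), window = 3L),
               rep(0, 10))

  for (seed in c(161, 162, 163)) {
    set.seed(seed)
    m <- sample(50:400, 1)
    fe <- sort(runif(m))
    ee <- rnorm(m, sd = runif(1, 0.01, 2))
    win <- sample(c(5L, 50L, 100L), 1)
    expect_equal(standardize_residuals(fe, ee, win), oracle_window_z(ee, win),
                 tolerance = 1e-8)
  }
})

test_that("ranking orders by descending Z with deterministic ties", {
  df <- data.frame(gene = c("a", "b", "c"), mean_expr = c(1, 1, 1),
                   z_score = c(3, 1, 2))
  r <- rank_genes(df, n_top = 2L)
  expect_equal(selected_genes(r), c("a", "c"))
  expect_equal(r$rank, 1:3)

  df2 <- data.frame(gene = c("zz", "aa", "mm"), mean_expr = c(1, 2, 1),
                    z_score = c(5, 5, 5))
  r2 <- rank_genes(df2, n_top = 10L)
  expect_equal(r2$gene, c("aa", "mm", "zz"))   # lambda desc, then id asc
  expect_length(selected_genes(r2), 3L)
})

test_that("the pipeline recovers injected marker genes", {
  sim <- simulate_glp_dataset(5000, 100, 1000, seed = 42)
  sc <- run_glp(sim$counts)
  expect_equal(length(selected_genes(sc)), 1000L)
  markers <- sim$truth$gene[sim$truth$is_marker]
  expect_gte(sum(markers %in% selected_genes(sc)), 90L)
  # markers sit above the Poisson curve and are typically round-1 outliers,
  # yet still receive fitted values, z-scores and ranks
  mk <- sc[sc$gene %in% markers, ]
  expect_true(all(is.finite(mk$fitted)))
  expect_true(all(is.finite(mk$z_score)))
  expect_true(any(mk$outlier))
})

test_that("identical input and config give byte-identical output", {
  sim <- simulate_glp_dataset(800, 20, 400, seed = 5)
  sc1 <- run_glp(sim$counts, glp_config(n_top = 100))
  sc2 <- run_glp(sim$counts, glp_config(n_top = 100))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_ranking(sc1, f1); write_ranking(sc2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene-row permutation leaves the selected set unchanged", {
  sim <- simulate_glp_dataset(600, 15, 300, seed = 6)
  set.seed(7)
  perm <- sample(nrow(sim$counts))
  sc1 <- run_glp(sim$counts, glp_config(span = 0.05, n_top = 50))
  sc2 <- run_glp(sim$counts[perm, ], glp_config(span = 0.05, n_top = 50))
  expect_setequal(selected_genes(sc1), selected_genes(sc2))
  expect_identical(sc1$gene, sc2$gene)   # deterministic sort => same order
})

test_that("filtered genes never appear and selection size is min(n_top, n)", {
  sim <- simulate_background(500, 60, c(0.005, 5), seed = 8)
  sc <- run_glp(sim$counts, glp_config(span = 0.1))
  st <- compute_gene_stats(sim$counts)
  low <- st$gene[st$n_detected < 3]
  expect_false(any(low %in% sc$gene))
  expect_true(all(sc$n_detected >= 3))
  expect_length(selected_genes(sc), min(1000L, nrow(sc)))
  expect_equal(attr(sc, "n_filtered_out"), length(low))
})

test_that("too few surviving genes raise a clear validation error", {
  m <- matrix(0, nrow = 6, ncol = 5,
              dimnames = list(paste0("g", 1:6), NULL))
  m[1, 1:4] <- 1
  expect_error(run_glp(m), class = "glp_validation_error")
})

test_that("a fixed span skips the grid search", {
  sim <- simulate_glp_dataset(500, 10, 250, seed = 9)
  sc <- run_glp(sim$counts, glp_config(span = 0.07))
  expect_equal(attr(sc, "span"), 0.07)
  expect_null(attr(sc, "bic_table"))
})
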