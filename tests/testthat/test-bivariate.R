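test_that("Spearman correlation matches the hand rank computation", {
  expect_equal(spearman_rho(1:5, c(3, 1, 2, 5, 4)), 0.6)
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")
  # invariant under strictly monotone transforms
  set.seed(71)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(spearman_rho(x, y), spearman_rho(exp(x), y^3 + 2 * y))
  expect_true(abs(spearman_rho(x, y)) <= 1)
})

test_that("contiguity weights give the textbook neighbour counts", {
  g <- lattice_grid(4, 5)
  w <- build_weights(g, standardize = "none")
  deg <- Matrix::rowSums(w$W)
  corner <- which(g$plots$gr %in% c(1, 4) & g$plots$gc %in% c(1, 5))
  interior <- which(g$plots$gr %in% 2:3 & g$plots$gc %in% 2:4)
  expect_true(all(deg[corner] == 3))
  expect_true(all(deg[interior] == 8))
  expect_true(all(Matrix::diag(w$W) == 0))
  wr <- build_weights(g, scheme = "rook", standardize = "none")
  expect_true(all(Matrix::rowSums(wr$W)[interior] == 4))
  ws <- build_weights(g)
  expect_equal(as.numeric(Matrix::rowSums(ws$W)), rep(1, 20))
})

test_that("global and local Moran match the double-loop oracle", {
  # 2x2 rook lattice with the alternating pattern
  g <- lattice_grid(2, 2)
  w <- build_weights(g, scheme = "rook", standardize = "none")
  xk <- c(1, -1, -1, 1)
  expect_equal(moran_bv_global(xk, xk, w),
               naive_moran_global(xk, xk, as.matrix(w$W)), tolerance = 1e-12)
  # random fields on lattices up to 5x5, both schemes and standardisations
  set.seed(81)
  for (side in 3:5) for (scheme in c("queen", "rook")) {
    g <- lattice_grid(side, side)
    w <- build_weights(g, scheme = scheme)
    xk <- rnorm(side^2); xl <- rnorm(side^2)
    W <- as.matrix(w$W)
    expect_equal(moran_bv_global(xk, xl, w), naive_moran_global(xk, xl, W),
                 tolerance = 1e-12)
    expect_equal(moran_bv_local(xk, xl, w), naive_moran_local(xk, xl, W),
                 tolerance = 1e-12)
  }
  expect_error(moran_bv_global(rep(1, 9), rnorm(9),
                               build_weights(lattice_grid(3, 3))),
               "zero-variance")
})

test_that("local statistics aggregate to the global numerator", {
  set.seed(91)
  g <- lattice_grid(6, 6)
  w <- build_weights(g)
  xk <- rnorm(36); xl <- rnorm(36)
  n <- 36
  Is <- moran_bv_local(xk, xl, w)
  I <- moran_bv_global(xk, xl, w)
  # with row-standardised W, sum(W) = n, so I = sum(Is) / (n - 1)
  expect_equal(I, sum(Is) / (n - 1), tolerance = 1e-12)
  # relabelling units leaves I and the multiset of Is unchanged
  perm <- sample(n)
  g2 <- g; g2$plots <- g$plots[perm, ]; g2$plots$plot_id <- seq_len(n)
  w2 <- build_weights(g2)
  expect_equal(moran_bv_global(xk[perm], xl[perm], w2), I, tolerance = 1e-12)
  expect_equal(sort(moran_bv_local(xk[perm], xl[perm], w2)), sort(Is),
               tolerance = 1e-12)
})

test_that("spatially shuffled fields have Moran near zero; smooth fields not", {
  set.seed(101)
  g <- lattice_grid(10, 10)
  w <- build_weights(g)
  x <- rnorm(100)
  Ishuf <- replicate(999, moran_bv_global(x, sample(x), w))
  expect_lt(abs(mean(Ishuf)), 0.02)
  # a smooth autocorrelated field correlates with itself spatially
  f <- greenrisk:::smooth_matrix(matrix(rnorm(100), 10, 10), 2)
  xs <- f[cbind(g$plots$gr, g$plots$gc)]
  expect_gt(moran_bv_global(xs, xs, w), 0)
})

test_that("LISA labels a self-similar smooth field H-H/L-L and flags noise at alpha", {
  set.seed(111)
  g <- lattice_grid(10, 10)
  w <- build_weights(g)
  fm <- greenrisk:::smooth_matrix(matrix(rnorm(100), 10, 10), 3)
  f <- fm[cbind(g$plots$gr, g$plots$gc)]
  lisa <- lisa_classify(f, f, w, n_perm = 499, seed = 5)
  sig <- lisa$cluster != "N-S"
  expect_gt(mean(sig), 0.3)
  expect_gt(mean(lisa$cluster[sig] %in% c("H-H", "L-L")), 0.9)
  # degenerate constant second field
  expect_warning(out <- lisa_classify(f, rep(1, 100), w, n_perm = 99),
                 "constant")
  expect_true(all(out$cluster == "N-S"))
})

test_that("the K-S gate keeps level under normality and rejects skew", {
  null500 <- ks_null_distribution(500, n_mc = 500, seed = 3)
  set.seed(121)
  p_null <- replicate(60, ks_normality(rnorm(500), null_stats = null500)$p_value)
  expect_gte(mean(p_null > 0.05), 0.9)
  p_alt <- replicate(60, ks_normality(rexp(500), null_stats = null500)$p_value)
  expect_gte(mean(p_alt < 0.05), 0.99)
  expect_error(ks_normality(rep(1, 20)), "zero-variance")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("the Monte-Carlo K-S p agrees with the Lilliefors approximation", {
  skip_if_not_installed("nortest")
  set.seed(131)
  x <- rnorm(200) + 0.3 * rexp(200)   # mild deviation, p away from 0/1
  ours <- ks_normality(x, n_mc = 4000, seed = 9)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_lt(abs(ours$p_value - ref$p.value), 0.05)
})
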