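test_that("the sampling grid tiles the extent and drops empty plots", {
  big <- lr(matrix(1L, 300, 300))
  g <- make_risk_grid(big)
  expect_equal(nrow(g$plots), 225)             # 15 x 15 plots of 20 km
  small <- lr(matrix(1L, 100, 100))
  expect_equal(nrow(make_risk_grid(small)$plots), 25)
  expect_error(make_risk_grid(lr(matrix(1L, 10, 10))), "smaller than one")
  expect_error(make_risk_grid(lr(matrix(0L, 40, 40))), "no valid cells")
  # a plot below the valid-data floor is dropped
  v <- matrix(1L, 40, 40)
  v[1:20, 1:20] <- 0L
  v[1, 1] <- 1L  # 1/400 valid < 10%
  expect_equal(nrow(make_risk_grid(lr(v))$plots), 3)
})

test_that("patch counting uses 8-connectivity", {
  board <- matrix(rep(c(1L, 2L), 8), 4, 4)     # checkerboard columns
  board[] <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1L, 2L))
  np <- count_patches(board)
  expect_equal(unname(np[1:2]), c(1L, 1L))     # diagonals connect each colour
  # two separated blocks of one class
  two <- matrix(2L, 5, 5)
  two[1:2, 1:2] <- 1L
  two[4:5, 4:5] <- 1L
  expect_equal(unname(count_patches(two)[1]), 2L)
  expect_equal(unname(count_patches(two)[3]), 0L)
})

test_that("per-plot statistics and indices match hand arithmetic", {
  # one 20x20 plot wholly covered by a single 400 km2 forest patch
  solo <- lr(matrix(2L, 20, 20))
  g <- make_risk_grid(solo)
  st <- patch_statistics(solo, g)
  expect_equal(st$grid_stats$N, 1)
  expect_equal(st$grid_stats$M, 1)
  expect_equal(unname(st$grid_stats$m[["forest"]]), 1)
  idx <- landscape_indices(st)
  expect_equal(idx$C, 1 / 400)
  expect_equal(idx$S, (400 / 800) * sqrt(1 / 400))
  expect_equal(idx$K, 1.0)
  expect_equal(idx$I, 0.5 * 0.0025 + 0.3 * 0.025 + 0.2 * 1.0)
  # weights (0.5, 0.3, 0.2) on unit indices give a unit disturbance
  fake <- st
  expect_equal(sum(c(0.5, 0.3, 0.2) * c(1, 1, 1)), 1)
  # doubling the patch count doubles fragmentation at fixed area
  st2 <- st
  st2$per_plot$n_patches <- st2$per_plot$n_patches * 2L
  st2$grid_stats$N <- st2$grid_stats$N * 2
  idx2 <- landscape_indices(st2)
  expect_equal(idx2$C, 2 * idx$C)
})

test_that("vulnerability ranks normalise to the published constants", {
  E <- vulnerability()
  expect_equal(sum(E), 1, tolerance = 1e-12)
  expect_equal(unname(E[["cultivated"]]), 6 / 21)
  expect_equal(unname(E[["construction"]]), 1 / 21)
  expect_equal(unname(vulnerability("water")), 2 / 21)
  expect_error(vulnerability("swamp"), "unknown class")
})

test_that("plot ERI equals the explicit area-weighted loss-index sum", {
  # single-class plot: ERI = (A_i/A_n) I E = I * E
  solo <- lr(matrix(4L, 20, 20))
  out <- assess_risk(solo, cell_km = 20)
  expect_equal(out$eri$eri, out$indices$I * unname(vulnerability("water")))
  # mixed landscape: recompute from the formula, independently
  cfg <- synth_config(n_rows = 60, n_cols = 60, seed = 19)
  m <- generate_base_landscape(cfg)
  a <- assess_risk(m, cell_km = 20)
  E <- vulnerability()
  manual <- sapply(split(a$indices, a$indices$plot_id), function(df) {
    An <- a$grid$plots$An_km2[a$grid$plots$plot_id == df$plot_id[1]]
    sum(df$Ai_km2 / An * df$I * E[df$class])
  })
  expect_equal(a$eri$eri, unname(manual[as.character(a$eri$plot_id)]),
               tolerance = 1e-12)
  expect_true(all(a$eri$eri >= 0))
})

test_that("scaling all areas rescales fragmentation but not dominance ratios", {
  cfg <- synth_config(n_rows = 40, n_cols = 40, seed = 29)
  m1 <- generate_base_landscape(cfg)
  m2 <- land_raster(m1$values, cell_size_m = 2000)   # areas x4
  g1 <- make_risk_grid(m1, cell_km = 20)
  g2 <- make_risk_grid(m2, cell_km = 40)             # same cell partition
  i1 <- landscape_indices(patch_statistics(m1, g1))
  i2 <- landscape_indices(patch_statistics(m2, g2))
  expect_equal(i2$C, i1$C / 4, tolerance = 1e-12)
  expect_equal(i2$K, i1$K, tolerance = 1e-12)        # ratio terms unchanged
})

test_that("kriging is exact at centroids and handles constant fields", {
  cfg <- synth_config(n_rows = 100, n_cols = 100, seed = 37)
  m <- generate_base_landscape(cfg)
  a <- assess_risk(m, cell_km = 20)
  coords <- as.matrix(a$eri[, c("x", "y")])
  model <- fit_variogram(coords, a$eri$eri)
  model$nugget <- 0
  pred <- ok_predict(coords, a$eri$eri, coords, model)
  expect_equal(pred, a$eri$eri, tolerance = 1e-6)
  # constant values interpolate to a constant surface
  constv <- rep(0.5, nrow(coords))
  predc <- ok_predict(coords, constv, cbind(runif(20, 0, 1e5),
                                            runif(20, 0, 1e5)), model)
  expect_equal(predc, rep(0.5, 20), tolerance = 1e-9)
})

test_that("kriging beats IDW on a smooth trend (cross-validation)", {
  set.seed(51)
  xy <- as.matrix(expand.grid(x = seq(0, 1e5, length.out = 12),
                              y = seq(0, 1e5, length.out = 12)))
  z <- 0.01 + 2e-8 * xy[, 1] + 1e-8 * xy[, 2] + rnorm(nrow(xy), sd = 1e-4)
  hold <- seq(5, 144, by = 12)
  tr <- setdiff(seq_len(nrow(xy)), hold)
  model <- fit_variogram(xy[tr, ], z[tr])
  pk <- ok_predict(xy[tr, ], z[tr], xy[hold, ], model)
  pi <- idw_predict(xy[tr, ], z[tr], xy[hold, ])
  rmse <- function(p) sqrt(mean((p - z[hold])^2))
  expect_lt(rmse(pk), rmse(pi))
})

test_that("natural breaks match an exhaustive-search oracle", {
  expect_equal(jenks_breaks(c(1, 1, 1, 10, 10, 10), 2), 1)
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(8:12, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < 5) next
    jb <- jenks_breaks(x, 5)
    bf <- brute_jenks(x, 5)
    expect_equal(partition_ssq(x, jb), bf$ssq, tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("risk surfaces classify into five labelled bands", {
  v <- matrix(c(0.009, 0.011, 0.0125, 0.014, 0.016, 0.02), 2, 3)
  cls <- classify_risk(v, breaks = "default")
  expect_equal(as.numeric(cls$classes), c(1, 2, 3, 4, 5, 5))
  expect_equal(cls$labels, c("low", "lower", "medium", "higher", "high"))
  # jenks path on a surface with two obvious groups
  v2 <- matrix(c(rep(1, 10), rep(2, 10), rep(5, 10), rep(9, 10), rep(20, 10)),
               5, 10)
  cls2 <- classify_risk(v2, breaks = "jenks")
  expect_equal(length(unique(as.numeric(cls2$classes))), 5)
})
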