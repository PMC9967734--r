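test_that("transition estimation reproduces hand counts", {
  t0 <- lr(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE))
  t1 <- lr(matrix(c(1, 2, 2, 2), 2, 2, byrow = TRUE))
  m <- estimate_transition(t0, t1)
  expect_equal(m$area_matrix[1, 1], 1)
  expect_equal(m$area_matrix[1, 2], 1)
  expect_equal(m$area_matrix[2, 2], 2)
  expect_equal(unname(m$prob_matrix[1, ]), c(0.5, 0.5, 0, 0, 0, 0))
  # absent classes get identity rows
  expect_equal(unname(m$prob_matrix[4, ]), c(0, 0, 0, 1, 0, 0))
  # identical maps give the identity matrix
  expect_equal(unname(estimate_transition(t0, t0)$prob_matrix), diag(6))
  # area-matrix row sums equal epoch-1 class counts
  expect_equal(rowSums(m$area_matrix), as.numeric(class_counts(t0)),
               ignore_attr = TRUE)
})

test_that("Markov demand projection matches a naive matrix-power loop", {
  set.seed(42)
  v <- sample(1:6, 3600, replace = TRUE)
  t0 <- lr(v, 60, 60)
  P <- default_transition_matrix()
  model <- structure(list(prob_matrix = P, period_years = 10L),
                     class = "transition_model")
  for (steps in c(1L, 3L)) {
    tg <- project_class_areas(model, t0, steps)
    expect_equal(sum(tg), 3600)
    n0 <- as.numeric(class_counts(t0))
    expected <- n0
    for (s in seq_len(steps)) expected <- as.numeric(expected %*% P)
    expect_true(all(abs(tg - expected) <= 1))  # largest-remainder rounding
  }
  # identity matrix leaves counts unchanged
  mid <- structure(list(prob_matrix = diag(6), period_years = 10L),
                   class = "transition_model")
  expect_equal(as.numeric(project_class_areas(mid, t0, 1L)),
               as.numeric(class_counts(t0)))
  # uniform matrix splits cells evenly
  mu <- structure(list(prob_matrix = matrix(1 / 6, 6, 6), period_years = 10L),
                  class = "transition_model")
  expect_equal(as.numeric(project_class_areas(mu, t0, 1L)), rep(600, 6))
})

steep_drivers <- function(nr = 10, nc = 10) {
  d <- list(
    elevation = matrix(500, nr, nc), slope = matrix(5, nr, nc),
    temperature = matrix(3, nr, nc), precipitation = matrix(600, nr, nc),
    popdens = matrix(10, nr, nc), gdp = matrix(50, nr, nc),
    dist_national = matrix(2, nr, nc), dist_provincial = matrix(2, nr, nc),
    dist_highway = matrix(2, nr, nc),
    blacksoil = matrix(FALSE, nr, nc))
  class(d) <- "driver_stack"
  d
}

test_that("NP masks allow everything; BCU encodes the conservation rules", {
  d <- steep_drivers()
  d$slope[1, 1] <- 20        # steep cultivated cell
  d$slope[2, 2] <- 20        # steep forest cell
  d$blacksoil[5, 5] <- TRUE  # black-soil forest cell
  v <- matrix(2L, 10, 10)    # forest everywhere ...
  v[1, 1] <- 1L; v[3, 3] <- 1L  # ... except two cultivated cells
  v[6, 6] <- 5L              # and one construction cell
  map <- lr(v)

  np <- apply_scenario_constraints(scenario_rules("NP"), d, map)
  expect_true(all(vapply(np, function(m) all(m == 1), logical(1))))

  bcu <- apply_scenario_constraints(scenario_rules("BCU"), d, map)
  # steep cultivated cell: only forest/grassland conversions remain open
  expect_equal(bcu$forest[1, 1], 1)
  expect_equal(bcu$grassland[1, 1], 1)
  expect_equal(bcu$water[1, 1], 0)
  expect_equal(bcu$construction[1, 1], 0)
  expect_equal(bcu$unutilized[1, 1], 0)
  # flat cultivated cell is fully locked in
  expect_true(all(vapply(setdiff(names(bcu), "cultivated"),
                         function(j) bcu[[j]][3, 3] == 0, logical(1))))
  # steep non-cultivated cells may not become cultivated
  expect_equal(bcu$cultivated[2, 2], 0)
  # green cells may not become construction; black soil bars construction
  expect_equal(bcu$construction[4, 4], 0)
  expect_equal(bcu$construction[5, 5], 0)
  # existing construction cell (non-green, off black soil) is unconstrained
  expect_equal(bcu$construction[6, 6], 1)
  # missing drivers are an error under BCU
  d2 <- d; d2$slope <- NULL
  expect_error(apply_scenario_constraints(scenario_rules("BCU"), d2, map),
               "slope")
})

test_that("suitability is a masked weighted sum of rescaled drivers", {
  d <- steep_drivers(6, 6)
  masks <- apply_scenario_constraints(scenario_rules("NP"), d, lr(matrix(2L, 6, 6)))
  # all drivers constant: rescaling is defined to give 0.5 everywhere
  atlas <- build_suitability(d, masks)
  expect_true(all(abs(atlas$suitability$forest - 0.5) < 1e-12))
  # zero mask forces zero suitability
  masks$forest[] <- 0
  atlas0 <- build_suitability(d, masks)
  expect_true(all(atlas0$suitability$forest == 0))
  # two informative drivers at weights (0.5, 0.5) average their rescaled values
  d$elevation <- matrix(seq(0, 1, length.out = 36), 6, 6)  # rescales to itself
  d$gdp <- matrix(rep(c(0, 1), 18), 6, 6)
  W <- matrix(0, 6, 9, dimnames = dimnames(default_suitability_orientations()))
  W[, "elevation"] <- 0.5; W[, "gdp"] <- 0.5
  O <- default_suitability_orientations(); O[] <- 1
  masks2 <- apply_scenario_constraints(scenario_rules("NP"), d, lr(matrix(2L, 6, 6)))
  atlas2 <- build_suitability(d, masks2, weights = W, orientations = O)
  expect_equal(atlas2$suitability$water,
               0.5 * d$elevation + 0.5 * d$gdp, tolerance = 1e-12)
  expect_error(build_suitability(d[-2], masks2), "missing drivers")
})

test_that("CA allocation conserves mass and honours zero demand", {
  set.seed(1)
  v <- sample(1:6, 400, replace = TRUE)
  map <- lr(v, 20, 20)
  d <- steep_drivers(20, 20)
  masks <- apply_scenario_constraints(scenario_rules("NP"), d, map)
  atlas <- build_suitability(d, masks)
  tg <- class_counts(map)
  out <- simulate_ca(map, tg, atlas, seed = 5)
  expect_identical(out$values, map$values)  # zero demand leaves the map alone
  expect_equal(attr(out, "shortfall"), setNames(rep(0, 6), names(LU_CLASSES)))
  # single-class map with unchanged target
  mono <- lr(rep(2L, 400), 20, 20)
  out2 <- simulate_ca(mono, class_counts(mono), atlas, seed = 5)
  expect_identical(out2$values, mono$values)
  # infeasible totals are rejected
  expect_error(simulate_ca(map, tg + 1, atlas, seed = 5), "sum")
})

test_that("CA hits feasible Markov targets and never crosses a mask", {
  cfg <- synth_config(n_rows = 80, n_cols = 80, seed = 13)
  t0 <- generate_base_landscape(cfg)
  t1 <- evolve_landscape(t0, cfg)
  d <- generate_drivers(cfg, t0)
  model <- estimate_transition(t0, t1)
  tg <- project_class_areas(model, t1, 1L)
  masks <- apply_scenario_constraints(scenario_rules("NP"), d, t1)
  atlas <- build_suitability(d, masks)
  sim <- simulate_ca(t1, tg, atlas, seed = 7)
  expect_true(all(abs(class_counts(sim) - tg) <= 0.01 * sum(tg)))
  expect_equal(sum(class_counts(sim)), sum(class_counts(t1)))

  # BCU: exhaustive post-hoc scan finds no forbidden transition
  masks_b <- apply_scenario_constraints(scenario_rules("BCU"), d, t1)
  atlas_b <- build_suitability(d, masks_b)
  sim_b <- simulate_ca(t1, tg, atlas_b, seed = 7)
  moved <- which(sim_b$values != t1$values)
  for (cell in moved)
    expect_equal(masks_b[[sim_b$values[cell]]][cell], 1)
})

test_that("raising a candidate's suitability never demotes it", {
  set.seed(3)
  v <- sample(c(1L, 2L), 400, replace = TRUE, prob = c(0.5, 0.5))
  map <- lr(v, 20, 20)
  d <- steep_drivers(20, 20)
  masks <- apply_scenario_constraints(scenario_rules("NP"), d, map)
  atlas <- build_suitability(d, masks)
  tg <- class_counts(map)
  shift <- min(60, tg[["cultivated"]] - 1)
  tg[["forest"]] <- tg[["forest"]] + shift
  tg[["cultivated"]] <- tg[["cultivated"]] - shift
  base_run <- simulate_ca(map, tg, atlas, seed = 9)
  won <- which(base_run$values == 2L & map$values == 1L)
  cell <- won[1]
  atlas2 <- atlas
  atlas2$suitability$forest[cell] <- 1  # strictly higher score, same seed
  run2 <- simulate_ca(map, tg, atlas2, seed = 9)
  expect_equal(run2$values[cell], 2L)
})

test_that("kappa matches hand computation and an independent implementation", {
  sim <- lr(rep(c(1L, 1L, 2L, 2L), c(40, 10, 10, 40)), 10, 10)
  ref <- lr(rep(c(1L, 2L, 1L, 2L), c(40, 10, 10, 40)), 10, 10)
  expect_equal(kappa_agreement(sim, ref), 0.6, tolerance = 1e-12)
  expect_equal(kappa_agreement(sim, sim), 1)
  # balanced two-class complement: perfect disagreement
  a <- lr(rep(c(1L, 2L), each = 50), 10, 10)
  b <- lr(rep(c(2L, 1L), each = 50), 10, 10)
  expect_equal(kappa_agreement(a, b), -1)
  skip_if_not_installed("e1071")
  set.seed(10)
  x <- lr(sample(1:6, 900, replace = TRUE), 30, 30)
  y <- lr(sample(1:6, 900, replace = TRUE), 30, 30)
  tab <- table(factor(x$values, 1:6), factor(y$values, 1:6))
  expect_equal(kappa_agreement(x, y), e1071::classAgreement(tab)$kappa,
               tolerance = 1e-12)
})
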