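# small construction helpers and independent oracles used across tests

lr <- function(x, nr = NULL, nc = NULL, cell = 1000) {
  if (!is.matrix(x)) x <- matrix(x, nr, nc)
  land_raster(x, cell_size_m = cell)
}

# a fake plot lattice for weights-matrix tests (no raster needed)
lattice_grid <- function(ngr, ngc) {
  plots <- expand.grid(gc = seq_len(ngc), gr = seq_len(ngr))
  plots <- data.frame(plot_id = seq_len(nrow(plots)),
                      gr = plots$gr, gc = plots$gc,
                      x = plots$gc * 1000, y = -plots$gr * 1000)
  structure(list(plots = plots), class = "risk_grid")
}

# population z-score, reimplemented independently of the package
zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# naive double-loop bivariate global Moran (the printed-formula form)
naive_moran_global <- function(xk, xl, W) {
  n <- length(xk)
  Qk <- zs(xk); Ql <- zs(xl)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * Qk[i] * Ql[j]
    S0 <- S0 + W[i, j]
  }
  n * num / ((n - 1) * S0)
}

naive_moran_local <- function(xk, xl, W) {
  n <- length(xk)
  Qk <- zs(xk); Ql <- zs(xl)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + W[i, j] * Ql[j]
    out[i] <- Qk[i] * acc
  }
  out
}

# exhaustive-search optimal 1-D classification (total within-class SSQ)
brute_jenks <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL; best_val <- Inf
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    val <- sum(vapply(seq_len(k), function(g) ssq(x[(b[g] + 1):b[g + 1]]),
                      numeric(1)))
    if (val < best_val) { best_val <- val; best <- cuts[, ci] }
  }
  list(breaks = x[best], ssq = best_val)
}

# total within-class SSQ of a partition of sorted x induced by break values
partition_ssq <- function(x, breaks) {
  x <- sort(x)
  grp <- findInterval(x, breaks, left.open = TRUE)
  sum(tapply(x, grp, function(v) sum((v - mean(v))^2)))
}
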