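#' Kolmogorov-Smirnov normality check with Lilliefors correction
#'
#' One-sample K-S statistic of the sample against a normal distribution
#' with the sample's own mean and SD. Because the parameters are
#' estimated, the classical K-S p-value is invalid; the p-value is
#' obtained from a seeded Monte-Carlo null distribution of the same
#' statistic (the statistic is pivotal under the normal null, so the null
#' depends only on n and can be precomputed and reused via `null_stats`).
#' Used to gate Spearman-vs-Pearson reporting.
#'
#' @param x numeric sample, n >= 8, non-constant.
#' @param n_mc Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the null simulation.
#' @param null_stats optional precomputed null statistics (from
#'   [ks_null_distribution()]) to avoid re-simulation.
#' @return List `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(x, n_mc = 10000L, seed = 1L, null_stats = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations")
  if (stats::sd(x) == 0) stop("zero-variance sample")
  D <- lilliefors_stat(x)
  if (is.null(null_stats)) null_stats <- ks_null_distribution(n, n_mc, seed)
  p <- (sum(null_stats >= D) + 1) / (length(null_stats) + 1)
  list(statistic = D, p_value = p, n = n)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F0 <- stats::pnorm(z)
  max(seq_len(n) / n - F0, F0 - (seq_len(n) - 1) / n)
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' @param n sample size.
#' @param n_mc replicates.
#' @param seed RNG seed.
#' @return Numeric vector of `n_mc` null statistics.
#' @export
ks_null_distribution <- function(n, n_mc = 10000L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n_mc), function(r) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y equal-length numeric vectors (n >= 3), non-constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Contiguity weights for the sampling grid
#'
#' Queen (default) or rook contiguity on the plot grid, optionally
#' row-standardised. Plots with no neighbours (islands) are flagged with
#' a warning and keep a zero row.
#'
#' @param grid a [make_risk_grid()] result (uses the plot grid row/col).
#' @param scheme `"queen"` (8 neighbours interior) or `"rook"` (4).
#' @param standardize `"row"` or `"none"`.
#' @return Object of class `weights_matrix`: sparse `W` (n x n), scheme,
#'   and the standardisation flag.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook"),
                          standardize = c("row", "none")) {
  scheme <- match.arg(scheme)
  standardize <- match.arg(standardize)
  p <- grid$plots
  n <- nrow(p)
  ii <- integer(0); jj <- integer(0)
  for (a in seq_len(n)) {
    dr <- abs(p$gr - p$gr[a]); dc <- abs(p$gc - p$gc[a])
    nb <- if (scheme == "queen") which(pmax(dr, dc) == 1L)
          else which(dr + dc == 1L)
    ii <- c(ii, rep(a, length(nb))); jj <- c(jj, nb)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(W)
  if (any(rs == 0)) warning(sum(rs == 0), " island unit(s) with no neighbours")
  if (standardize == "row") {
    W <- Matrix::Diagonal(n, x = ifelse(rs > 0, 1 / rs, 0)) %*% W
  }
  structure(list(W = W, scheme = scheme, row_standardized =
                   standardize == "row", plot_id = p$plot_id),
            class = "weights_matrix")
}

# z-standardise with population (1/n) standard deviation
z_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero-variance attribute")
  (x - mean(x)) / s
}

#' Bivariate global Moran's I
#'
#' I = n * sum_ij W_ij Q_ki Q_lj / ((n - 1) * sum_ij W_ij) with Q the
#' population-SD z-scores of the two attributes. `denominator = "geoda"`
#' instead computes the conventional cross-Moran
#' sum_i Q_ki (W Q_l)_i / sum_ij W_ij for cross-checking.
#'
#' @param x_k,x_l non-constant attribute vectors over the spatial units.
#' @param w a [build_weights()] object.
#' @param denominator `"standard"` or `"geoda"`.
#' @return Scalar I; positive values indicate positive spatial
#'   association between x_k and the spatial lag of x_l.
#' @export
moran_bv_global <- function(x_k, x_l, w, denominator = c("standard", "geoda")) {
  denominator <- match.arg(denominator)
  stopifnot(length(x_k) == length(x_l))
  n <- length(x_k)
  if (n < 2) stop("need at least 2 units")
  Qk <- z_pop(x_k); Ql <- z_pop(x_l)
  W <- w$W
  num <- as.numeric(Qk %*% (W %*% Ql))
  S0 <- sum(W)
  if (denominator == "standard") n * num / ((n - 1) * S0)
  else num / S0
}

#' Bivariate local Moran's I
#'
#' I_s(i) = Q_ki * sum_j W_ij Q_lj.
#'
#' @inheritParams moran_bv_global
#' @return Numeric vector of per-unit local statistics.
#' @export
moran_bv_local <- function(x_k, x_l, w) {
  stopifnot(length(x_k) == length(x_l))
  Qk <- z_pop(x_k); Ql <- z_pop(x_l)
  as.numeric(Qk * (w$W %*% Ql))
}

#' LISA cluster classification with conditional permutation
#'
#' Per-unit significance of the bivariate local Moran statistic by
#' conditional permutation: the focal unit's Q_k is held fixed while its
#' neighbours' Q_l values are drawn (without replacement) from the other
#' units, `n_perm` times. The two-sided pseudo p-value is
#' (#(|I*| >= |I_s|) + 1) / (n_perm + 1). Significant units are labelled
#' by the quadrant of (Q_k, lag Q_l): H-H, L-L, L-H or H-L; others N-S.
#'
#' @inheritParams moran_bv_global
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per unit (default 999).
#' @param seed RNG seed.
#' @return data.frame local_i, p_value, cluster
#'   (factor H-H/L-L/L-H/H-L/N-S).
#' @export
lisa_classify <- function(x_k, x_l, w, alpha = 0.05, n_perm = 999L,
                          seed = 1L) {
  n <- length(x_k)
  if (stats::sd(x_l) == 0 || stats::sd(x_k) == 0) {
    warning("constant attribute: all units labelled N-S")
    return(data.frame(local_i = rep(0, n), p_value = rep(1, n),
                      cluster = factor(rep("N-S", n),
                                       levels = c("H-H", "L-L", "L-H",
                                                  "H-L", "N-S"))))
  }
  Qk <- z_pop(x_k); Ql <- z_pop(x_l)
  W <- w$W
  lag <- as.numeric(W %*% Ql)
  obs <- Qk * lag
  Wt <- as(W, "TsparseMatrix")
  nb_list <- split(Wt@j + 1L, Wt@i + 1L)
  wt_list <- split(Wt@x, Wt@i + 1L)
  pvals <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      nb <- nb_list[[as.character(i)]]
      k <- length(nb)
      if (!k) { pvals[i] <- 1; next }
      wts <- wt_list[[as.character(i)]]
      pool <- Ql[-i]
      perm_lag <- vapply(seq_len(n_perm), function(r)
        sum(wts * pool[sample.int(n - 1L, k)]), numeric(1))
      perm_i <- Qk[i] * perm_lag
      pvals[i] <- (sum(abs(perm_i) >= abs(obs[i])) + 1) / (n_perm + 1)
    }
  })
  lab <- rep("N-S", n)
  sig <- pvals <= alpha
  lab[sig & Qk > 0 & lag > 0] <- "H-H"
  lab[sig & Qk < 0 & lag < 0] <- "L-L"
  lab[sig & Qk < 0 & lag > 0] <- "L-H"
  lab[sig & Qk > 0 & lag < 0] <- "H-L"
  data.frame(local_i = obs, p_value = pvals,
             cluster = factor(lab, levels = c("H-H", "L-L", "L-H",
                                              "H-L", "N-S")))
}
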