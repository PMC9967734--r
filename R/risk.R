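#' Build the square sampling grid for risk assessment
#'
#' Partitions the raster extent into axis-aligned square plots of side
#' `cell_km`, clipped to the data footprint. Plots whose valid-cell
#' fraction falls below `min_valid_frac` of the nominal plot size are
#' dropped rather than padded, to avoid inflated separation indices at
#' ragged borders.
#'
#' @param map a [land_raster()].
#' @param cell_km plot side length in km (default 20).
#' @param min_valid_frac minimum fraction of valid cells to keep a plot.
#' @return Object of class `risk_grid`: data.frame `plots` (plot_id, grid
#'   row/col, cell index ranges, valid cell count, valid area `An_km2`,
#'   centroid x/y in metres) plus grid metadata.
#' @export
make_risk_grid <- function(map, cell_km = 20, min_valid_frac = 0.1) {
  stopifnot(inherits(map, "land_raster"))
  k <- as.integer(round(cell_km * 1000 / map$cell_size_m))
  nr <- nrow(map$values); nc <- ncol(map$values)
  if (k < 1 || nr < k || nc < k)
    stop("extent is smaller than one sampling plot")
  ok <- valid_mask(map)
  if (!any(ok)) stop("raster contains no valid cells")
  ngr <- ceiling(nr / k); ngc <- ceiling(nc / k)
  rows <- list()
  id <- 0L
  for (gr in seq_len(ngr)) for (gc in seq_len(ngc)) {
    r0 <- (gr - 1L) * k + 1L; r1 <- min(nr, gr * k)
    c0 <- (gc - 1L) * k + 1L; c1 <- min(nc, gc * k)
    nv <- sum(ok[r0:r1, c0:c1])
    if (nv < min_valid_frac * k * k) next
    id <- id + 1L
    rows[[id]] <- data.frame(
      plot_id = id, gr = gr, gc = gc,
      row0 = r0, row1 = r1, col0 = c0, col1 = c1,
      n_valid = nv,
      An_km2 = nv * cell_area_km2(map),
      x = ((c0 + c1) / 2 - 0.5) * map$cell_size_m,
      y = (nr - (r0 + r1) / 2 + 0.5) * map$cell_size_m)
  }
  if (!id) stop("no plot reaches the minimum valid-data fraction")
  structure(list(plots = do.call(rbind, rows), cell_km = cell_km,
                 k_cells = k, n_rows = nr, n_cols = nc,
                 cell_size_m = map$cell_size_m),
            class = "risk_grid")
}

#' Count 8-connected same-value patches in a categorical matrix
#'
#' Connected-component count per class within a (small) window, using
#' flood fill with 8-connectivity (diagonals connect).
#'
#' @param values integer matrix (0 = nodata).
#' @param classes which class codes to count (default 1:6).
#' @return Named integer vector of patch counts per class.
#' @export
count_patches <- function(values, classes = 1:6) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  counts <- integer(length(classes))
  names(counts) <- as.character(classes)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    todo <- which(values == cl & lab == 0L)
    for (start in todo) {
      if (lab[start] != 0L) next
      counts[ci] <- counts[ci] + 1L
      stack <- start
      lab[start] <- counts[ci]
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        r <- ((cur - 1L) %% nr) + 1L
        cc <- ((cur - 1L) %/% nr) + 1L
        rr <- r + nb_dr; ccn <- cc + nb_dc
        keep <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
        nbr <- (ccn[keep] - 1L) * nr + rr[keep]
        nbr <- nbr[values[nbr] == cl & lab[nbr] == 0L]
        if (length(nbr)) {
          lab[nbr] <- counts[ci]
          stack <- c(stack, nbr)
        }
      }
    }
    lab[] <- 0L
  }
  counts
}

#' Per-plot and grid-wide patch statistics
#'
#' For every plot and land-use class: the 8-connected patch count `n_i`
#' and class area `Ai_km2`. Grid-wide: the total patch count N, the plot
#' count M, the number of plots `m_i` in which each class occurs, and the
#' total valid area A over all plots.
#'
#' @param map a [land_raster()].
#' @param grid a [make_risk_grid()] result.
#' @return List with `per_plot` (data.frame plot_id, class, n_patches,
#'   Ai_km2) and `grid_stats` (N, M, m, A_km2).
#' @export
patch_statistics <- function(map, grid) {
  stopifnot(inherits(map, "land_raster"), inherits(grid, "risk_grid"))
  areakm <- cell_area_km2(map)
  per <- vector("list", nrow(grid$plots))
  for (i in seq_len(nrow(grid$plots))) {
    p <- grid$plots[i, ]
    win <- map$values[p$row0:p$row1, p$col0:p$col1, drop = FALSE]
    np <- count_patches(win)
    ar <- tabulate(win[win != 0L], nbins = 6L) * areakm
    per[[i]] <- data.frame(plot_id = p$plot_id, class = names(LU_CLASSES),
                           n_patches = as.integer(np), Ai_km2 = ar,
                           row.names = NULL)
  }
  per <- do.call(rbind, per)
  m <- vapply(names(LU_CLASSES), function(cl)
    sum(per$n_patches[per$class == cl] > 0), integer(1))
  grid_stats <- list(N = sum(per$n_patches), M = nrow(grid$plots),
                     m = m, A_km2 = sum(grid$plots$An_km2))
  list(per_plot = per, grid_stats = grid_stats)
}

#' Landscape fragmentation, separation, dominance and disturbance indices
#'
#' Per plot and class with positive area: fragmentation C_i = n_i / A_i;
#' separation S_i = (A / (2 A_i)) * sqrt(n_i / A); dominance
#' K_i = (n_i/N + m_i/M)/4 + (A_i/A)/2; disturbance
#' I_i = a C_i + b S_i + c K_i with default weights a = 0.5, b = 0.3,
#' c = 0.2. A, N, M and m_i are grid-wide totals.
#'
#' @param stats a [patch_statistics()] result.
#' @param weights length-3 disturbance weights (a, b, c), summing to 1.
#' @return data.frame plot_id, class, n_patches, Ai_km2, C, S, K, I
#'   (classes absent from a plot are omitted).
#' @export
landscape_indices <- function(stats, weights = c(0.5, 0.3, 0.2)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("disturbance weights must sum to 1")
  per <- stats$per_plot
  gs <- stats$grid_stats
  per <- per[per$Ai_km2 > 0, , drop = FALSE]
  A <- gs$A_km2
  per$C <- per$n_patches / per$Ai_km2
  per$S <- (A / (2 * per$Ai_km2)) * sqrt(per$n_patches / A)
  per$K <- (per$n_patches / gs$N + gs$m[per$class] / gs$M) / 4 +
    (per$Ai_km2 / A) / 2
  per$I <- weights[1] * per$C + weights[2] * per$S + weights[3] * per$K
  rownames(per) <- NULL
  per
}

#' Landscape vulnerability index E_i
#'
#' Rank normalisation over the six classes: construction (built-up) 1,
#' water 2, grassland 3, forest 4, unutilized 5, cultivated (cropland) 6,
#' each divided by the rank sum 21.
#'
#' @param class class name(s) or code(s) 1-6; default all six classes.
#' @return Named numeric vector of E_i values (sums to 1 over all six).
#' @export
vulnerability <- function(class = names(LU_CLASSES)) {
  ranks <- c(cultivated = 6, forest = 4, grassland = 3, water = 2,
             construction = 1, unutilized = 5)
  if (is.numeric(class)) class <- names(LU_CLASSES)[class]
  if (any(is.na(class)) || !all(class %in% names(ranks)))
    stop("unknown class")
  ranks[class] / sum(ranks)
}

#' Per-plot ecological risk index
#'
#' ERI = sum over classes of (A_i / A_n) * R_i, where the loss index
#' R_i = I_i * E_i couples the disturbance index with the class
#' vulnerability.
#'
#' @param indices a [landscape_indices()] table.
#' @param grid the [make_risk_grid()] used to compute it.
#' @return data.frame plot_id, x, y, eri.
#' @export
plot_eri <- function(indices, grid) {
  E <- vulnerability()
  An <- grid$plots$An_km2[match(indices$plot_id, grid$plots$plot_id)]
  r <- (indices$Ai_km2 / An) * indices$I * E[indices$class]
  eri <- tapply(r, indices$plot_id, sum)
  out <- grid$plots[, c("plot_id", "x", "y")]
  out$eri <- as.numeric(eri[as.character(out$plot_id)])
  out$eri[is.na(out$eri)] <- 0
  rownames(out) <- NULL
  out
}

#' Landscape ecological risk per plot (convenience wrapper)
#'
#' Runs [make_risk_grid()], [patch_statistics()], [landscape_indices()]
#' and [plot_eri()] in one call.
#'
#' @param map a [land_raster()].
#' @param cell_km plot side in km.
#' @return List with `grid`, `indices`, `eri` (data.frame with centroids).
#' @export
assess_risk <- function(map, cell_km = 20) {
  grid <- make_risk_grid(map, cell_km = cell_km)
  stats <- patch_statistics(map, grid)
  idx <- landscape_indices(stats)
  list(grid = grid, indices = idx, eri = plot_eri(idx, grid))
}

# ---- variogram + ordinary kriging --------------------------------------

#' Fit a spherical variogram to point data
#'
#' Empirical semivariogram on 12 equal-width lag bins up to half the
#' maximum pairwise distance, then weighted least squares (weights
#' N_h / h^2) for the spherical model parameters (nugget, partial sill,
#' range).
#'
#' @param coords n x 2 matrix of point coordinates.
#' @param values numeric vector of length n.
#' @param n_lags number of lag bins (default 12).
#' @return List `nugget`, `psill`, `range`, plus the empirical bins.
#' @export
fit_variogram <- function(coords, values, n_lags = 12L) {
  d <- as.matrix(stats::dist(coords))
  iu <- upper.tri(d)
  h <- d[iu]
  g <- 0.5 * (outer(values, values, "-")[iu])^2
  cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  bins <- cut(h, breaks = seq(0, cutoff, length.out = n_lags + 1L),
              include.lowest = TRUE)
  hb <- tapply(h, bins, mean)
  gb <- tapply(g, bins, mean)
  nb <- tapply(h, bins, length)
  okb <- !is.na(gb)
  hb <- hb[okb]; gb <- gb[okb]; nb <- nb[okb]
  w <- nb / hb^2
  obj <- function(par) {
    mod <- spherical_gamma(hb, par[1], par[2], par[3])
    sum(w * (gb - mod)^2)
  }
  s0 <- stats::var(values)
  fit <- stats::optim(c(nugget = 0, psill = max(s0, 1e-12),
                        range = cutoff / 2), obj,
                      method = "L-BFGS-B",
                      lower = c(0, 1e-12, min(hb) / 10))
  list(nugget = unname(fit$par[1]), psill = unname(fit$par[2]),
       range = unname(fit$par[3]),
       empirical = data.frame(h = as.numeric(hb), gamma = as.numeric(gb),
                              n = as.numeric(nb)))
}

spherical_gamma <- function(h, nugget, psill, range) {
  out <- nugget + psill * ifelse(h >= range, 1,
                                 1.5 * h / range - 0.5 * (h / range)^3)
  out[h == 0] <- 0
  out
}

#' Ordinary-kriging prediction
#'
#' Exact interpolator (with zero nugget) solving the standard OK system
#' built from the spherical variogram. Falls back to [idw_predict()] with
#' a warning if the kriging system is singular.
#'
#' @param coords,values data locations and values.
#' @param newcoords m x 2 matrix of prediction locations.
#' @param model a [fit_variogram()] model (fitted from the data when NULL).
#' @param jitter_seed seed for the tiny jitter applied to duplicated
#'   data locations.
#' @return Numeric vector of m predictions.
#' @export
ok_predict <- function(coords, values, newcoords, model = NULL,
                       jitter_seed = 1L) {
  coords <- as.matrix(coords)
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) {
    with_seed(jitter_seed, {
      coords <- coords + matrix(stats::rnorm(length(coords), sd = 1e-6),
                                nrow(coords))
    })
  }
  if (is.null(model)) model <- fit_variogram(coords, values)
  n <- nrow(coords)
  G <- spherical_gamma(as.matrix(stats::dist(coords)),
                       model$nugget, model$psill, model$range)
  K <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Kinv <- tryCatch(solve(K), error = function(e) NULL)
  if (is.null(Kinv)) {
    warning("singular kriging system; falling back to IDW")
    return(idw_predict(coords, values, newcoords))
  }
  newcoords <- as.matrix(newcoords)
  out <- numeric(nrow(newcoords))
  chunk <- max(1L, floor(4e6 / n))
  i <- 1L
  while (i <= nrow(newcoords)) {
    j <- min(nrow(newcoords), i + chunk - 1L)
    d0 <- sqrt(outer(newcoords[i:j, 1], coords[, 1], "-")^2 +
               outer(newcoords[i:j, 2], coords[, 2], "-")^2)
    g0 <- cbind(spherical_gamma(d0, model$nugget, model$psill, model$range), 1)
    lam <- g0 %*% Kinv
    out[i:j] <- as.numeric(lam[, seq_len(n), drop = FALSE] %*% values)
    i <- j + 1L
  }
  out
}

#' Inverse-distance-weighted prediction (power 2)
#'
#' @param coords,values data locations and values.
#' @param newcoords prediction locations.
#' @param power IDW exponent.
#' @export
idw_predict <- function(coords, values, newcoords, power = 2) {
  coords <- as.matrix(coords); newcoords <- as.matrix(newcoords)
  out <- numeric(nrow(newcoords))
  for (i in seq_len(nrow(newcoords))) {
    d <- sqrt((coords[, 1] - newcoords[i, 1])^2 +
              (coords[, 2] - newcoords[i, 2])^2)
    if (any(d == 0)) { out[i] <- values[which.min(d)]; next }
    w <- 1 / d^power
    out[i] <- sum(w * values) / sum(w)
  }
  out
}

#' Interpolate plot ERI values to a raster surface
#'
#' Assigns each plot's ERI to its centroid and interpolates to the cell
#' centres of the source raster geometry by ordinary kriging (default)
#' or IDW.
#'
#' @param eri a [plot_eri()] table (plot_id, x, y, eri).
#' @param grid the [make_risk_grid()] carrying the raster geometry.
#' @param method `"kriging"` or `"idw"`.
#' @return Object of class `risk_surface`: `values` matrix plus the
#'   variogram `model` (kriging only).
#' @export
interpolate_surface <- function(eri, grid, method = c("kriging", "idw")) {
  method <- match.arg(method)
  if (nrow(eri) < 10) stop("need at least 10 plots to interpolate")
  coords <- as.matrix(eri[, c("x", "y")])
  nr <- grid$n_rows; nc <- grid$n_cols
  xy <- cell_xy(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr),
                grid$cell_size_m, nr)
  model <- NULL
  if (method == "kriging") {
    model <- fit_variogram(coords, eri$eri)
    z <- ok_predict(coords, eri$eri, xy, model)
  } else {
    z <- idw_predict(coords, eri$eri, xy)
  }
  structure(list(values = matrix(z, nr, nc), model = model, method = method),
            class = "risk_surface")
}

# ---- natural breaks -----------------------------------------------------

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification minimising total within-class sum of squared
#' deviations, by dynamic programming over the sorted values. For more
#' than `max_n` values a deterministic order-statistics thinning is
#' applied first (every m-th sorted value), which leaves the break
#' positions essentially unchanged for smooth distributions.
#'
#' @param x numeric vector.
#' @param k number of classes.
#' @param max_n maximum number of values used exactly.
#' @return Numeric vector of k - 1 interior break values (class upper
#'   bounds; a value v belongs to class j if breaks[j-1] < v <= breaks[j]).
#' @export
jenks_breaks <- function(x, k, max_n = 2000L) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (length(unique(x)) < k) stop("fewer distinct values than classes")
  if (n > max_n) {
    idx <- unique(round(seq(1, n, length.out = max_n)))
    x <- x[idx]
    n <- length(x)
  }
  S1 <- cumsum(x); S2 <- cumsum(x^2)
  ssq <- function(i, j) {
    # within-group SSQ of x[i..j], vectorised over i
    s1 <- S1[j] - ifelse(i > 1, S1[i - 1], 0)
    s2 <- S2[j] - ifelse(i > 1, S2[i - 1], 0)
    s2 - s1^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- ssq(1L, j)
  B[1, ] <- 1L
  for (g in 2:k) {
    for (j in g:n) {
      i <- g:j  # first index of group g
      cost <- D[g - 1, i - 1] + ssq(i, j)
      best <- which.min(cost)
      D[g, j] <- cost[best]
      B[g, j] <- i[best]
    }
  }
  # backtrack group boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (g in k:2) {
    i <- B[g, j]
    breaks[g - 1] <- x[i - 1]
    j <- i - 1
  }
  breaks
}

#' Risk band thresholds used for reporting
#'
#' Interior thresholds for the five bands low / lower / medium / higher /
#' high: 0.010, 0.012, 0.013, 0.015.
#' @export
RISK_BREAKS_DEFAULT <- c(0.010, 0.012, 0.013, 0.015)

#' Classify a risk surface into five bands
#'
#' @param surface a [interpolate_surface()] result or numeric matrix.
#' @param breaks `"default"` (the reporting thresholds in
#'   [RISK_BREAKS_DEFAULT]), `"jenks"` (data-driven natural breaks), or a
#'   numeric vector of 4 interior thresholds.
#' @return Object of class `risk_classes`: integer matrix 1-5 (NA where
#'   the surface is NA), `breaks`, and the band `labels`.
#' @export
classify_risk <- function(surface, breaks = "default") {
  v <- if (inherits(surface, "risk_surface")) surface$values else surface
  if (is.character(breaks)) {
    breaks <- switch(match.arg(breaks, c("default", "jenks")),
                     default = RISK_BREAKS_DEFAULT,
                     jenks = jenks_breaks(as.numeric(v), 5L))
  }
  if (length(breaks) != 4L) stop("need 4 interior thresholds for 5 bands")
  cls <- matrix(findInterval(v, breaks, left.open = TRUE) + 1L,
                nrow(v), ncol(v))
  cls[is.na(v)] <- NA_integer_
  structure(list(classes = cls, breaks = breaks,
                 labels = c("low", "lower", "medium", "higher", "high")),
            class = "risk_classes")
}
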