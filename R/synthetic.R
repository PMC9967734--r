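#' Synthetic-landscape configuration
#'
#' Bundles every parameter of the synthetic study system: grid size, the
#' target class proportions, the spatial autocorrelation range of the
#' underlying random field, the ground-truth class-transition matrix used to
#' evolve the landscape to a second epoch, the black-soil area fraction, and
#' the master seed. All generator outputs are pure functions of this object.
#'
#' Defaults describe a cultivated/forest-dominated provincial landscape at
#' 1 km resolution on a 300 x 300 grid; see the methods vignette for the
#' rationale behind each default.
#'
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param cell_size_m cell edge length in metres.
#' @param class_proportions length-6 non-negative vector summing to 1
#'   (cultivated, forest, grassland, water, construction, unutilized).
#' @param autocorr_range_cells Gaussian smoothing sigma, in cells, of the
#'   latent field; larger values give larger coherent patches.
#' @param true_transition_matrix 6x6 row-stochastic matrix; row i gives the
#'   per-period probabilities of a class-i cell transitioning to each class.
#' @param seed master integer seed.
#' @param blacksoil_fraction fraction of the grid covered by the contiguous
#'   black-soil region.
#' @param driver_noise_sd standard deviation of the white-noise component
#'   added to the continuous driver surfaces.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_rows = 300, n_cols = 300, cell_size_m = 1000,
                         class_proportions = c(0.35, 0.38, 0.08, 0.04, 0.09, 0.06),
                         autocorr_range_cells = 6,
                         true_transition_matrix = default_transition_matrix(),
                         seed = 1L,
                         blacksoil_fraction = 0.25,
                         driver_noise_sd = 1) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  p <- as.numeric(class_proportions)
  if (length(p) != 6L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be 6 non-negative fractions summing to 1")
  P <- as.matrix(true_transition_matrix)
  if (!identical(dim(P), c(6L, 6L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("true_transition_matrix must be 6x6 row-stochastic")
  if (autocorr_range_cells <= 0) stop("autocorr_range_cells must be positive")
  if (blacksoil_fraction < 0 || blacksoil_fraction > 1)
    stop("blacksoil_fraction must be in [0, 1]")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_m = as.numeric(cell_size_m),
    class_proportions = p,
    autocorr_range_cells = as.numeric(autocorr_range_cells),
    true_transition_matrix = P,
    seed = as.integer(seed),
    blacksoil_fraction = as.numeric(blacksoil_fraction),
    driver_noise_sd = as.numeric(driver_noise_sd)
  ), class = "synth_config")
}

#' Default ground-truth transition matrix
#'
#' Strongly diagonal (classes mostly persist over one period) with modest
#' cultivated/forest/grassland interchange, conversion pressure toward
#' construction, and slow reclamation of unutilized land.
#'
#' @return 6x6 row-stochastic matrix with class-name dimnames.
#' @export
default_transition_matrix <- function() {
  P <- matrix(c(
    # to: cult  forest grass  water constr unutil
    0.870, 0.040, 0.030, 0.005, 0.045, 0.010,  # cultivated
    0.050, 0.900, 0.030, 0.005, 0.010, 0.005,  # forest
    0.100, 0.060, 0.790, 0.010, 0.020, 0.020,  # grassland
    0.020, 0.010, 0.020, 0.920, 0.010, 0.020,  # water
    0.010, 0.005, 0.005, 0.000, 0.975, 0.005,  # construction
    0.060, 0.040, 0.050, 0.010, 0.020, 0.820), # unutilized
    nrow = 6, byrow = TRUE,
    dimnames = list(names(LU_CLASSES), names(LU_CLASSES)))
  P
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gaussian-smoothed white noise: separable convolution with a Gaussian
# kernel of standard deviation `sigma` cells, truncated at 3 sigma.
# Edge-normalised (kernel re-weighted by the in-grid mass).
gaussian_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smooth_matrix(z, sigma)
  (f - mean(f)) / stats::sd(f)  # unit variance regardless of sigma
}

smooth_matrix <- function(z, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, k) {
    # convolve each column with k, edge-renormalised
    n <- nrow(m)
    pad <- matrix(0, length(k) %/% 2, ncol(m))
    mp <- rbind(pad, m, pad)
    wp <- rbind(pad, matrix(1, n, ncol(m)), pad)
    num <- apply_kernel_cols(mp, k, n)
    den <- apply_kernel_cols(wp, k, n)
    num / den
  }
  z1 <- conv1(z, k)
  t(conv1(t(z1), k))
}

apply_kernel_cols <- function(mp, k, n_out) {
  out <- matrix(0, n_out, ncol(mp))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n_out - 1L), , drop = FALSE]
  out
}

#' Generate the first-epoch land-use raster
#'
#' Thresholds a Gaussian-smoothed white-noise field at the empirical
#' quantiles implied by `class_proportions`, producing a spatially
#' autocorrelated categorical map whose class fractions match the target.
#'
#' @param config a [synth_config()].
#' @return A [land_raster()].
#' @export
generate_base_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  p <- config$class_proportions
  with_seed(config$seed, {
    f <- gaussian_field(config$n_rows, config$n_cols,
                        config$autocorr_range_cells)
    cp <- cumsum(p)
    # interior breakpoints only for classes with positive mass
    brk <- stats::quantile(f, probs = pmin(cp[-6L], 1))
    cls <- findInterval(f, vec = brk, left.open = TRUE) + 1L
    # findInterval on quantiles can land one past the end at the maximum
    cls[cls > 6L] <- 6L
    # zero-proportion classes collapse onto the previous breakpoint; remap
    # any class whose target proportion is 0 to the nearest positive class
    zero <- which(p == 0)
    if (length(zero)) {
      pos <- which(p > 0)
      for (z in zero) cls[cls == z] <- pos[which.min(abs(pos - z))]
    }
    land_raster(matrix(cls, config$n_rows, config$n_cols),
                cell_size_m = config$cell_size_m)
  })
}

#' Evolve the landscape one period under the ground-truth transition matrix
#'
#' Each valid cell of class i independently draws its second-epoch class
#' from row i of `true_transition_matrix`. This provides the known ground
#' truth against which [estimate_transition()] can be validated.
#'
#' @param base first-epoch [land_raster()].
#' @param config the [synth_config()] holding the matrix and seed.
#' @return Second-epoch [land_raster()].
#' @export
evolve_landscape <- function(base, config) {
  stopifnot(inherits(base, "land_raster"), inherits(config, "synth_config"))
  P <- config$true_transition_matrix
  v <- base$values
  out <- v
  with_seed(config$seed + 1L, {
    for (c in 1:6) {
      idx <- which(v == c)
      if (!length(idx)) next
      out[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = P[c, ])
    }
  })
  land_raster(out, cell_size_m = base$cell_size_m)
}

# ---- driver surfaces ----------------------------------------------------

#' Generate continuous driver surfaces and the black-soil mask
#'
#' Produces the nine driver rasters used by the suitability model —
#' elevation, slope (degrees, finite differences from elevation),
#' temperature, precipitation, population density, GDP, and Euclidean
#' distances to three synthetic road networks — plus a contiguous
#' black-soil mask covering `blacksoil_fraction` of the grid. Population
#' and GDP means are tripled inside a randomly placed urban disc so that
#' construction suitability has spatial signal.
#'
#' @param config a [synth_config()].
#' @param base the first-epoch raster (fixes grid geometry).
#' @return Object of class `driver_stack`: named list of numeric matrices
#'   (`elevation`, `slope`, `temperature`, `precipitation`, `popdens`,
#'   `gdp`, `dist_national`, `dist_provincial`, `dist_highway`) and the
#'   logical `blacksoil` matrix.
#' @export
generate_drivers <- function(config, base) {
  stopifnot(inherits(config, "synth_config"), inherits(base, "land_raster"))
  nr <- config$n_rows; nc <- config$n_cols
  sd0 <- config$driver_noise_sd
  with_seed(config$seed + 2L, {
    # two-scale relief: broad ranges plus rough mountain texture so that
    # the slope raster has a realistic tail above the 15-degree threshold
    elev <- 600 + 350 * gaussian_field(nr, nc, 2 * config$autocorr_range_cells) +
      250 * gaussian_field(nr, nc, 1.5) +
      sd0 * matrix(stats::rnorm(nr * nc), nr, nc)
    slope <- slope_from_elevation(elev, config$cell_size_m)
    temp <- 2 + 3 * gaussian_field(nr, nc, 3 * config$autocorr_range_cells) +
      0.1 * sd0 * matrix(stats::rnorm(nr * nc), nr, nc)
    prec <- 550 + 80 * gaussian_field(nr, nc, 3 * config$autocorr_range_cells) +
      sd0 * matrix(stats::rnorm(nr * nc), nr, nc)

    pop <- exp(3 + 0.8 * gaussian_field(nr, nc, config$autocorr_range_cells))
    gdp <- exp(4 + 0.8 * gaussian_field(nr, nc, config$autocorr_range_cells))
    # urban disc: tripled mean for population and GDP
    ctr <- c(stats::runif(1, 0.2, 0.8) * nr, stats::runif(1, 0.2, 0.8) * nc)
    rad <- 0.12 * min(nr, nc)
    dd <- outer(seq_len(nr), seq_len(nc),
                function(i, j) sqrt((i - ctr[1])^2 + (j - ctr[2])^2))
    urban <- dd <= rad
    pop[urban] <- pop[urban] * 3
    gdp[urban] <- gdp[urban] * 3

    roads <- lapply(c(2L, 3L, 2L), function(k) random_polyline_mask(nr, nc, k))
    dists <- lapply(roads, function(m) distance_transform(m) * config$cell_size_m)

    blacksoil <- blacksoil_disc(nr, nc, config$blacksoil_fraction)

    structure(list(
      elevation = elev, slope = slope, temperature = temp,
      precipitation = prec, popdens = pop, gdp = gdp,
      dist_national = dists[[1]], dist_provincial = dists[[2]],
      dist_highway = dists[[3]], blacksoil = blacksoil
    ), class = "driver_stack")
  })
}

#' Slope in degrees from an elevation surface
#'
#' Central finite differences (one-sided at edges) of the elevation grid;
#' slope = atan(|grad|) in degrees.
#'
#' @param elev numeric elevation matrix (metres).
#' @param cell_size_m cell size in metres.
#' @export
slope_from_elevation <- function(elev, cell_size_m) {
  nr <- nrow(elev); nc <- ncol(elev)
  gx <- elev[, pmin(nc, seq_len(nc) + 1L)] - elev[, pmax(1L, seq_len(nc) - 1L)]
  dx <- matrix(rep(ifelse(seq_len(nc) %in% c(1L, nc), 1, 2), each = nr), nr, nc)
  gy <- elev[pmin(nr, seq_len(nr) + 1L), ] - elev[pmax(1L, seq_len(nr) - 1L), ]
  dy <- matrix(rep(ifelse(seq_len(nr) %in% c(1L, nr), 1, 2), nc), nr, nc)
  g <- sqrt((gx / (dx * cell_size_m))^2 + (gy / (dy * cell_size_m))^2)
  atan(g) * 180 / pi
}

# rasterize k random polylines (random waypoint chains) onto a logical mask
random_polyline_mask <- function(n_rows, n_cols, k = 2L) {
  m <- matrix(FALSE, n_rows, n_cols)
  for (line in seq_len(k)) {
    npts <- 4L
    pr <- round(stats::runif(npts, 1, n_rows))
    pc <- round(stats::runif(npts, 1, n_cols))
    for (s in seq_len(npts - 1L)) {
      seg <- bresenham(pr[s], pc[s], pr[s + 1L], pc[s + 1L])
      m[cbind(seg$r, seg$c)] <- TRUE
    }
  }
  m
}

bresenham <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  list(r = round(seq(r0, r1, length.out = n)),
       c = round(seq(c0, c1, length.out = n)))
}

#' Euclidean distance transform from a logical source mask
#'
#' Exact distance (in cell units) from every cell to the nearest TRUE cell,
#' computed by chunked nearest-source search.
#'
#' @param mask logical matrix with at least one TRUE cell.
#' @return numeric matrix of distances (0 on the sources).
#' @export
distance_transform <- function(mask) {
  src <- which(mask, arr.ind = TRUE)
  if (!nrow(src)) stop("mask has no source cells")
  nr <- nrow(mask); nc <- ncol(mask)
  all_r <- rep(seq_len(nr), times = nc)
  all_c <- rep(seq_len(nc), each = nr)
  out <- numeric(nr * nc)
  chunk <- max(1L, floor(4e6 / nrow(src)))
  i <- 1L
  while (i <= length(out)) {
    j <- min(length(out), i + chunk - 1L)
    d2 <- outer(all_r[i:j], src[, 1], "-")^2 + outer(all_c[i:j], src[, 2], "-")^2
    out[i:j] <- sqrt(do.call(pmin, as.data.frame(d2)))
    i <- j + 1L
  }
  matrix(out, nr, nc)
}

# contiguous black-soil region: disc with radius chosen by bisection so the
# clipped area matches the requested fraction
blacksoil_disc <- function(n_rows, n_cols, fraction) {
  if (fraction <= 0) return(matrix(FALSE, n_rows, n_cols))
  if (fraction >= 1) return(matrix(TRUE, n_rows, n_cols))
  ctr <- c(stats::runif(1, 0.3, 0.7) * n_rows, stats::runif(1, 0.3, 0.7) * n_cols)
  dd <- outer(seq_len(n_rows), seq_len(n_cols),
              function(i, j) sqrt((i - ctr[1])^2 + (j - ctr[2])^2))
  target <- fraction * n_rows * n_cols
  lo <- 0; hi <- sqrt(n_rows^2 + n_cols^2)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(dd <= mid) < target) lo <- mid else hi <- mid
  }
  dd <= hi
}

#' Write synthetic inputs to a directory
#'
#' Serialises the land-use epochs, drivers and black-soil mask as ESRI
#' ASCII grids, with a JSON sidecar recording the full configuration.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the list of file paths written.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- generate_base_landscape(config)
  t1 <- evolve_landscape(base, config)
  drv <- generate_drivers(config, base)
  paths <- list()
  paths$t0 <- write_ascii_grid(base, file.path(dir, "landuse_t0.asc"))
  paths$t1 <- write_ascii_grid(t1, file.path(dir, "landuse_t1.asc"))
  for (nm in setdiff(names(drv), "blacksoil"))
    paths[[nm]] <- write_ascii_grid(drv[[nm]], file.path(dir, paste0(nm, ".asc")),
                                    cell_size_m = config$cell_size_m)
  paths$blacksoil <- write_ascii_grid(drv$blacksoil * 1,
                                      file.path(dir, "blacksoil.asc"),
                                      cell_size_m = config$cell_size_m)
  cfg <- unclass(config)
  cfg$true_transition_matrix <- unname(as.data.frame(cfg$true_transition_matrix))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
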