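#' Estimate the Markov transition structure between two epochs
#'
#' Cross-tabulates the two aligned rasters into a 6x6 transfer-area matrix
#' (cell counts) and row-normalises it into a transition probability
#' matrix. Classes absent at the first epoch receive an identity row.
#'
#' @param map_t0,map_t1 aligned [land_raster()] objects.
#' @param period_years length of the observation period in years (metadata
#'   only; probabilities are per period, no annualisation is attempted).
#' @return Object of class `transition_model` with elements `prob_matrix`,
#'   `area_matrix` (cell counts) and `period_years`.
#' @export
estimate_transition <- function(map_t0, map_t1, period_years = 10L) {
  stop_if_misaligned(map_t0, map_t1)
  v0 <- map_t0$values; v1 <- map_t1$values
  ok <- v0 != 0L
  if (!any(ok)) stop("all cells are nodata")
  A <- matrix(0, 6, 6, dimnames = list(names(LU_CLASSES), names(LU_CLASSES)))
  tab <- table(factor(v0[ok], levels = 1:6), factor(v1[ok], levels = 1:6))
  A[] <- as.numeric(tab)
  P <- A / ifelse(rowSums(A) > 0, rowSums(A), 1)
  empty <- rowSums(A) == 0
  P[empty, ] <- diag(6)[empty, ]
  structure(list(prob_matrix = P, area_matrix = A,
                 period_years = as.integer(period_years)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> period = %d years\n", x$period_years))
  print(round(x$prob_matrix, 3))
  invisible(x)
}

#' Markov demand: project class cell counts forward
#'
#' Multiplies the epoch class counts by the transition matrix raised to
#' `steps` model periods and rounds the fractional result to integers by
#' the largest-remainder method, so the targets sum exactly to the number
#' of valid cells.
#'
#' @param model a [estimate_transition()] result.
#' @param map_t0 the raster giving current class counts.
#' @param steps number of model periods to project (>= 1).
#' @return Named integer vector of length 6 (target cell counts).
#' @export
project_class_areas <- function(model, map_t0, steps = 1L) {
  stopifnot(inherits(model, "transition_model"), steps >= 1)
  n0 <- class_counts(map_t0)
  P <- model$prob_matrix
  Pk <- diag(6)
  for (s in seq_len(steps)) Pk <- Pk %*% P
  target <- as.numeric(n0 %*% Pk)
  round_largest_remainder(target, sum(n0))
}

# largest-remainder rounding to integers with a fixed total
round_largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- x - fl
  short <- as.integer(round(total - sum(fl)))
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  out <- as.integer(fl)
  names(out) <- names(LU_CLASSES)
  out
}

#' Scenario rule set
#'
#' @param scenario_id `"NP"` (natural progression: no constraints) or
#'   `"BCU"` (black-soil conservation and utilisation rules).
#' @param slope_threshold_deg slope limit for cultivated-land rules
#'   (default 15 degrees).
#' @export
scenario_rules <- function(scenario_id = c("NP", "BCU"),
                           slope_threshold_deg = 15) {
  scenario_id <- match.arg(scenario_id)
  if (slope_threshold_deg <= 0) stop("slope_threshold_deg must be positive")
  structure(list(scenario_id = scenario_id,
                 slope_threshold_deg = slope_threshold_deg),
            class = "scenario_rules")
}

#' Per-class conversion constraint masks for a scenario
#'
#' Returns, for each target class j, a 0/1 matrix saying where conversion
#' *to* j is permitted, evaluated against the first-epoch map. Under NP all
#' conversions are allowed. Under BCU:
#' \itemize{
#'   \item green cells (cultivated, forest, grassland, water) may not
#'     convert to construction;
#'   \item cultivated cells may not convert to any other class, except to
#'     forest or grassland where slope exceeds the threshold;
#'   \item no cell steeper than the threshold may convert to cultivated;
#'   \item nothing may convert to construction on the black-soil mask.
#' }
#'
#' @param rules a [scenario_rules()].
#' @param drivers a `driver_stack` (needs `slope` and `blacksoil` under BCU).
#' @param map_t0 first-epoch [land_raster()].
#' @return List of six 0/1 matrices named by class.
#' @export
apply_scenario_constraints <- function(rules, drivers, map_t0) {
  stopifnot(inherits(rules, "scenario_rules"), inherits(map_t0, "land_raster"))
  nr <- nrow(map_t0$values); nc <- ncol(map_t0$values)
  masks <- stats::setNames(
    replicate(6, matrix(1, nr, nc), simplify = FALSE), names(LU_CLASSES))
  if (rules$scenario_id == "NP") return(masks)
  if (is.null(drivers$slope) || is.null(drivers$blacksoil))
    stop("BCU constraints require slope and blacksoil drivers")
  v <- map_t0$values
  steep <- drivers$slope > rules$slope_threshold_deg
  green <- v %in% GREEN_CLASSES
  cult <- v == LU_CLASSES[["cultivated"]]
  # (i) green -> construction forbidden
  masks$construction[green] <- 0
  # (i)+(iii) cultivated is locked in, except steep cells -> forest/grassland
  for (j in c("forest", "grassland"))
    masks[[j]][cult & !steep] <- 0
  for (j in c("water", "construction", "unutilized"))
    masks[[j]][cult] <- 0
  # (ii) steep cells may not become cultivated
  masks$cultivated[steep & !cult] <- 0
  # (iv) construction is barred on black soil
  masks$construction[drivers$blacksoil] <- 0
  masks
}

#' Build the MCE suitability atlas
#'
#' Min-max rescales each driver to [0, 1], orients it per class (a negative
#' orientation uses 1 - rescaled value), combines the drivers as a weighted
#' linear sum, and multiplies by the class's constraint mask. Default
#' weights are equal across the nine drivers; default orientations are
#' documented in [default_suitability_orientations()].
#'
#' @param drivers a `driver_stack`.
#' @param constraint_masks output of [apply_scenario_constraints()].
#' @param weights optional 6x9 matrix (class x driver) of non-negative
#'   weights; rows are renormalised to sum to 1.
#' @param orientations optional 6x9 matrix of +1/-1 orientations.
#' @return Object of class `suitability_atlas`: list with `suitability`
#'   (six [0,1] matrices) and `masks`.
#' @export
build_suitability <- function(drivers, constraint_masks,
                              weights = NULL, orientations = NULL) {
  dn <- c("elevation", "slope", "temperature", "precipitation", "popdens",
          "gdp", "dist_national", "dist_provincial", "dist_highway")
  missing <- setdiff(dn, names(drivers))
  if (length(missing)) stop("missing drivers: ", paste(missing, collapse = ", "))
  if (is.null(orientations)) orientations <- default_suitability_orientations()
  if (is.null(weights))
    weights <- matrix(1 / 9, 6, 9, dimnames = dimnames(orientations))
  weights <- weights / rowSums(weights)
  scaled <- lapply(drivers[dn], function(m) {
    rng <- range(m, finite = TRUE)
    if (diff(rng) == 0) matrix(0.5, nrow(m), ncol(m))
    else (m - rng[1]) / diff(rng)
  })
  suit <- vector("list", 6)
  names(suit) <- names(LU_CLASSES)
  for (cls in names(LU_CLASSES)) {
    acc <- 0
    for (d in dn) {
      s <- scaled[[d]]
      if (orientations[cls, d] < 0) s <- 1 - s
      acc <- acc + weights[cls, d] * s
    }
    suit[[cls]] <- acc * constraint_masks[[cls]]
  }
  structure(list(suitability = suit, masks = constraint_masks),
            class = "suitability_atlas")
}

#' Default driver orientations per class
#'
#' +1 means higher driver values raise suitability for the class, -1 the
#' opposite. Cultivated land prefers flat, low, warm, wet, road-accessible
#' cells; forest and grassland tolerate steeper, higher terrain away from
#' settlement; water prefers low flat terrain; construction prefers flat
#' terrain near roads with high population/GDP; unutilized land is the
#' mirror of cultivation pressure.
#'
#' @return 6x9 matrix of +1/-1, classes x drivers.
#' @export
default_suitability_orientations <- function() {
  dn <- c("elevation", "slope", "temperature", "precipitation", "popdens",
          "gdp", "dist_national", "dist_provincial", "dist_highway")
  M <- matrix(1, 6, 9, dimnames = list(names(LU_CLASSES), dn))
  M["cultivated", ] <- c(-1, -1, 1, 1, 1, 1, -1, -1, -1)
  M["forest", ]     <- c( 1,  1, -1, 1, -1, -1, 1, 1, 1)
  M["grassland", ]  <- c( 1,  1, -1, -1, -1, -1, 1, 1, 1)
  M["water", ]      <- c(-1, -1, 1, 1, -1, -1, 1, 1, 1)
  M["construction", ] <- c(-1, -1, 1, -1, 1, 1, -1, -1, -1)
  M["unutilized", ] <- c( 1,  1, -1, -1, -1, -1, 1, 1, 1)
  M
}

# per-class neighbourhood density: fraction of the w x w window (clipped at
# edges) occupied by the class, via separable box sums
neighbourhood_density <- function(values, cls, w) {
  ind <- (values == cls) * 1
  box_mean(ind, w)
}

box_mean <- function(m, w) {
  r <- w %/% 2
  cs <- function(x) {
    # running sum over window of width w along columns
    n <- nrow(x)
    cx <- apply(x, 2, cumsum)
    upper <- rbind(matrix(0, r + 1, ncol(x)),
                   cx[seq_len(n - r - 1L), , drop = FALSE])
    lower <- cx[pmin(n, seq_len(n) + r), , drop = FALSE]
    lower - upper
  }
  num <- t(cs(t(cs(m))))
  den <- t(cs(t(cs(matrix(1, nrow(m), ncol(m))))))
  num / den
}

#' Constrained cellular-automaton allocation
#'
#' Allocates the Markov class demands onto the map over `iterations`
#' rounds. Each round moves class counts a further 1/`iterations` of the
#' way from the initial counts to `targets`. Growth classes claim candidate
#' cells in descending score order, where score = suitability x
#' neighbourhood density over a `filter_size` x `filter_size` window,
#' with a seeded random jitter breaking ties; a cell is claimable only if
#' the constraint mask permits the conversion and its current class has
#' cells to spare. Where every in-neighbourhood candidate is exhausted,
#' remaining demand may seed new patches ranked by suitability alone.
#'
#' @param map_t0 starting [land_raster()].
#' @param targets named 6-vector of target cell counts (must sum to the
#'   valid-cell count).
#' @param atlas a [build_suitability()] atlas (carries the constraint masks).
#' @param filter_size odd CA window size (default 5).
#' @param iterations allocation rounds (default 10).
#' @param seed integer seed for tie-breaking.
#' @return Projected [land_raster()]; attribute `shortfall` holds any
#'   per-class unmet demand (all zero when the targets are feasible).
#' @export
simulate_ca <- function(map_t0, targets, atlas, filter_size = 5L,
                        iterations = 10L, seed = 1L) {
  stopifnot(inherits(map_t0, "land_raster"),
            inherits(atlas, "suitability_atlas"))
  v <- map_t0$values
  ok <- v != 0L
  if (abs(sum(targets) - sum(ok)) > 0.5)
    stop("targets must sum to the valid-cell count")
  init <- as.numeric(class_counts(map_t0))
  net <- as.numeric(targets) - init
  cur <- init
  with_seed(seed, {
    jitter <- matrix(stats::runif(length(v)), nrow(v), ncol(v)) * 1e-9
    for (it in seq_len(iterations)) {
      desired <- init + round(net * it / iterations)
      # keep the running total consistent despite rounding
      desired <- round_largest_remainder(desired, sum(ok))
      delta <- desired - cur
      grow <- order(delta, decreasing = TRUE)
      for (j in grow) {
        need <- delta[j]
        if (need <= 0) next
        dens <- neighbourhood_density(v, j, filter_size)
        score <- atlas$suitability[[j]] * dens + jitter
        cand <- which(ok & v != j & atlas$masks[[j]] == 1)
        if (!length(cand)) next
        # donors: classes currently above their desired count
        cand <- cand[(cur - desired)[v[cand]] > 0]
        if (!length(cand)) next
        primary <- cand[dens[cand] > 0]
        backup <- cand[dens[cand] == 0]
        ordc <- c(primary[order(score[primary], decreasing = TRUE)],
                  backup[order(atlas$suitability[[j]][backup] + jitter[backup],
                               decreasing = TRUE)])
        surplus <- pmax(cur - desired, 0)
        taken <- 0L
        for (cell in ordc) {
          if (taken >= need) break
          from <- v[cell]
          if (surplus[from] <= 0) next
          v[cell] <- j
          surplus[from] <- surplus[from] - 1
          cur[from] <- cur[from] - 1
          cur[j] <- cur[j] + 1
          taken <- taken + 1L
        }
      }
    }
  })
  out <- land_raster(v, cell_size_m = map_t0$cell_size_m)
  shortfall <- as.numeric(targets) - as.numeric(class_counts(out))
  names(shortfall) <- names(LU_CLASSES)
  attr(out, "shortfall") <- shortfall
  out
}

#' Cohen's kappa between two categorical rasters
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) over valid cells,
#' with p_e from the marginal class frequencies. Two identical
#' single-class maps return 1 by convention.
#'
#' @param sim,ref aligned [land_raster()] objects.
#' @return Kappa in [-1, 1].
#' @export
kappa_agreement <- function(sim, ref) {
  stop_if_misaligned(sim, ref)
  ok <- valid_mask(sim)
  a <- factor(sim$values[ok], levels = 1:6)
  b <- factor(ref$values[ok], levels = 1:6)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}
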