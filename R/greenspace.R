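#' Evolution-type codes
#'
#' Integer codes used in evolution maps: 1 stable_green, 2 stable_nongreen,
#' 3 expansion (non-green to green), 4 exchange (green to a different green
#' class), 5 loss (green to non-green); 0 nodata.
#' @export
EVOLUTION_CODES <- c(stable_green = 1L, stable_nongreen = 2L,
                     expansion = 3L, exchange = 4L, loss = 5L)

#' Classify cells as green or non-green space
#'
#' Green space comprises cultivated land, forest, grassland and water;
#' construction and unutilized land are non-green. Note that water counts
#' as green under this four-type definition even though it is not
#' vegetated.
#'
#' @param map a [land_raster()].
#' @return Logical matrix: TRUE = green, FALSE = non-green, NA = nodata.
#' @export
classify_green <- function(map) {
  stopifnot(inherits(map, "land_raster"))
  v <- map$values
  out <- matrix(NA, nrow(v), ncol(v))
  out[v %in% GREEN_CLASSES] <- TRUE
  out[v %in% c(5L, 6L)] <- FALSE
  out
}

#' Type the green-space evolution between two epochs
#'
#' Per-cell labels: green to non-green is loss, non-green to green is
#' expansion, green to a *different* green class is exchange, and
#' unchanged class or movement within non-green is stable.
#'
#' @param map_t0,map_t1 aligned [land_raster()] objects.
#' @return Object of class `evolution_map`: integer matrix of
#'   [EVOLUTION_CODES] plus `cell_area_km2`.
#' @export
evolution_type <- function(map_t0, map_t1) {
  stop_if_misaligned(map_t0, map_t1)
  g0 <- classify_green(map_t0)
  g1 <- classify_green(map_t1)
  v0 <- map_t0$values; v1 <- map_t1$values
  lab <- matrix(0L, nrow(v0), ncol(v0))
  ok <- v0 != 0L
  lab[ok & g0 & !g1] <- EVOLUTION_CODES[["loss"]]
  lab[ok & !g0 & g1] <- EVOLUTION_CODES[["expansion"]]
  lab[ok & g0 & g1 & v0 != v1] <- EVOLUTION_CODES[["exchange"]]
  lab[ok & g0 & g1 & v0 == v1] <- EVOLUTION_CODES[["stable_green"]]
  lab[ok & !g0 & !g1] <- EVOLUTION_CODES[["stable_nongreen"]]
  structure(list(labels = lab, cell_area_km2 = cell_area_km2(map_t0)),
            class = "evolution_map")
}

#' Tabulate evolution areas
#'
#' @param evo an [evolution_type()] result.
#' @return data.frame with columns `type` and `area_km2` for the five
#'   evolution types.
#' @export
tabulate_evolution <- function(evo) {
  stopifnot(inherits(evo, "evolution_map"))
  counts <- tabulate(evo$labels[evo$labels != 0L], nbins = 5L)
  data.frame(type = names(EVOLUTION_CODES),
             area_km2 = counts * evo$cell_area_km2,
             row.names = NULL)
}

#' Net green-space loss prevented by one scenario relative to another
#'
#' (loss - expansion) under the baseline minus (loss - expansion) under
#' the alternative: the net green area the alternative scenario retains.
#'
#' @param table_np,table_bcu [tabulate_evolution()] tables for the baseline
#'   (e.g. natural-progression) and alternative (e.g. conservation)
#'   scenarios.
#' @return Prevented net loss in km2 (positive when the alternative
#'   retains more green space).
#' @export
prevented_net_loss <- function(table_np, table_bcu) {
  get <- function(tab, ty) tab$area_km2[match(ty, tab$type)]
  (get(table_np, "loss") - get(table_np, "expansion")) -
    (get(table_bcu, "loss") - get(table_bcu, "expansion"))
}
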