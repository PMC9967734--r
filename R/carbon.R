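#' Read a carbon-density table
#'
#' Loads per-class carbon densities for the four pools (above-ground,
#' below-ground, soil organic, dead organic matter), in t/ha, from a CSV
#' with columns `class, above, below, soil, dead`. The bundled default
#' table carries densities representative of a temperate
#' cultivated/forest mosaic; densities are region-specific estimates and
#' should be swapped for local values when available.
#'
#' @param path CSV path; default is the bundled table.
#' @return data.frame with the four pool columns plus `total` (their sum),
#'   rownames = class names.
#' @export
read_carbon_density <- function(path = system.file("extdata",
                                                   "carbon_density_default.csv",
                                                   package = "greenrisk")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "above", "below", "soil", "dead")
  if (!all(need %in% names(tab)))
    stop("density table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(tab$class, names(LU_CLASSES)))
    stop("density table must cover exactly the six land-use classes")
  if (any(tab[, c("above", "below", "soil", "dead")] < 0))
    stop("carbon pool densities must be non-negative")
  rownames(tab) <- tab$class
  tab <- tab[names(LU_CLASSES), ]
  tab$total <- tab$above + tab$below + tab$soil + tab$dead
  tab
}

#' Total carbon density of one class
#'
#' Sum of the four pools (t/ha) for the given class.
#'
#' @param table a [read_carbon_density()] table.
#' @param class class name or code 1-6.
#' @export
class_total_density <- function(table, class) {
  if (is.numeric(class)) class <- names(LU_CLASSES)[class]
  if (any(is.na(class)) || !all(class %in% rownames(table)))
    stop("unknown class")
  table[class, "total"]
}

#' Per-cell carbon stock map
#'
#' Per-cell stock (t) = class total density (t/ha) x cell area (ha); a
#' 1 km2 cell is 100 ha. Also reports by-class and overall totals.
#'
#' @param map a [land_raster()].
#' @param table a [read_carbon_density()] table.
#' @return Object of class `carbon_map`: `stock` matrix (t, NA on nodata),
#'   `total_t`, `by_class_t`, `cell_area_ha`.
#' @export
carbon_map <- function(map, table = read_carbon_density()) {
  stopifnot(inherits(map, "land_raster"))
  area_ha <- cell_area_ha(map)
  dens <- c(table$total, NA_real_)  # index 7 unused
  v <- map$values
  stock <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- v != 0L
  stock[ok] <- dens[v[ok]] * area_ha
  by_class <- vapply(1:6, function(c) sum(stock[v == c]), numeric(1))
  names(by_class) <- names(LU_CLASSES)
  structure(list(stock = stock, total_t = sum(stock[ok]),
                 by_class_t = by_class, cell_area_ha = area_ha),
            class = "carbon_map")
}

#' Carbon change between epochs, aggregated by evolution type
#'
#' Per-cell change (t) = epoch-2 stock - epoch-1 stock, with totals per
#' green-space evolution type. Totals over the five types partition the
#' overall change exactly.
#'
#' @param cm_t0,cm_t1 [carbon_map()] objects on the same grid.
#' @param evo matching [evolution_type()] result.
#' @return Object of class `carbon_change`: `delta` matrix (t),
#'   `total_t`, and `by_type_t` (named by evolution type).
#' @export
carbon_change <- function(cm_t0, cm_t1, evo) {
  stopifnot(inherits(cm_t0, "carbon_map"), inherits(cm_t1, "carbon_map"),
            inherits(evo, "evolution_map"))
  if (!identical(dim(cm_t0$stock), dim(cm_t1$stock)) ||
      !identical(dim(cm_t0$stock), dim(evo$labels)))
    stop("grids are not aligned")
  delta <- cm_t1$stock - cm_t0$stock
  by_type <- vapply(seq_along(EVOLUTION_CODES), function(k)
    sum(delta[evo$labels == k], na.rm = TRUE), numeric(1))
  names(by_type) <- names(EVOLUTION_CODES)
  structure(list(delta = delta,
                 total_t = sum(delta[evo$labels != 0L], na.rm = TRUE),
                 by_type_t = by_type),
            class = "carbon_change")
}

#' Green-space carbon total for one epoch
#'
#' Sums the carbon stock over the epoch's own green-space mask.
#'
#' @param cm a [carbon_map()].
#' @param map the [land_raster()] the map was computed from.
#' @return Total green-space carbon (t).
#' @export
green_carbon_total <- function(cm, map) {
  g <- classify_green(map)
  sum(cm$stock[which(g)], na.rm = TRUE)
}
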