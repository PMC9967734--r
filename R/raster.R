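#' Land-use class codes
#'
#' Integer codes for the six land-use classes used throughout the package:
#' 1 cultivated, 2 forest, 3 grassland, 4 water, 5 construction,
#' 6 unutilized. Code 0 marks nodata.
#'
#' @format Named integer vector of length 6.
#' @export
LU_CLASSES <- c(
  cultivated   = 1L,
  forest       = 2L,
  grassland    = 3L,
  water        = 4L,
  construction = 5L,
  unutilized   = 6L
)

#' Green-space class codes (cultivated, forest, grassland, water)
#' @export
GREEN_CLASSES <- c(1L, 2L, 3L, 4L)

#' Construct a categorical land-use raster
#'
#' A `land_raster` is an integer matrix of class codes 1-6 with 0 as nodata,
#' plus a cell size in metres. The matrix is stored row-major in display
#' orientation: row 1 is the northernmost row and the origin is the
#' top-left corner.
#'
#' @param values integer matrix of class codes (0 = nodata).
#' @param cell_size_m cell edge length in metres (default 1000).
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, cell_size_m = 1000) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  bad <- values[!is.na(values)]
  if (length(bad) && (any(bad < 0L) || any(bad > 6L)))
    stop("class codes must be in 0..6 (0 = nodata)")
  values[is.na(values)] <- 0L
  structure(list(values = values, cell_size_m = as.numeric(cell_size_m)),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  v <- valid_mask(x)
  cat(sprintf("<land_raster> %d x %d cells @ %g m (%d valid)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, sum(v)))
  tab <- tabulate(x$values[v], nbins = 6L)
  cat("  class counts:", paste(names(LU_CLASSES), tab, sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

#' Logical mask of valid (non-nodata) cells
#' @param x a `land_raster`.
#' @return logical matrix, TRUE where data are present.
#' @export
valid_mask <- function(x) {
  stopifnot(inherits(x, "land_raster"))
  x$values != 0L
}

#' Cell area in hectares / km2
#' @param x a `land_raster` (or numeric cell size in metres).
#' @export
cell_area_ha <- function(x) {
  s <- if (inherits(x, "land_raster")) x$cell_size_m else as.numeric(x)
  (s * s) / 1e4
}

#' @rdname cell_area_ha
#' @export
cell_area_km2 <- function(x) cell_area_ha(x) / 100

#' Per-class cell counts over valid cells
#' @param x a `land_raster`.
#' @return integer vector of length 6 named by class.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "land_raster"))
  n <- tabulate(x$values[valid_mask(x)], nbins = 6L)
  names(n) <- names(LU_CLASSES)
  n
}

stop_if_misaligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("rasters have different dimensions")
  if (!identical(valid_mask(a), valid_mask(b)))
    stop("rasters have different nodata masks")
  invisible(TRUE)
}

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text interchange format: 6 header lines then space-separated rows,
# row 1 = northernmost. No R package in scope writes it, so it is done here.

#' Write a matrix or land_raster as an ESRI ASCII grid
#'
#' @param x `land_raster` or numeric matrix.
#' @param path output file path.
#' @param cell_size_m cell size (taken from `x` when it is a `land_raster`).
#' @param nodata nodata marker written to the header.
#' @param xll,yll lower-left corner coordinates in metres.
#' @export
write_ascii_grid <- function(x, path, cell_size_m = 1000, nodata = -9999,
                             xll = 0, yll = 0) {
  if (inherits(x, "land_raster")) {
    cell_size_m <- x$cell_size_m
    m <- x$values
    m[m == 0L] <- as.integer(nodata)
  } else {
    m <- x
    m[is.na(m)] <- nodata
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", xll),
    sprintf("yllcorner %.6f", yll),
    sprintf("cellsize %.6f", cell_size_m),
    sprintf("NODATA_value %s", format(nodata, scientific = FALSE))
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param categorical if TRUE return a `land_raster`, else a numeric matrix
#'   with NA for nodata.
#' @export
read_ascii_grid <- function(path, categorical = FALSE) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (nrow(m) != val[["nrows"]] || ncol(m) != val[["ncols"]])
    stop("grid body does not match header dimensions")
  nd <- val[["nodata_value"]]
  if (categorical) {
    m[m == nd] <- 0
    land_raster(m, cell_size_m = val[["cellsize"]])
  } else {
    m[m == nd] <- NA_real_
    attr(m, "cell_size_m") <- val[["cellsize"]]
    m
  }
}

# centroid coordinates (metres, origin at top-left) for a cell index
cell_xy <- function(row, col, cell_size_m, n_rows) {
  cbind(x = (col - 0.5) * cell_size_m,
        y = (n_rows - row + 0.5) * cell_size_m)
}
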