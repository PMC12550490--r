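## Light grid-raster container (plain matrices) with ESRI ASCII-grid text
## I/O. Matrix row 1 is the northern-most row; cell (row, col) has centre
## x = xll + (col - 0.5) * cellsize, y = yll + (nrow - row + 0.5) * cellsize.
## `crs` is either "planar_km" (toy planar grids, coordinates and cell size
## in km) or "lonlat" (degrees; areas use a cosine-latitude approximation).

#' Construct a raster stack
#'
#' @param layers Named list of numeric matrices on a common grid (NA =
#'   missing cell).
#' @param cell_size Cell edge length (km for `"planar_km"`, degrees for
#'   `"lonlat"`).
#' @param xll,yll Lower-left corner of the grid.
#' @param crs `"planar_km"` or `"lonlat"`.
#' @param period Optional period label (e.g. `"present"`, `"LGM"`).
#' @return A `raster_stack` object.
#' @export
raster_stack <- function(layers, cell_size, xll = 0, yll = 0,
                         crs = c("planar_km", "lonlat"), period = NULL) {
  crs <- match.arg(crs)
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)),
            cell_size > 0)
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L) stop("all layers must share the same grid")
  structure(list(layers = layers, nrow = dims[[1]][1], ncol = dims[[1]][2],
                 cell_size = cell_size, xll = xll, yll = yll, crs = crs,
                 period = period), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat("raster_stack: ", length(x$layers), " layer(s) [",
      paste(utils::head(names(x$layers), 5), collapse = ", "),
      if (length(x$layers) > 5) ", ..." else "", "], ",
      x$nrow, " x ", x$ncol, " cells of ", x$cell_size,
      if (x$crs == "planar_km") " km" else " deg",
      if (!is.null(x$period)) paste0(" (", x$period, ")"), "\n", sep = "")
  invisible(x)
}

#' Cell-centre coordinates of a raster stack
#' @param stack A [raster_stack()].
#' @return Data frame `x`, `y` in cell order (row-major, northern row first).
#' @export
cell_coords <- function(stack) {
  g <- expand.grid(col = seq_len(stack$ncol), row = seq_len(stack$nrow))
  data.frame(x = stack$xll + (g$col - 0.5) * stack$cell_size,
             y = stack$yll + (stack$nrow - g$row + 0.5) * stack$cell_size)
}

#' Layer values as a cells-by-layers matrix
#' @param stack A [raster_stack()].
#' @return Numeric matrix, one column per layer, rows in [cell_coords()]
#'   order.
#' @export
cell_values <- function(stack) {
  sapply(stack$layers, function(m) as.vector(t(m)))
}

#' Per-cell area in km^2
#'
#' Planar grids have exact `cell_size^2` areas; lon/lat grids use the
#' cosine-latitude approximation `(111.32 * cs)^2 * cos(lat)`.
#'
#' @param stack A [raster_stack()].
#' @return Numeric vector of areas, one per cell.
#' @export
cell_areas_km2 <- function(stack) {
  if (stack$crs == "planar_km") {
    rep(stack$cell_size^2, stack$nrow * stack$ncol)
  } else {
    lat <- cell_coords(stack)$y
    (111.32 * stack$cell_size)^2 * cos(lat * pi / 180)
  }
}

## cell index (row-major) of coordinate pairs; NA outside the grid
cell_index <- function(stack, x, y) {
  col <- floor((x - stack$xll) / stack$cell_size) + 1L
  row <- stack$nrow - floor((y - stack$yll) / stack$cell_size)
  bad <- col < 1L | col > stack$ncol | row < 1L | row > stack$nrow
  idx <- (row - 1L) * stack$ncol + col
  idx[bad] <- NA_integer_
  idx
}

#' Write one raster layer as ESRI ASCII grid text
#'
#' @param stack A [raster_stack()].
#' @param layer Layer name.
#' @param path Output path.
#' @export
write_ascii_grid <- function(stack, layer, path) {
  m <- stack$layers[[layer]]
  if (is.null(m)) stop("no layer '", layer, "'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", stack$ncol), paste("nrows", stack$nrow),
               paste("xllcorner", stack$xll), paste("yllcorner", stack$yll),
               paste("cellsize", stack$cell_size),
               "NODATA_value -9999"), con)
  m[is.na(m)] <- -9999
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file as a one-layer raster stack
#'
#' @param path File path.
#' @param layer_name Name for the layer.
#' @param crs Coordinate system of the grid.
#' @return A [raster_stack()].
#' @export
read_ascii_grid <- function(path, layer_name = "layer1",
                            crs = c("planar_km", "lonlat")) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  tolower(vapply(kv, `[`, "", 1L)))
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == hdr[["nodata_value"]]] <- NA
  raster_stack(setNames(list(m), layer_name), cell_size = hdr[["cellsize"]],
               xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]],
               crs = match.arg(crs))
}

#' Crop a raster stack to an occurrence bounding box plus buffer
#'
#' The crop extent is the occurrence bounding box expanded by `buffer` in
#' coordinate units (degrees for lon/lat grids), clipped to the raster
#' bounds.
#'
#' @param stack A [raster_stack()].
#' @param occ Occurrence data frame with `lon`, `lat` columns (in the grid's
#'   coordinate units).
#' @param buffer Buffer width in coordinate units (default 10).
#' @return The cropped [raster_stack()].
#' @export
crop_with_buffer <- function(stack, occ, buffer = 10) {
  stopifnot(nrow(occ) >= 1L, buffer >= 0)
  xmax_r <- stack$xll + stack$ncol * stack$cell_size
  ymax_r <- stack$yll + stack$nrow * stack$cell_size
  x0 <- max(min(occ$lon) - buffer, stack$xll)
  x1 <- min(max(occ$lon) + buffer, xmax_r)
  y0 <- max(min(occ$lat) - buffer, stack$yll)
  y1 <- min(max(occ$lat) + buffer, ymax_r)
  if (x0 >= x1 || y0 >= y1) stop("crop extent does not intersect the raster")
  c0 <- floor((x0 - stack$xll) / stack$cell_size) + 1L
  c1 <- ceiling((x1 - stack$xll) / stack$cell_size)
  r1 <- stack$nrow - floor((y0 - stack$yll) / stack$cell_size)
  r0 <- stack$nrow - ceiling((y1 - stack$yll) / stack$cell_size) + 1L
  layers <- lapply(stack$layers, function(m) m[r0:r1, c0:c1, drop = FALSE])
  raster_stack(layers, cell_size = stack$cell_size,
               xll = stack$xll + (c0 - 1L) * stack$cell_size,
               yll = stack$yll + (stack$nrow - r1) * stack$cell_size,
               crs = stack$crs, period = stack$period)
}
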