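#' Georeferenced cell lattice
#'
#' A `geo_grid` is a rectangular lattice of square cells in geographic
#' (WGS84 longitude/latitude, decimal degree) coordinates. Values are held
#' in a matrix whose first row is the northernmost row of cells; `NA`
#' marks nodata. `origin_lon`/`origin_lat` give the lower-left corner of
#' the grid (cell edges, not centers), as in the ESRI ASCII grid format.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` = nodata.
#' @param origin_lon,origin_lat lower-left corner of the grid, degrees.
#' @param cell_size cell edge length in degrees (> 0).
#' @return An object of class `geo_grid`.
#' @export
geo_grid <- function(values, origin_lon, origin_lat, cell_size) {
  values <- as.matrix(values)
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            is.numeric(origin_lon), is.numeric(origin_lat))
  storage.mode(values) <- "double"
  structure(list(values = values, origin_lon = origin_lon,
                 origin_lat = origin_lat, cell_size = cell_size),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("geo_grid: %d rows x %d cols, cell %.6g deg, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin_lon, x$origin_lat))
  cat(sprintf("  %d cells (%d nodata); value range [%.4g, %.4g]\n",
              length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)

grid_extent <- function(g) {
  c(xmin = g$origin_lon, xmax = g$origin_lon + grid_ncol(g) * g$cell_size,
    ymin = g$origin_lat, ymax = g$origin_lat + grid_nrow(g) * g$cell_size)
}

same_geometry <- function(a, b, tol = 1e-9) {
  grid_nrow(a) == grid_nrow(b) && grid_ncol(a) == grid_ncol(b) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

# Column-major cell ids (matching as.vector on the value matrix).
cell_index <- function(g, row, col) row + (col - 1L) * grid_nrow(g)

# Cell (row, col) containing each lon/lat point; NA when off-grid.
# Points exactly on the top/right edge are assigned to the last cell.
cell_of <- function(g, lon, lat) {
  ext <- grid_extent(g)
  col <- floor((lon - g$origin_lon) / g$cell_size) + 1
  row <- grid_nrow(g) - floor((lat - g$origin_lat) / g$cell_size)
  col[lon == ext["xmax"]] <- grid_ncol(g)
  row[lat == ext["ymax"]] <- 1
  off <- lon < ext["xmin"] | lon > ext["xmax"] | lat < ext["ymin"] | lat > ext["ymax"]
  row[off] <- NA_integer_; col[off] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Longitude of cell centers per column / latitude per row (row 1 = north).
col_center_lon <- function(g) g$origin_lon + (seq_len(grid_ncol(g)) - 0.5) * g$cell_size
row_center_lat <- function(g) g$origin_lat + (grid_nrow(g) - seq_len(grid_nrow(g)) + 0.5) * g$cell_size

# Center coordinates of every cell, column-major order (cell id order).
cell_centers <- function(g) {
  lon <- col_center_lon(g); lat <- row_center_lat(g)
  data.frame(lon = rep(lon, each = grid_nrow(g)), lat = rep(lat, grid_ncol(g)))
}

#' Stack of co-registered raster layers
#'
#' @param layers named list of [geo_grid()] objects sharing one geometry.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  if (anyDuplicated(names(layers)))
    stop("layer names must be unique")
  g1 <- layers[[1]]
  for (l in layers)
    if (!same_geometry(g1, l)) stop("all layers must share the grid geometry")
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("raster_stack: %d layers (%s) on %d x %d grid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              grid_nrow(g), grid_ncol(g)))
  invisible(x)
}

#' Grid geometry and value matrix of a stack
#'
#' `stack_grid` returns the [geo_grid()] carrying the shared geometry (the
#' first layer); `stack_matrix` returns the cells x layers value matrix in
#' column-major cell order, one named column per layer.
#'
#' @param s a [raster_stack()].
#' @export
stack_grid <- function(s) s$layers[[1]]

# Cells masked (nodata) in any layer.
stack_mask <- function(s) {
  m <- Reduce(`|`, lapply(s$layers, function(l) is.na(l$values)))
  m
}

#' @rdname stack_grid
#' @export
stack_matrix <- function(s) {
  out <- vapply(s$layers, function(l) as.vector(l$values),
                numeric(length(s$layers[[1]]$values)))
  colnames(out) <- names(s$layers)
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (one file per layer).
#' `NODATA_value` cells become `NA`.
#'
#' @param path file path.
#' @param grid a [geo_grid()].
#' @param nodata value written for `NA` cells.
#' @return `read_asc` returns a [geo_grid()]; `write_asc` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = hdr["nrows"], ncol = hdr["ncols"], byrow = TRUE)
  if (!is.na(hdr["nodata_value"])) m[m == hdr["nodata_value"]] <- NA_real_
  geo_grid(m, unname(hdr["xllcorner"]), unname(hdr["yllcorner"]),
           unname(hdr["cellsize"]))
}

#' @rdname read_asc
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin_lon),
           sprintf("yllcorner %.10g", grid$origin_lat),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a directory of .asc layers into a raster stack
#'
#' Layer names are the file stems.
#' @param dir directory containing `*.asc` files.
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers found in ", dir)
  layers <- lapply(files, read_asc)
  names(layers) <- sub("\\.asc$", "", basename(files))
  raster_stack(layers)
}

#' Write every layer of a stack as .asc files
#' @param stack a [raster_stack()].
#' @param dir output directory (created if absent).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_asc(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' Extract predictor values at point locations
#'
#' Containing-cell lookup of every stack layer at each point. Points that
#' fall off the grid or on nodata cells are dropped; the counts are
#' attached as the `"dropped"` attribute and the surviving row indices as
#' `"kept"`.
#'
#' @param stack a [raster_stack()].
#' @param points data frame with `lon` and `lat` columns (degrees, WGS84).
#' @return matrix of extracted values (rows = retained points, columns =
#'   layer names).
#' @export
extract_values <- function(stack, points) {
  g <- stack_grid(stack)
  rc <- cell_of(g, points$lon, points$lat)
  off <- is.na(rc[, "row"])
  idx <- cell_index(g, rc[!off, "row"], rc[!off, "col"])
  vals <- stack_matrix(stack)[idx, , drop = FALSE]
  nod <- rowSums(is.na(vals)) > 0
  if (all(off) || all(nod)) stop("no points fall on valid grid cells")
  out <- vals[!nod, , drop = FALSE]
  kept <- which(!off)[!nod]
  attr(out, "kept") <- kept
  attr(out, "dropped") <- c(off_grid = sum(off), nodata = sum(nod))
  attr(out, "cell") <- idx[!nod]
  out
}
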