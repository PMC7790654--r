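#' Binary range map from a suitability surface
#'
#' Cells with suitability at or above the threshold become 1, others 0;
#' nodata is preserved. The threshold is recorded in the `"threshold"`
#' attribute.
#'
#' @param suitability a [geo_grid()].
#' @param threshold finite binarization threshold.
#' @return a [geo_grid()] with values in \{0, 1, NA\}.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(is.finite(threshold))
  v <- suitability$values
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  out <- geo_grid(b, suitability$origin_lon, suitability$origin_lat,
                  suitability$cell_size)
  attr(out, "threshold") <- threshold
  out
}

# Spherical area (km^2) of one cell in each grid row, using the exact
# spherical-quadrilateral formula R^2 * dlambda * (sin(phi_top) -
# sin(phi_bottom)) with the cell-edge latitudes (exact for the cell; a
# cos(phi_center) approximation would bias coarse cells).
cell_area_by_row <- function(grid) {
  r <- 6371
  cs <- grid$cell_size * pi / 180
  lat_top <- (grid$origin_lat + (grid_nrow(grid) - seq_len(grid_nrow(grid)) + 1) *
                grid$cell_size) * pi / 180
  lat_bot <- lat_top - grid$cell_size * pi / 180
  r^2 * cs * (sin(lat_top) - sin(lat_bot))
}

#' Suitable-range area of a binary map
#'
#' Sums the spherical cell areas of all cells equal to 1.
#'
#' @param map a binary [geo_grid()] (from [binarize()]).
#' @return area in km^2.
#' @export
area_km2 <- function(map) {
  a <- cell_area_by_row(map)
  suit <- map$values == 1
  suit[is.na(suit)] <- FALSE
  sum(a * rowSums(suit))
}

#' Minimum convex polygon of occurrence points
#'
#' @param points data frame with `lon`/`lat`; at least 3 non-collinear
#'   points.
#' @return closed polygon ring as a data frame (`lon`, `lat`), class
#'   `range_polygon`, with a `"derivation"` attribute of `"mcp"`.
#' @export
mcp <- function(points) {
  pts <- unique(data.frame(lon = points$lon, lat = points$lat))
  if (nrow(pts) < 3) stop("need at least 3 distinct points")
  h <- grDevices::chull(pts$lon, pts$lat)
  ring <- pts[c(h, h[1]), ]
  # planar shoelace only to detect collinearity
  sh <- sum(ring$lon[-nrow(ring)] * ring$lat[-1] -
              ring$lon[-1] * ring$lat[-nrow(ring)]) / 2
  if (abs(sh) < 1e-12) stop("points are collinear; polygon is degenerate")
  rownames(ring) <- NULL
  attr(ring, "derivation") <- "mcp"
  class(ring) <- c("range_polygon", "data.frame")
  ring
}

# Ray-casting point-in-polygon test (ring closed or open), vectorized
# over points. Boundary points count as inside.
point_in_polygon <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  if (ring_x[1] == ring_x[n] && ring_y[1] == ring_y[n]) {
    ring_x <- ring_x[-n]; ring_y <- ring_y[-n]; n <- n - 1
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring_x[i]; yi <- ring_y[i]; xj <- ring_x[j]; yj <- ring_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Extent-of-occurrence area
#'
#' Spherical area of a range polygon (radius 6,371 km). When a landmask
#' grid is supplied, the area is instead the summed spherical area of
#' land cells (unmasked, nonzero cells of the landmask) whose centers lie
#' inside the polygon -- the "excluding the ocean" convention.
#'
#' @param polygon a [mcp()] polygon (or any closed `lon`/`lat` ring).
#' @param landmask optional [geo_grid()]; cells with value 1 are land.
#' @return area in km^2.
#' @export
eoo_area <- function(polygon, landmask = NULL) {
  ring <- as.data.frame(polygon)
  if (is.null(landmask)) {
    open <- ring[-nrow(ring), c("lon", "lat")]
    return(abs(geosphere::areaPolygon(as.matrix(open), a = 6371000, f = 0)) / 1e6)
  }
  cc <- cell_centers(landmask)
  land <- as.vector(landmask$values)
  inside <- point_in_polygon(cc$lon, cc$lat, ring$lon, ring$lat)
  ok <- inside & !is.na(land) & land != 0
  a <- rep(cell_area_by_row(landmask), grid_ncol(landmask))
  sum(a[ok])
}
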