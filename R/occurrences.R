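#' Clean raw occurrence records
#'
#' Drops records without usable coordinates, rejects coordinates outside
#' the valid longitude/latitude domain, and collapses exact coordinate
#' duplicates to the first record in file order. A removal report
#' (`n_input`, `no_georeference`, `invalid_coordinate`, `duplicate`,
#' `n_retained`) is attached as the `"report"` attribute.
#'
#' @param records data frame with `lon` and `lat` columns (any additional
#'   columns, e.g. `source` or `id`, are carried through).
#' @return cleaned data frame of class `occurrence_set`.
#' @export
clean_occurrences <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("lon", "lat") %in% names(records)))
    stop("records must have 'lon' and 'lat' columns")
  n_input <- nrow(records)
  lon <- suppressWarnings(as.numeric(records$lon))
  lat <- suppressWarnings(as.numeric(records$lat))
  no_geo <- is.na(lon) | is.na(lat)
  invalid <- !no_geo & (lat < -90 | lat > 90 | lon < -180 | lon > 180)
  keep <- !no_geo & !invalid
  out <- records[keep, , drop = FALSE]
  out$lon <- lon[keep]; out$lat <- lat[keep]
  dup <- duplicated(out[, c("lon", "lat")])
  out <- out[!dup, , drop = FALSE]
  if (!nrow(out)) stop("no valid occurrence records remain after cleaning")
  rownames(out) <- NULL
  attr(out, "report") <- c(n_input = n_input,
                           no_georeference = sum(no_geo),
                           invalid_coordinate = sum(invalid),
                           duplicate = sum(dup),
                           n_retained = nrow(out))
  attr(out, "crs") <- "WGS84"
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Full pairwise haversine distance matrix (km).
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- haversine_km(lon[i], lat[i], lon, lat)
  }
  # enforce exact symmetry against floating-point asymmetry
  (D + t(D)) / 2
}

#' Spatial thinning of occurrence records
#'
#' Enforces a minimum pairwise great-circle distance between retained
#' records, the standard correction for spatial sampling bias in
#' presence-only data. Each trial repeatedly removes one record among
#' those with the largest number of neighbours closer than `min_dist_km`
#' (uniformly at random among ties) until no pair violates the distance;
#' the largest retained set over `n_trials` trials is returned. This is a
#' randomized greedy maximum-independent-set heuristic: repetition makes
#' it near-optimal on realistic record counts.
#'
#' @param occ data frame with `lon`/`lat` (e.g. from [clean_occurrences()]).
#' @param min_dist_km minimum allowed pairwise distance, km.
#' @param n_trials number of randomized trials.
#' @param seed RNG seed.
#' @return the thinned subset of `occ`; retained row indices in attribute
#'   `"kept"`.
#' @export
thin_occurrences <- function(occ, min_dist_km = 4, n_trials = 100, seed = NULL) {
  stopifnot(min_dist_km > 0, n_trials >= 1)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  D <- haversine_matrix(occ$lon, occ$lat)
  A <- D < min_dist_km
  diag(A) <- FALSE
  if (!any(A)) {
    attr(occ, "kept") <- seq_len(n)
    return(occ)
  }
  Ad <- A * 1
  best <- NULL
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      keep <- rep(TRUE, n)
      cnt <- rowSums(Ad)
      repeat {
        cmax <- max(cnt[keep])
        if (cmax == 0) break
        cand <- which(keep & cnt == cmax)
        drop <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
        keep[drop] <- FALSE
        cnt <- cnt - Ad[, drop]
      }
      if (is.null(best) || sum(keep) > length(best)) best <- which(keep)
    }
  })
  out <- occ[best, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- best
  attr(out, "report") <- attr(occ, "report")
  class(out) <- class(occ)
  out
}
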