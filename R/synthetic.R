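#' Synthetic study scenario
#'
#' Defines a reproducible synthetic landscape: a stack of standardized,
#' spatially autocorrelated predictor layers; a known log-linear
#' (linear + quadratic) intensity surface over them; and occurrences
#' sampled proportional to that intensity. Every downstream stage of the
#' pipeline can be validated against this ground truth without external
#' data.
#'
#' Defaults describe the package's reference landscape: a 100 x 100 grid
#' of 2.5 arc-minute cells (the resolution of the study design this
#' emulates), three predictors with moderate spatial autocorrelation and
#' independent cross-correlation, concave (negative-quadratic) responses,
#' and 500 expected presences.
#'
#' @param n_rows,n_cols grid dimensions in cells.
#' @param cell_size cell edge, degrees (default 2.5 arc-minutes).
#' @param origin_lon,origin_lat lower-left corner, degrees.
#' @param n_layers number of predictor layers.
#' @param autocorr_length Gaussian smoothing scale in cells (0 = white noise).
#' @param cross_corr target between-layer correlation matrix (symmetric,
#'   positive semi-definite, unit diagonal).
#' @param beta_linear,beta_quadratic true per-layer coefficients of the
#'   log-intensity: eta = sum(bL * z + bQ * z^2).
#' @param n_presences number of occurrence points to draw.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows = 100, n_cols = 100, cell_size = 2.5 / 60,
                               origin_lon = -75, origin_lat = -15,
                               n_layers = 3, autocorr_length = 5,
                               cross_corr = diag(n_layers),
                               beta_linear = c(1, -0.7, 0.5)[seq_len(n_layers)],
                               beta_quadratic = c(-0.8, -0.4, -0.2)[seq_len(n_layers)],
                               n_presences = 500, seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, n_layers >= 1,
            n_presences >= 1, length(beta_linear) == n_layers,
            length(beta_quadratic) == n_layers)
  cross_corr <- as.matrix(cross_corr)
  if (nrow(cross_corr) != n_layers || ncol(cross_corr) != n_layers)
    stop("cross_corr must be ", n_layers, " x ", n_layers)
  if (max(abs(cross_corr - t(cross_corr))) > 1e-10)
    stop("cross_corr must be symmetric")
  if (max(abs(diag(cross_corr) - 1)) > 1e-10)
    stop("cross_corr must have unit diagonal")
  ev <- eigen(cross_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("cross_corr is not positive semi-definite (eigenvalue %.6g)",
                 min(ev)))
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 n_layers = n_layers, autocorr_length = autocorr_length,
                 cross_corr = cross_corr, beta_linear = beta_linear,
                 beta_quadratic = beta_quadratic, n_presences = n_presences,
                 seed = seed),
            class = "synthetic_scenario")
}

# Row-normalized Gaussian smoothing matrix for one axis. Truncating at the
# matrix edge and renormalizing keeps the smoother mean-preserving there.
gaussian_smoother <- function(n, L) {
  if (L <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * L^2))
  K / rowSums(K)
}

# Symmetric PSD square root (tolerates semi-definite cross_corr where
# Cholesky would fail).
psd_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate the synthetic predictor stack
#'
#' White Gaussian noise per layer is mixed across layers to the target
#' cross-correlation, smoothed with a separable Gaussian kernel of scale
#' `autocorr_length` cells, and each layer re-standardized to zero mean and
#' unit variance. The same kernel is applied to every layer, so mixing
#' before smoothing preserves the between-layer correlation.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [raster_stack()] with layers `env1`, `env2`, ...
#' @export
generate_predictor_stack <- function(scenario) {
  sc <- scenario
  ncell <- sc$n_rows * sc$n_cols
  with_seed(sc$seed, {
    E <- matrix(stats::rnorm(ncell * sc$n_layers), ncell, sc$n_layers)
    E <- E %*% psd_sqrt(sc$cross_corr)
    Kr <- gaussian_smoother(sc$n_rows, sc$autocorr_length)
    Kc <- gaussian_smoother(sc$n_cols, sc$autocorr_length)
    layers <- lapply(seq_len(sc$n_layers), function(k) {
      m <- matrix(E[, k], sc$n_rows, sc$n_cols)
      m <- Kr %*% m %*% t(Kc)
      m <- (m - mean(m)) / stats::sd(m)
      geo_grid(m, sc$origin_lon, sc$origin_lat, sc$cell_size)
    })
    names(layers) <- paste0("env", seq_len(sc$n_layers))
    raster_stack(layers)
  })
}

#' True intensity and suitability surfaces
#'
#' Computes the ground-truth log-linear intensity eta = sum_k (bL_k z_k +
#' bQ_k z_k^2) over all unmasked cells, the normalized intensity
#' raw = exp(eta)/sum(exp(eta)) (sums to 1), and its complementary log-log
#' suitability cloglog = 1 - exp(-exp(H) * raw), where H is the Shannon
#' entropy of raw. With all coefficients zero, raw is uniform and cloglog
#' equals 1 - exp(-1) everywhere.
#'
#' @param stack a [raster_stack()].
#' @param beta_linear,beta_quadratic per-layer coefficients.
#' @return list with elements `raw` and `cloglog` ([geo_grid()]s), plus
#'   `eta` and the entropy `H`.
#' @export
true_suitability <- function(stack, beta_linear, beta_quadratic) {
  Z <- stack_matrix(stack)
  if (ncol(Z) != length(beta_linear) || ncol(Z) != length(beta_quadratic))
    stop("coefficient vectors must match the layer count")
  ok <- !is.na(rowSums(Z))
  if (!any(ok)) stop("all cells are masked")
  eta <- rep(NA_real_, nrow(Z))
  eta[ok] <- Z[ok, , drop = FALSE] %*% beta_linear +
    (Z[ok, , drop = FALSE]^2) %*% beta_quadratic
  lse <- logsumexp(eta[ok])
  raw <- exp(eta - lse)
  H <- -sum(raw[ok] * (eta[ok] - lse))
  clog <- 1 - exp(-exp(H) * raw)
  g <- stack_grid(stack)
  shape <- function(v) geo_grid(matrix(v, grid_nrow(g), grid_ncol(g)),
                                g$origin_lon, g$origin_lat, g$cell_size)
  list(raw = shape(raw), cloglog = shape(clog), eta = shape(eta), H = H)
}

#' Sample presence points from a normalized intensity surface
#'
#' Cell membership is multinomial with probabilities proportional to the
#' (unmasked) intensity values; positions within a cell are uniform, so
#' points live in continuous space rather than on cell centers.
#'
#' @param raw a [geo_grid()] of non-negative intensities.
#' @param n_presences number of points (>= 1).
#' @param seed RNG seed.
#' @return data frame with columns `lon`, `lat`.
#' @export
sample_presences <- function(raw, n_presences, seed = NULL) {
  if (n_presences <= 0) stop("n_presences must be positive")
  v <- as.vector(raw$values)
  ok <- which(!is.na(v) & v > 0)
  if (!length(ok)) stop("intensity surface has no positive unmasked cells")
  nr <- grid_nrow(raw)
  with_seed(seed, {
    cells <- ok[sample.int(length(ok), n_presences, replace = TRUE,
                           prob = v[ok])]
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    lon <- raw$origin_lon + (col - 1L + stats::runif(n_presences)) * raw$cell_size
    lat <- raw$origin_lat + (nr - row + stats::runif(n_presences)) * raw$cell_size
    data.frame(lon = lon, lat = lat)
  })
}
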