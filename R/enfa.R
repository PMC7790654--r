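# Ecological Niche Factor Analysis: ordination of the occupied niche
# against the available (background) environment. The marginality vector
# m is the mean shift of the occupied cells in background-standardized
# units; the specialization factors maximize the ratio of background to
# occupied variance subject to R_s-orthogonality to earlier factors.

# Weighted covariance with population (1/sum(w)) normalization.
weighted_cov <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc * sqrt(w), Xc * sqrt(w))
}

# Symmetric inverse square root; errors on a numerically singular matrix.
inv_sqrt_sym <- function(S, label = "matrix") {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-12)
    stop(sprintf("%s is singular (condition number %.3g)", label,
                 max(e$values) / max(min(e$values), .Machine$double.xmin)))
  list(inv = e$vectors %*% (1 / sqrt(e$values) * t(e$vectors)),
       sqrt = e$vectors %*% (sqrt(e$values) * t(e$vectors)))
}

#' Ecological Niche Factor Analysis
#'
#' Contrasts the environment at occupied cells with a large random sample
#' of the available background. Predictors are standardized to zero mean
#' and unit variance over the background sample; occupied cells are
#' weighted by their occurrence counts. The marginality vector `m` is the
#' weighted mean of the standardized values over occupied cells and the
#' overall marginality is `M = sqrt(sum(m^2))` (a shift of one background
#' standard deviation on a single axis gives M = 1). With `R_s` the
#' weighted occupied covariance and `R_g` the background covariance, the
#' first factor is aligned with `m`; each further factor maximizes the
#' specialization ratio `u' R_g u / u' R_s u` subject to
#' R_s-orthogonality to all earlier factors. The achieved ratios are the
#' eigenvalues; overall specialization is `S = sqrt(mean(eigenvalues))`
#' (1 when the occupied niche is as wide as the background).
#'
#' @param stack a [raster_stack()] of at least 2 predictors.
#' @param occ occurrence data frame (`lon`/`lat`); typically the full
#'   unfiltered record set, since ENFA measures environments at points
#'   and is insensitive to duplicated sampling of the same conditions.
#' @param n_background background sample size (default 100,000; all
#'   cells are used, with a message, if fewer exist).
#' @param seed RNG seed for the background sample.
#' @return object of class `enfa_result`: `marginality` vector and `M`,
#'   `eigenvalues` (first entry = marginality axis) and `S`, `loadings`
#'   (predictors x axes, unit-norm columns), `variance_share` (%).
#' @export
enfa_fit <- function(stack, occ, n_background = 100000, seed = NULL) {
  if (length(stack$layers) < 2) stop("ENFA needs at least 2 predictors")
  bg <- sample_background(stack, n_background, seed = seed)
  pres <- extract_values(stack, occ)
  cells <- attr(pres, "cell")
  # weight occupied cells by their occurrence counts
  tab <- table(cells)
  ucell <- as.integer(names(tab))
  w <- as.numeric(tab)
  M0 <- stack_matrix(stack)
  X_occ <- M0[ucell, , drop = FALSE]

  mu <- colMeans(bg)
  sdv <- apply(bg, 2, stats::sd)
  if (any(sdv == 0)) stop("constant predictor over the background")
  Zb <- sweep(sweep(unclass(bg), 2, mu), 2, sdv, "/")
  Zo <- sweep(sweep(X_occ, 2, mu), 2, sdv, "/")

  m <- colSums(Zo * (w / sum(w)))
  M <- sqrt(sum(m^2))
  Rg <- weighted_cov(Zb, rep(1, nrow(Zb)))
  Rs <- weighted_cov(Zo, w)

  P <- ncol(Zb)
  iso <- inv_sqrt_sym(Rs, "occupied covariance R_s")
  B <- iso$inv %*% Rg %*% iso$inv
  u1 <- if (M > 1e-12) m / M else c(1, rep(0, P - 1))
  lam1 <- drop(t(u1) %*% Rg %*% u1) / drop(t(u1) %*% Rs %*% u1)
  v1 <- drop(iso$sqrt %*% u1); v1 <- v1 / sqrt(sum(v1^2))
  Pr <- diag(P) - tcrossprod(v1)
  Bp <- Pr %*% B %*% Pr
  eb <- eigen((Bp + t(Bp)) / 2, symmetric = TRUE)
  spec_v <- eb$vectors[, seq_len(P - 1), drop = FALSE]
  lam_spec <- vapply(seq_len(P - 1), function(k) {
    v <- spec_v[, k]
    drop(t(v) %*% B %*% v) / drop(crossprod(v))
  }, numeric(1))
  U <- cbind(u1, iso$inv %*% spec_v)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  rownames(U) <- names(stack$layers)
  colnames(U) <- c("Marg", paste0("Spec", seq_len(P - 1)))
  lam <- c(lam1, lam_spec)
  names(lam) <- colnames(U)
  S <- sqrt(mean(lam))
  structure(list(marginality = stats::setNames(m, names(stack$layers)), M = M,
                 eigenvalues = lam, S = S, loadings = U,
                 variance_share = 100 * lam / sum(lam),
                 n_background = nrow(bg), n_occurrences = nrow(pres),
                 n_occupied_cells = length(ucell)),
            class = "enfa_result")
}

#' @export
print.enfa_result <- function(x, ...) {
  cat(sprintf("ENFA: %d predictors, %d occurrences on %d cells, %d background\n",
              nrow(x$loadings), x$n_occurrences, x$n_occupied_cells,
              x$n_background))
  cat(sprintf("  marginality M = %.3f, specialization S = %.3f\n", x$M, x$S))
  invisible(x)
}

#' Ordered ENFA loadings table
#'
#' Predictors as rows, sorted by descending absolute marginality
#' coefficient; columns are the marginality axis and the specialization
#' axes, followed by the variance share of each axis in the final row
#' attribute.
#'
#' @param result an [enfa_fit()] result.
#' @return data frame of loadings, with `"variance_share"` attribute.
#' @export
enfa_loadings_table <- function(result) {
  L <- result$loadings
  ord <- order(abs(L[, "Marg"]), decreasing = TRUE)
  out <- as.data.frame(L[ord, , drop = FALSE])
  attr(out, "variance_share") <- result$variance_share
  out
}
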