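# Penalized inhomogeneous-Poisson-process (maxent-equivalent) fitting.
#
# The model is log-linear in the features: eta(x) = f(x)' beta. Fitting
# minimizes the convex objective
#
#   f(beta) = -(1/n) sum_presences eta(x_i)
#             + log sum_background exp(eta(z_j))
#             + sum_k lambda_k |beta_k|
#
# which is the (negative, per-presence) conditional log-likelihood of an
# IPP observed at the presence points with the background as quadrature,
# plus the maxent L1 penalty. No intercept is fitted: the background
# normalizer absorbs it.

# Default per-feature-class regularization schedule, interpolated on the
# presence sample size, transcribed from the open-source maxnet reference
# implementation. When quadratic features are present the quadratic table
# governs all linear+quadratic features.
lambda_class_schedule <- function(classes, n_presences) {
  lin <- list(n = c(0, 10, 30, 100), beta = c(1, 1, 0.2, 0.05))
  quad <- list(n = c(0, 10, 17, 30, 100), beta = c(1.3, 0.8, 0.5, 0.25, 0.05))
  tab <- if ("quadratic" %in% classes) quad else lin
  stats::approx(tab$n, tab$beta, xout = n_presences, rule = 2)$y
}

# Per-feature L1 weights: rm * Lambda_class(n) * sd_k(presences) / sqrt(n).
ppm_penalties <- function(pres_features, classes, rm) {
  n <- nrow(pres_features)
  sds <- apply(pres_features, 2, stats::sd)
  sds <- pmax(sds, sqrt(.Machine$double.eps))   # guard a degenerate feature
  rm * lambda_class_schedule(classes, n) * sds / sqrt(n)
}

#' Fit a penalized point-process (maxent-equivalent) model
#'
#' Minimizes the L1-penalized IPP objective by accelerated proximal
#' gradient descent (FISTA with backtracking and restart). Convergence is
#' declared when the objective decreases by less than `tol` between
#' iterations.
#'
#' @param pres_features,bg_features feature matrices from
#'   [build_features()] for presences and background (same columns; the
#'   presence matrix must carry the calibration `"spec"` attribute or one
#'   must be supplied via `spec`).
#' @param rm regularization multiplier scaling all penalties.
#' @param spec optional [feature_spec()] override.
#' @param tol convergence threshold on the objective change.
#' @param max_iter iteration cap; non-convergence is recorded, not an error.
#' @return object of class `ppm_model`: coefficients, penalties, feature
#'   spec, background log-normalizer `log_z`, entropy `H` of the fitted
#'   raw distribution over the background, sample sizes and convergence
#'   metadata.
#' @export
ppm_fit <- function(pres_features, bg_features, rm = 1, spec = NULL,
                    tol = 1e-5, max_iter = 5000) {
  Fp <- unclass(pres_features); Fb <- unclass(bg_features)
  if (is.null(spec)) spec <- attr(pres_features, "spec")
  if (!identical(colnames(Fp), colnames(Fb)))
    stop("presence and background feature columns differ")
  if (any(!is.finite(Fp)) || any(!is.finite(Fb)))
    stop("non-finite feature values")
  n <- nrow(Fp)
  if (n < 2) stop("need at least 2 presences")
  if (nrow(Fb) < n)
    warning("background smaller than presence sample; estimates may be unstable")
  classes <- if (!is.null(spec)) spec$classes else
    if (any(grepl("\\^2$", colnames(Fp)))) c("linear", "quadratic") else "linear"
  lambda <- ppm_penalties(Fp, classes, rm)

  mean_p <- colMeans(Fp)
  smooth <- function(b) {
    eta <- drop(Fb %*% b)
    list(val = -sum(mean_p * b) + logsumexp(eta), eta = eta)
  }
  grad <- function(eta) {
    w <- exp(eta - logsumexp(eta))
    drop(crossprod(Fb, w)) - mean_p
  }
  obj <- function(b, sval) sval + sum(lambda * abs(b))

  K <- ncol(Fp)
  beta <- numeric(K)
  y <- beta
  t_k <- 1
  step <- 1
  s <- smooth(beta)
  f_old <- obj(beta, s$val)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    sy <- smooth(y)
    g <- grad(sy$eta)
    # backtracking line search on the smooth majorization
    repeat {
      b_new <- sign(y - step * g) * pmax(abs(y - step * g) - step * lambda, 0)
      d <- b_new - y
      s_new <- smooth(b_new)
      if (s_new$val <= sy$val + sum(g * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    f_new <- obj(b_new, s_new$val)
    if (f_new > f_old) {         # restart acceleration on non-monotone step
      y <- beta; t_k <- 1
      next
    }
    y <- b_new + ((t_k - 1) / t_new) * (b_new - beta)
    beta <- b_new
    t_k <- t_new
    if (abs(f_old - f_new) < tol) {
      f_old <- f_new
      converged <- TRUE
      break
    }
    f_old <- f_new
  }
  eta_b <- drop(Fb %*% beta)
  log_z <- logsumexp(eta_b)
  raw <- exp(eta_b - log_z)
  H <- -sum(raw * (eta_b - log_z))
  structure(list(beta = stats::setNames(beta, colnames(Fp)),
                 lambda = lambda, rm = rm, spec = spec,
                 log_z = log_z, entropy = H,
                 n_presences = n, n_background = nrow(Fb),
                 converged = converged, iterations = iter,
                 objective = f_old),
            class = "ppm_model")
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf("ppm_model: %d features (%d nonzero), rm = %g, n = %d presences\n",
              length(x$beta), sum(x$beta != 0), x$rm, x$n_presences))
  cat(sprintf("  entropy H = %.4f, converged = %s (%d iterations)\n",
              x$entropy, x$converged, x$iterations))
  invisible(x)
}

#' Predict suitability from a fitted point-process model
#'
#' `raw` is the relative intensity normalized by the calibration
#' background (it sums to 1 over the calibration background); `cloglog`
#' is `1 - exp(-exp(H) * raw)`, a 0-1 suitability index that preserves
#' the ordering of the linear predictor.
#'
#' @param object a [ppm_model()] fit.
#' @param newdata predictor value matrix (columns named as in calibration)
#'   or a prebuilt feature matrix with matching columns.
#' @param type `"raw"` or `"cloglog"`.
#' @param clamp clamp features to the calibration [0, 1] range (used when
#'   projecting beyond calibration conditions).
#' @param ... unused.
#' @return numeric vector of suitabilities.
#' @export
predict.ppm_model <- function(object, newdata, type = c("cloglog", "raw"),
                              clamp = FALSE, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (identical(colnames(newdata), names(object$beta))) {
    F <- newdata
  } else {
    F <- build_features(newdata, object$spec, clamp = clamp)
    if (!identical(colnames(F), names(object$beta)))
      stop("feature specification mismatch between model and newdata")
  }
  eta <- drop(F %*% object$beta)
  raw <- exp(eta - object$log_z)
  if (type == "raw") raw else 1 - exp(-exp(object$entropy) * raw)
}

#' Small-sample corrected AIC for a point-process model
#'
#' The raw prediction is re-standardized to sum to one over the supplied
#' full set of grid cells; the log-likelihood is the sum of log
#' standardized intensities at the presences; K counts nonzero
#' coefficients. Candidates with `n - K - 1 <= 0` are flagged invalid
#' (`valid = FALSE`, `aicc = NA`) rather than raising an error.
#'
#' @param model a [ppm_model()].
#' @param pres_values predictor values at presences.
#' @param grid_values predictor values over the full grid (or background).
#' @return list with `aicc`, `logL`, `K`, `n`, `valid`.
#' @export
ppm_aicc <- function(model, pres_values, grid_values) {
  Fp <- build_features(as.matrix(pres_values), model$spec, clamp = TRUE)
  Fg <- build_features(as.matrix(grid_values), model$spec, clamp = TRUE)
  eta_p <- drop(Fp %*% model$beta)
  eta_g <- drop(Fg %*% model$beta)
  lse <- logsumexp(eta_g)
  logL <- sum(eta_p - lse)
  K <- sum(model$beta != 0)
  n <- nrow(Fp)
  if (n - K - 1 <= 0)
    return(list(aicc = NA_real_, logL = logL, K = K, n = n, valid = FALSE))
  list(aicc = aicc_formula(K, n, logL), logL = logL, K = K, n = n, valid = TRUE)
}

# Small-sample AIC correction (Hurvich-Tsai form).
aicc_formula <- function(K, n, logL) {
  2 * K - 2 * logL + 2 * K * (K + 1) / (n - K - 1)
}

#' Sample background cells from a raster stack
#'
#' Uniform random sample of unmasked cells (without replacement when
#' enough cells exist, otherwise all cells are used and a message is
#' emitted). Returns the predictor matrix at the sampled cells with cell
#' ids in the `"cell"` attribute.
#'
#' @param stack a [raster_stack()].
#' @param n number of background points (default 10,000).
#' @param seed RNG seed.
#' @export
sample_background <- function(stack, n = 10000, seed = NULL) {
  M <- stack_matrix(stack)
  ok <- which(!is.na(rowSums(M)))
  if (!length(ok)) stop("stack has no unmasked cells")
  if (length(ok) <= n) {
    message("background request (", n, ") >= unmasked cells (", length(ok),
            "); using all cells")
    idx <- ok
  } else {
    idx <- with_seed(seed, ok[sample.int(length(ok), n)])
  }
  out <- M[idx, , drop = FALSE]
  attr(out, "cell") <- idx
  out
}
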