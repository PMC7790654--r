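#' Feature specification for point-process models
#'
#' Holds the feature classes (linear and/or quadratic) and the per-
#' predictor scaling bounds computed from calibration data. Linear
#' features are min-max scaled predictor values; quadratic features are
#' min-max scaled squared values. On calibration data all features lie in
#' [0, 1]; projection data outside the calibration range is clamped.
#'
#' @param classes subset of `c("linear", "quadratic")`.
#' @param bounds optional list of scaling bounds as produced by
#'   [build_features()]; computed from data when absent.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic"), bounds = NULL) {
  classes <- match.arg(classes, c("linear", "quadratic"), several.ok = TRUE)
  structure(list(classes = classes, bounds = bounds), class = "feature_spec")
}

#' Build the model feature matrix
#'
#' @param values predictor matrix (rows = samples, named columns).
#' @param spec a [feature_spec()]; when its bounds are `NULL` they are
#'   computed from `values` (calibration mode) and returned in the
#'   `"spec"` attribute.
#' @param clamp clamp features to [0, 1] (projection mode); the clamped
#'   fraction is recorded in the `"clamp_fraction"` attribute.
#' @return feature matrix with attributes `spec` and `clamp_fraction`.
#' @export
build_features <- function(values, spec = feature_spec(), clamp = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("x", seq_len(ncol(values)))
  if (any(!is.finite(values))) stop("non-finite predictor values")
  if (is.null(spec$bounds)) {
    bounds <- list()
    for (p in colnames(values)) {
      x <- values[, p]
      if (max(x) == min(x))
        stop("constant predictor: ", p)
      bounds[[p]] <- list(lin = range(x), quad = range(x^2))
    }
    spec$bounds <- bounds
  }
  pred <- names(spec$bounds)
  missing <- setdiff(pred, colnames(values))
  if (length(missing))
    stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
  cols <- list()
  for (p in pred) {
    b <- spec$bounds[[p]]
    if ("linear" %in% spec$classes)
      cols[[p]] <- (values[, p] - b$lin[1]) / diff(b$lin)
    if ("quadratic" %in% spec$classes)
      cols[[paste0(p, "^2")]] <- (values[, p]^2 - b$quad[1]) / diff(b$quad)
  }
  F <- do.call(cbind, cols)
  clamp_frac <- 0
  if (clamp) {
    out <- F < 0 | F > 1
    clamp_frac <- mean(out)
    F[F < 0] <- 0
    F[F > 1] <- 1
  }
  attr(F, "spec") <- spec
  attr(F, "clamp_fraction") <- clamp_frac
  F
}
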