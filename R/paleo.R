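#' Project a fitted model onto a (possibly alternative-period) stack
#'
#' Builds the model features from the stack layers named in the model's
#' feature specification, clamping to the calibration [0, 1] feature
#' range, and returns the cloglog suitability surface computed with the
#' model's stored background normalizer and entropy. Projecting onto the
#' calibration stack therefore reproduces the training suitability
#' exactly.
#'
#' @param model a [ppm_model()].
#' @param stack a [raster_stack()] supplying every model predictor.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @return a [geo_grid()] of suitabilities, with the clamped feature
#'   fraction in the `"clamp_fraction"` attribute.
#' @export
project_model <- function(model, stack, type = c("cloglog", "raw")) {
  type <- match.arg(type)
  need <- names(model$spec$bounds)
  missing <- setdiff(need, names(stack$layers))
  if (length(missing))
    stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
  M <- stack_matrix(stack)[, need, drop = FALSE]
  ok <- !is.na(rowSums(M))
  out <- rep(NA_real_, nrow(M))
  F <- build_features(M[ok, , drop = FALSE], model$spec, clamp = TRUE)
  out[ok] <- predict(model, F, type = type)
  g <- stack_grid(stack)
  res <- geo_grid(matrix(out, grid_nrow(g), grid_ncol(g)),
                  g$origin_lon, g$origin_lat, g$cell_size)
  attr(res, "clamp_fraction") <- attr(F, "clamp_fraction")
  res
}

#' Cell-wise ensemble of suitability grids
#'
#' @param grids list of [geo_grid()]s on one lattice.
#' @param method `"mean"` (default) or `"sum"`; nodata in any member
#'   propagates.
#' @return a [geo_grid()].
#' @export
ensemble_grids <- function(grids, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(length(grids) >= 1)
  g1 <- grids[[1]]
  for (g in grids)
    if (!same_geometry(g1, g)) stop("grids are on mismatched lattices")
  acc <- Reduce(`+`, lapply(grids, function(g) g$values))
  if (method == "mean") acc <- acc / length(grids)
  geo_grid(acc, g1$origin_lon, g1$origin_lat, g1$cell_size)
}

#' Schoener's D niche overlap between two suitability surfaces
#'
#' Each surface is normalized to sum to 1 over the cells unmasked in
#' both; `D = 1 - 0.5 * sum(|p - q|)` ranges from 0 (disjoint) to 1
#' (identical).
#'
#' @param g1,g2 [geo_grid()]s on a common lattice.
#' @return D in [0, 1]; `NA` with a warning if either surface sums to 0.
#' @export
schoeners_d <- function(g1, g2) {
  if (!same_geometry(g1, g2)) stop("grids are on mismatched lattices")
  a <- as.vector(g1$values); b <- as.vector(g2$values)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no shared unmasked cells")
  a <- a[ok]; b <- b[ok]
  if (sum(a) <= 0 || sum(b) <= 0) {
    warning("all-zero surface; Schoener's D undefined")
    return(NA_real_)
  }
  1 - 0.5 * sum(abs(a / sum(a) - b / sum(b)))
}

#' Climate-stability classification
#'
#' Combines the current binary range with binary maps for past periods.
#' With `c` the current state and `f` the fraction of past periods in
#' which a cell is suitable: `stable` (c = 1, f = 1), `colonizable`
#' (c = 1, f < 1), `unstable` (c = 0, f > 0), `absence` (c = 0, f = 0).
#' The numeric code layer maps absence to -2, colonizable to `f - 1`
#' (in (-1, 0]), stable to 1, and unstable to 2.
#'
#' @param current a binary [geo_grid()].
#' @param past list of binary [geo_grid()]s (>= 1) on the same lattice.
#' @return list with `class` ([geo_grid()] of class indices 1-4),
#'   `code` ([geo_grid()] of the numeric legend), `f` (past suitable
#'   fraction grid), and `code_book`.
#' @export
stability_map <- function(current, past) {
  stopifnot(length(past) >= 1)
  for (g in past)
    if (!same_geometry(current, g)) stop("grids are on mismatched lattices")
  cvec <- as.vector(current$values)
  fmat <- vapply(past, function(g) as.vector(g$values), numeric(length(cvec)))
  f <- rowMeans(fmat)
  cls <- rep(NA_integer_, length(cvec))
  code <- rep(NA_real_, length(cvec))
  ok <- !is.na(cvec) & !is.na(f)
  cls[ok & cvec == 0 & f == 0] <- 1L                      # absence
  cls[ok & cvec == 1 & f < 1] <- 2L                       # colonizable
  cls[ok & cvec == 1 & f == 1] <- 3L                      # stable
  cls[ok & cvec == 0 & f > 0] <- 4L                       # unstable
  code[which(cls == 1L)] <- -2
  code[which(cls == 2L)] <- f[which(cls == 2L)] - 1
  code[which(cls == 3L)] <- 1
  code[which(cls == 4L)] <- 2
  shape <- function(v) geo_grid(matrix(v, grid_nrow(current), grid_ncol(current)),
                                current$origin_lon, current$origin_lat,
                                current$cell_size)
  list(class = shape(as.numeric(cls)), code = shape(code), f = shape(f),
       code_book = c(`1` = "absence", `2` = "colonizable", `3` = "stable",
                     `4` = "unstable"))
}
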