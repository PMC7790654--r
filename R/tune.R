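#' Hierarchical spatial partition of points into 4 folds
#'
#' Assigns each point to one of four spatially structured folds by
#' crossing two block colorings of the grid: a fine checkerboard on
#' blocks of `agg1` cells, and a coarse latitudinal banding on blocks of
#' `agg1 * agg2` cells. The crossing yields 4 spatial folds; on dense
#' uniform point sets each fold holds about a quarter of the points.
#'
#' @param points data frame with `lon`/`lat`.
#' @param grid a [geo_grid()] supplying the cell lattice.
#' @param agg1 aggregation factor (cells per checkerboard block).
#' @param agg2 second-level aggregation factor (blocks per band).
#' @return integer vector of fold labels in 1..4; empty folds trigger a
#'   warning.
#' @export
checkerboard_partition <- function(points, grid, agg1 = 2, agg2 = 2) {
  stopifnot(agg1 >= 1, agg2 >= 1)
  rc <- cell_of(grid, points$lon, points$lat)
  if (anyNA(rc)) stop("points outside the grid extent")
  r0 <- rc[, "row"] - 1L; c0 <- rc[, "col"] - 1L
  l1 <- (r0 %/% agg1 + c0 %/% agg1) %% 2L
  l2 <- (r0 %/% (agg1 * agg2)) %% 2L
  fold <- as.integer(2L * l2 + l1 + 1L)
  if (length(unique(fold)) < 4L)
    warning("empty spatial fold(s): only ", length(unique(fold)),
            " of 4 folds contain points")
  fold
}

#' Seeded random k-fold partition
#'
#' Non-spatial alternative partition (e.g. 5 folds).
#' @param n number of points.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold labels in 1..k.
#' @export
random_partition <- function(n, k = 5, seed = NULL) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Tune regularization and feature classes by AICc
#'
#' Fits one candidate model per combination of regularization multiplier
#' and feature-class set (default 9 x 2 = 18 candidates) on the full
#' presence set, scores each by AICc against the full grid, and (when a
#' partition is supplied) cross-validates AUC and omission rates by
#' training on all folds but one. The candidate minimizing AICc is
#' selected; ties break toward fewer nonzero coefficients, then a smaller
#' regularization multiplier.
#'
#' @param pres_values,bg_values predictor matrices at presences and
#'   background.
#' @param grid_values predictor matrix over the full grid for the AICc
#'   standardization (defaults to `bg_values`).
#' @param rm_grid regularization multipliers (default 1 to 5 by 0.5).
#' @param class_grid named list of feature-class sets.
#' @param folds optional integer fold label per presence (e.g. from
#'   [checkerboard_partition()]); enables the cross-validated columns.
#' @param tol,max_iter passed to [ppm_fit()].
#' @return list with `table` (the candidate data frame, ordered as
#'   evaluated, with a `delta_aicc` column), `model` (the selected
#'   [ppm_model()]), and `selected` (its row index).
#' @export
ppm_tune <- function(pres_values, bg_values, grid_values = NULL,
                     rm_grid = seq(1, 5, by = 0.5),
                     class_grid = list(L = "linear", LQ = c("linear", "quadratic")),
                     folds = NULL, tol = 1e-5, max_iter = 5000) {
  stopifnot(length(rm_grid) >= 1, length(class_grid) >= 1)
  pres_values <- as.matrix(pres_values); bg_values <- as.matrix(bg_values)
  if (is.null(grid_values)) grid_values <- bg_values
  cand <- expand.grid(class = names(class_grid), rm = rm_grid,
                      stringsAsFactors = FALSE)
  cand <- cand[order(cand$rm, match(cand$class, names(class_grid))), ]
  rownames(cand) <- NULL
  models <- vector("list", nrow(cand))
  rows <- vector("list", nrow(cand))
  calib <- rbind(pres_values, bg_values)
  for (i in seq_len(nrow(cand))) {
    classes <- class_grid[[cand$class[i]]]
    spec <- feature_spec(classes)
    Fc <- build_features(calib, spec)
    spec <- attr(Fc, "spec")
    Fp <- Fc[seq_len(nrow(pres_values)), , drop = FALSE]
    Fb <- Fc[-seq_len(nrow(pres_values)), , drop = FALSE]
    fit <- ppm_fit(Fp, Fb, rm = cand$rm[i], spec = spec,
                   tol = tol, max_iter = max_iter)
    ic <- ppm_aicc(fit, pres_values, grid_values)
    cv <- c(auc_train = NA_real_, auc_test = NA_real_, auc_diff = NA_real_,
            or_mtp = NA_real_, or_10tp = NA_real_)
    if (!is.null(folds)) {
      per <- lapply(sort(unique(folds)), function(f) {
        tr <- folds != f
        if (sum(tr) < 2 || sum(!tr) < 1) return(NULL)
        m <- ppm_fit(Fp[tr, , drop = FALSE], Fb, rm = cand$rm[i], spec = spec,
                     tol = tol, max_iter = max_iter)
        s_tr <- predict(m, Fp[tr, , drop = FALSE], type = "cloglog")
        s_te <- predict(m, Fp[!tr, , drop = FALSE], type = "cloglog")
        s_bg <- predict(m, Fb, type = "cloglog")
        c(auc_train = auc(s_tr, s_bg), auc_test = auc(s_te, s_bg),
          or_mtp = omission_rate(s_te, presence_threshold(s_tr, "mtp")),
          or_10tp = omission_rate(s_te, presence_threshold(s_tr, "p10")))
      })
      per <- do.call(rbind, Filter(Negate(is.null), per))
      if (!is.null(per)) {
        mu <- colMeans(per)
        cv <- c(auc_train = unname(mu["auc_train"]),
                auc_test = unname(mu["auc_test"]),
                auc_diff = unname(mu["auc_train"] - mu["auc_test"]),
                or_mtp = unname(mu["or_mtp"]), or_10tp = unname(mu["or_10tp"]))
      }
    }
    models[[i]] <- fit
    rows[[i]] <- data.frame(rm = cand$rm[i], classes = cand$class[i],
                            K = ic$K, logL = ic$logL, aicc = ic$aicc,
                            auc_train = cv["auc_train"], auc_test = cv["auc_test"],
                            auc_diff = cv["auc_diff"], or_mtp = cv["or_mtp"],
                            or_10tp = cv["or_10tp"], valid = ic$valid,
                            converged = fit$converged, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$valid)) stop("all candidate models are invalid (n - K - 1 <= 0)")
  aic_ok <- ifelse(tab$valid, tab$aicc, Inf)
  ord <- order(aic_ok, tab$K, tab$rm)
  sel <- ord[1]
  tab$delta_aicc <- ifelse(tab$valid, tab$aicc - tab$aicc[sel], NA_real_)
  list(table = tab, model = models[[sel]], selected = sel)
}
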