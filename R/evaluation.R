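#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(pos > neg) + 0.5 P(pos = neg)` computed from ranks, identical to the
#' normalized Mann-Whitney U statistic.
#'
#' @param pos_scores,neg_scores numeric score vectors (both nonempty).
#' @return AUC in [0, 1].
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Presence-score thresholds
#'
#' `mtp` is the minimum training-presence score; `p10` is the empirical
#' 10th percentile of training-presence scores (linear interpolation
#' between order statistics, i.e. the rule that removes the lowest 10% of
#' predicted presence values).
#'
#' @param train_scores scores of training presences.
#' @param rule `"mtp"` or `"p10"`.
#' @return threshold value.
#' @export
presence_threshold <- function(train_scores, rule = c("mtp", "p10")) {
  stopifnot(length(train_scores) > 0)
  rule <- match.arg(rule)
  if (rule == "mtp") min(train_scores)
  else unname(stats::quantile(train_scores, 0.10, type = 7))
}

#' Omission rate at a threshold
#'
#' Fraction of test scores strictly below the threshold (so the MTP
#' omission of the training data itself is 0 by construction).
#'
#' @param test_scores scores of test presences.
#' @param threshold binarization threshold.
#' @return omission rate in [0, 1].
#' @export
omission_rate <- function(test_scores, threshold) {
  stopifnot(length(test_scores) > 0)
  mean(test_scores < threshold)
}

# Partial area under the (proportion-of-area, sensitivity) curve for
# sensitivity >= 1 - E, plus the area under the 1:1 null line on the same
# x-domain. x and y are coordinates ordered by increasing x, starting at
# (0, 0) and ending at (1, 1).
partial_areas <- function(x, y, E) {
  y0 <- 1 - E
  above <- y >= y0 - 1e-12
  if (!any(above)) return(c(model = 0, null = 0))
  i0 <- which(above)[1]
  if (i0 > 1) {  # interpolate the crossing of y = 1 - E
    x1 <- x[i0 - 1]; x2 <- x[i0]; y1 <- y[i0 - 1]; y2 <- y[i0]
    xc <- if (y2 > y1) x1 + (y0 - y1) * (x2 - x1) / (y2 - y1) else x2
    xs <- c(xc, x[above]); ys <- c(y0, y[above])
  } else {
    xs <- x[above]; ys <- y[above]
  }
  a_model <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  a_null <- (utils::tail(xs, 1)^2 - xs[1]^2) / 2
  c(model = a_model, null = a_null)
}

#' Bootstrap partial ROC ratio
#'
#' Tests a suitability surface against a random-model null while giving
#' precedence to omission over commission errors. Per bootstrap
#' replicate, `ceil(boot_prop * n)` test-presence scores are resampled
#' with replacement; the curve of (proportion of all cells scoring at or
#' above a threshold, sensitivity of the resample at that threshold) is
#' restricted to sensitivity `>= 1 - E` and its partial area is divided
#' by the partial area of the 1:1 line on the same region. Ratios near 1
#' indicate a random model; the p-value is the fraction of replicates
#' with ratio <= 1.
#'
#' @param cell_scores suitability over all (unmasked) cells.
#' @param test_scores suitability at test presences.
#' @param E allowed omission error rate (default 0.05).
#' @param n_boot bootstrap replicates (default 1000).
#' @param boot_prop resampled proportion of test points (default 0.5).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `range`, `p`, and the replicate `ratios`.
#' @export
partial_roc <- function(cell_scores, test_scores, E = 0.05, n_boot = 1000,
                        boot_prop = 0.5, seed = NULL) {
  stopifnot(E > 0, E < 1, length(test_scores) > 0)
  cell_scores <- cell_scores[!is.na(cell_scores)]
  if (length(unique(cell_scores)) < 2)
    stop("need at least 2 distinct cell scores")
  sc <- sort(cell_scores)
  ncell <- length(sc)
  thr <- unique(sc)
  if (length(thr) > 1500) thr <- unique(stats::quantile(sc, seq(0, 1, length.out = 1500), type = 7))
  # x(t): proportion of cells with score >= t, decreasing in t
  x <- (ncell - findInterval(thr, sc, left.open = TRUE)) / ncell
  ord <- order(x)
  thr_o <- thr[ord]; x_o <- x[ord]
  m <- ceiling(boot_prop * length(test_scores))
  ratios <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bs <- sort(test_scores[sample.int(length(test_scores), m, replace = TRUE)])
    y <- (m - findInterval(thr_o, bs, left.open = TRUE)) / m
    a <- partial_areas(c(0, x_o, 1), c(0, y, 1), E)
    if (a["null"] <= 0) NA_real_ else unname(a["model"] / a["null"])
  }, numeric(1)))
  ratios <- ratios[!is.na(ratios)]
  list(mean = mean(ratios), sd = stats::sd(ratios), range = range(ratios),
       p = mean(ratios <= 1), ratios = ratios)
}

#' Continuous Boyce Index
#'
#' Measures calibration of a suitability surface: across moving windows
#' spanning the background score range, the predicted-to-expected ratio
#' `F_i = P_i / E_i` (share of presence scores in window i over share of
#' background scores in it) should increase with suitability for a
#' well-calibrated model. CBI is the Spearman correlation between `F_i`
#' and the window centers; windows with no background mass are dropped.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @param n_windows number of moving windows (default 101).
#' @param window_frac window width as a fraction of the background score
#'   range (default 0.1).
#' @return CBI in [-1, 1], or `NA` (with a warning) when fewer than 3
#'   windows are usable.
#' @export
continuous_boyce <- function(presence_scores, background_scores,
                             n_windows = 101, window_frac = 0.1) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  lo <- min(background_scores); hi <- max(background_scores)
  w <- window_frac * (hi - lo)
  if (w <= 0) { warning("degenerate background score range"); return(NA_real_) }
  centers <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  P <- vapply(centers, function(cc)
    mean(presence_scores >= cc - w / 2 & presence_scores <= cc + w / 2), numeric(1))
  E <- vapply(centers, function(cc)
    mean(background_scores >= cc - w / 2 & background_scores <= cc + w / 2), numeric(1))
  use <- E > 0
  if (sum(use) < 3) { warning("fewer than 3 usable windows"); return(NA_real_) }
  stats::cor(P[use] / E[use], centers[use], method = "spearman")
}

#' Cross-validated Continuous Boyce Index
#'
#' Splits the presence scores into `k` seeded folds and evaluates
#' [continuous_boyce()] of each held-out fold (1/k of the presences, 20%
#' for the default 5 folds) against the background; reports the per-fold
#' values and their mean.
#'
#' @inheritParams continuous_boyce
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return list with `mean` and per-fold `folds`.
#' @export
boyce_cv <- function(presence_scores, background_scores, k = 5, seed = NULL,
                     n_windows = 101, window_frac = 0.1) {
  fold <- random_partition(length(presence_scores), k, seed)
  vals <- vapply(seq_len(k), function(f)
    continuous_boyce(presence_scores[fold == f], background_scores,
                     n_windows, window_frac), numeric(1))
  list(mean = mean(vals, na.rm = TRUE), folds = vals)
}

#' Evaluation report for a fitted model
#'
#' Bundles the discrimination, calibration and null-comparison metrics
#' for one train/test split of the presence scores.
#'
#' @param train_scores,test_scores presence suitability scores.
#' @param bg_scores background suitability scores.
#' @param cell_scores suitability over all cells (for the partial ROC);
#'   defaults to `bg_scores`.
#' @param seed RNG seed for the bootstrap and CBI folds.
#' @param n_boot partial-ROC bootstrap replicates.
#' @return list of class `evaluation_report`.
#' @export
evaluate_model <- function(train_scores, test_scores, bg_scores,
                           cell_scores = bg_scores, seed = NULL,
                           n_boot = 1000) {
  seeds <- expand_seeds(if (is.null(seed)) 0 else seed, 2)
  mtp <- presence_threshold(train_scores, "mtp")
  p10 <- presence_threshold(train_scores, "p10")
  pr <- partial_roc(cell_scores, test_scores, seed = seeds[1], n_boot = n_boot)
  cbi <- boyce_cv(c(train_scores, test_scores), bg_scores, seed = seeds[2])
  structure(list(
    auc_train = auc(train_scores, bg_scores),
    auc_test = auc(test_scores, bg_scores),
    auc_diff = auc(train_scores, bg_scores) - auc(test_scores, bg_scores),
    threshold_mtp = mtp, threshold_10tp = p10,
    or_mtp = omission_rate(test_scores, mtp),
    or_10tp = omission_rate(test_scores, p10),
    proc_mean = pr$mean, proc_sd = pr$sd, proc_range = pr$range, proc_p = pr$p,
    cbi_mean = cbi$mean, cbi_folds = cbi$folds), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC train %.3f / test %.3f (diff %.3f)\n",
              x$auc_train, x$auc_test, x$auc_diff))
  cat(sprintf("Omission: MTP %.3f, 10TP %.3f (thresholds %.3f / %.3f)\n",
              x$or_mtp, x$or_10tp, x$threshold_mtp, x$threshold_10tp))
  cat(sprintf("pROC ratio %.3f +/- %.3f (range %.3f-%.3f, p = %.3g)\n",
              x$proc_mean, x$proc_sd, x$proc_range[1], x$proc_range[2], x$proc_p))
  cat(sprintf("CBI mean %.3f\n", x$cbi_mean))
  invisible(x)
}
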