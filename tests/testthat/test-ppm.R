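test_that("feature construction scales to [0,1] with the declared layout", {
  x <- cbind(p = c(0, 2, 5, 10), q = c(-1, 0, 1, 3))
  FL <- build_features(x, feature_spec("linear"))
  expect_equal(ncol(FL), 2)                       # L: one feature per predictor
  expect_equal(unname(FL[, "p"]), c(0, 0.2, 0.5, 1))
  FLQ <- build_features(x, feature_spec(c("linear", "quadratic")))
  expect_equal(ncol(FLQ), 4)                      # LQ: two per predictor
  expect_true(all(FLQ >= 0 & FLQ <= 1))
  # projection beyond calibration bounds is clamped and logged
  spec <- attr(FLQ, "spec")
  Fp <- build_features(cbind(p = c(-5, 20), q = c(0, 0)), spec, clamp = TRUE)
  expect_true(all(Fp >= 0 & Fp <= 1))
  expect_gt(attr(Fp, "clamp_fraction"), 0)
  expect_error(build_features(cbind(p = rep(3, 4)), feature_spec("linear")),
               "constant predictor: p")
})

test_that("overwhelming regularization shrinks all coefficients to zero", {
  w <- tiny_world(seed = 12, n_presences = 150)
  f <- tiny_fit(w, rm = 1e6)
  expect_true(all(f$fit$beta == 0))
  raw <- predict(f$fit, f$bg, type = "raw")
  expect_equal(max(abs(raw - 1 / nrow(f$bg))), 0, tolerance = 1e-12)
  # zero coefficients give the cloglog uniform limit 1 - exp(-1)
  cl <- predict(f$fit, f$bg, type = "cloglog")
  expect_equal(max(abs(cl - (1 - exp(-1)))), 0, tolerance = 1e-12)
})

test_that("predictions normalize over the calibration background and are monotone in eta", {
  w <- tiny_world(seed = 13, n_presences = 200)
  f <- tiny_fit(w)
  raw <- predict(f$fit, f$bg, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  cl <- predict(f$fit, f$bg, type = "cloglog")
  expect_true(all(cl > 0 & cl < 1))
  expect_identical(order(raw), order(cl))
  expect_error(predict(f$fit, f$bg[, 1, drop = FALSE]), "missing predictor")
})

test_that("fit is invariant to predictor rescaling and row duplication", {
  w <- tiny_world(seed = 14, n_presences = 120)
  f1 <- tiny_fit(w)
  # multiply a raw predictor by a constant: min-max features are identical
  w2 <- w
  w2$stack$layers[[1]]$values <- w2$stack$layers[[1]]$values * 37
  w2$pres <- extract_values(w2$stack, w2$occ)
  f2 <- tiny_fit(w2)
  expect_equal(predict(f1$fit, f1$bg, type = "cloglog"),
               predict(f2$fit, f2$bg, type = "cloglog"), tolerance = 1e-8)
  # duplicating every presence row: with n >= 100 the class schedule is
  # flat, so rescaling rm to undo the sqrt(n) and sample-sd changes
  # reproduces identical penalties; the objective (hence beta) is then
  # invariant to the duplication
  f1p <- tiny_fit(w, tol = 1e-9)
  n <- nrow(f1p$Fp)
  Fp2 <- rbind(f1p$Fp, f1p$Fp)
  rm_adj <- sqrt(2) * sqrt((2 * n - 1) / (2 * (n - 1)))   # sd denominator shift
  fit_dup <- ppm_fit(Fp2, f1p$Fb, rm = rm_adj, spec = attr(f1p$Fp, "spec"),
                     tol = 1e-9, max_iter = 20000)
  expect_equal(unname(fit_dup$beta), unname(f1p$fit$beta), tolerance = 1e-3)
})

test_that("the fitted model improves the unpenalized likelihood over beta = 0", {
  w <- tiny_world(seed = 15, n_presences = 200)
  f <- tiny_fit(w)
  unpen <- function(b) {
    -mean(f$Fp %*% b) + ppmrange:::logsumexp(drop(f$Fb %*% b))
  }
  expect_lte(unpen(f$fit$beta), unpen(numeric(length(f$fit$beta))))
})

test_that("IPP and weighted logistic regression agree in the large-weight limit", {
  skip_if_not_installed("glmnet")
  w <- tiny_world(seed = 21, n_rows = 10, n_cols = 15, n_presences = 30)
  f <- tiny_fit(w, tol = 1e-12)
  lambda <- f$fit$lambda
  np <- nrow(f$Fp)
  X <- rbind(f$Fp, f$Fb)
  p <- c(rep(1, np), rep(0, nrow(f$Fb)))
  iwlr <- function(W) {
    wts <- p + (1 - p) * W
    lam <- 10^(seq(4, 0, length.out = 200)) *
      sum(lambda) / length(lambda) * np / sum(wts)
    g <- glmnet::glmnet(x = X, y = as.factor(p), family = "binomial",
                        standardize = FALSE, penalty.factor = lambda,
                        lambda = lam, weights = wts, thresh = 1e-14,
                        maxit = 1e6)
    stats::coef(g)[-1, 200]
  }
  # discrepancy decays with the background weight: the equivalence is the
  # infinitely-weighted limit
  d <- vapply(c(100, 1000, 10000), function(W) max(abs(f$fit$beta - iwlr(W))),
              numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 1e-3)
})

test_that("AICc uses the nonzero-coefficient count and the corrected formula", {
  # hand-built model over 4 grid cells with identity feature bounds
  spec <- feature_spec("linear",
                       bounds = list(p = list(lin = c(0, 1), quad = c(0, 1)),
                                     q = list(lin = c(0, 1), quad = c(0, 1))))
  model <- structure(list(beta = c(p = 1, q = 2), spec = spec, log_z = 0,
                          entropy = 1, rm = 1), class = "ppm_model")
  grid <- cbind(p = c(0, 1, 0, 1), q = c(0, 0, 1, 1))
  pres <- grid[c(2, 4, 4, 3, 2, 4), ]
  # independent arithmetic: eta = p + 2q, softmax over the 4 cells
  eta <- grid %*% c(1, 2)
  got <- ppm_aicc(model, pres, grid)
  expect_equal(got$logL,
               sum(eta[c(2, 4, 4, 3, 2, 4)]) - 6 * log(sum(exp(eta))),
               tolerance = 1e-12)
  expect_equal(got$K, 2)
  expect_equal(got$aicc,
               2 * 2 - 2 * got$logL + 2 * 2 * 3 / (got$n - 2 - 1),
               tolerance = 1e-12)
  # an exactly-zero coefficient changes neither K nor AICc
  model0 <- model; model0$beta <- c(model$beta, r = 0)
  model0$spec$bounds$r <- list(lin = c(0, 1), quad = c(0, 1))
  got0 <- ppm_aicc(model0, cbind(pres, r = rep(0.5, nrow(pres))),
                   cbind(grid, r = rep(0.5, 4)))
  expect_equal(got0$K, 2)
  expect_equal(got0$aicc, got$aicc, tolerance = 1e-12)
  # too few presences for the correction: flagged invalid, no error
  got_bad <- ppm_aicc(model, pres[1:2, ], grid)  # n = 2, K = 2
  expect_false(got_bad$valid)
  expect_true(is.na(got_bad$aicc))
})

test_that("checkerboard partition labels points spatially into 4 folds", {
  g <- geo_grid(matrix(0, 2, 2), 0, 0, 1)
  pts <- data.frame(lon = c(0.5, 1.5, 0.5, 1.5), lat = c(0.5, 0.5, 1.5, 1.5))
  f <- checkerboard_partition(pts, g, 1, 1)
  expect_equal(sort(unique(f)), 1:4)
  # all points inside one block: degenerate folds trigger a warning
  big <- geo_grid(matrix(0, 16, 16), 0, 0, 1)
  inblock <- data.frame(lon = runif(20, 0.1, 0.9), lat = runif(20, 0.1, 0.9))
  expect_warning(checkerboard_partition(inblock, big, 16, 1), "empty spatial fold")
  # uniform points split roughly evenly
  set.seed(2)
  u <- data.frame(lon = runif(4000, 0, 16), lat = runif(4000, 0, 16))
  fu <- checkerboard_partition(u, big, 2, 2)
  expect_true(all(abs(tabulate(fu, 4) - 1000) < 100))
})

test_that("AICc tuning evaluates the full candidate grid and selects the minimum", {
  w <- tiny_world(seed = 16, n_rows = 30, n_cols = 30, n_presences = 100)
  bg <- stack_matrix(w$stack)
  tuned <- ppm_tune(w$pres, bg, rm_grid = c(1, 2), folds = NULL)
  expect_equal(nrow(tuned$table), 4)       # 2 rm x {L, LQ}
  expect_equal(min(tuned$table$delta_aicc), 0)
  expect_true(all(tuned$table$delta_aicc >= 0))
  sel <- tuned$table[tuned$selected, ]
  # idempotence: re-evaluating the selected model reproduces its row
  Fc <- build_features(rbind(w$pres, bg), feature_spec(tuned$model$spec$classes))
  re <- ppm_aicc(tuned$model, w$pres, bg)
  expect_equal(re$aicc, sel$aicc, tolerance = 1e-9)
  # cross-validated columns appear when folds are supplied
  folds <- checkerboard_partition(w$occ, stack_grid(w$stack), 2, 2)
  tuned_cv <- ppm_tune(w$pres, bg, rm_grid = 1, folds = folds)
  expect_true(all(is.finite(tuned_cv$table$auc_test)))
  expect_true(all(tuned_cv$table$auc_test > 0 & tuned_cv$table$auc_test < 1))
})
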