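# An ENFA world: independent standardized layers plus occurrences sampled
# with a controlled environmental bias.
enfa_world <- function(seed = 1, n_layers = 3, nr = 60, nc = 60,
                       beta_linear = rep(0, n_layers), n_occ = 4000,
                       autocorr = 2) {
  sc <- synthetic_scenario(n_rows = nr, n_cols = nc, n_layers = n_layers,
                           autocorr_length = autocorr, seed = seed,
                           beta_linear = beta_linear,
                           beta_quadratic = rep(0, n_layers))
  st <- generate_predictor_stack(sc)
  tr <- true_suitability(st, sc$beta_linear, sc$beta_quadratic)
  occ <- sample_presences(tr$raw, n_occ, seed = seed + 500)
  list(stack = st, occ = occ)
}

test_that("background-identical presences show no marginality or specialization", {
  w <- enfa_world(seed = 31)                      # uniform sampling of cells
  res <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 1e5, seed = 1))
  expect_lte(res$M, 0.08)
  expect_lte(abs(res$S - 1), 0.08)
})

test_that("a one-predictor exponential tilt yields unit marginality on that axis", {
  # sampling cells with probability prop. to exp(z1) tilts the occupied
  # z1 distribution from N(0,1) to N(1,1): m ~ (1, 0, 0), M ~ 1. White
  # noise layers (no smoothing) keep the landscape's own tilted
  # expectation within a couple of percent of the analytic moments.
  w <- enfa_world(seed = 32, nr = 100, nc = 100, autocorr = 0,
                  beta_linear = c(1, 0, 0), n_occ = 8000)
  res <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 1e5, seed = 2))
  # exact multinomial target for this landscape
  Z <- stack_matrix(w$stack)
  wgt <- exp(Z[, 1]); wgt <- wgt / sum(wgt)
  target <- colSums(Z * wgt)
  expect_equal(unname(res$marginality), unname(target), tolerance = 0.1)
  expect_equal(unname(res$marginality[1]), 1, tolerance = 0.12)
  expect_lt(max(abs(res$marginality[2:3])), 0.15)
  expect_equal(res$M, 1, tolerance = 0.15)
})

test_that("specialization factors are R_s-orthogonal with normalized loadings", {
  w <- enfa_world(seed = 33, beta_linear = c(0.8, -0.5, 0))
  res <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 5e4, seed = 3))
  # reconstruct R_s exactly as the fit saw it
  U <- res$loadings
  expect_equal(unname(sqrt(colSums(U^2))), rep(1, ncol(U)), tolerance = 1e-10)
  # R_s-orthogonality via the generalized Rayleigh construction:
  # verify u_i' R_s u_j ~ 0 using the fit's own occupied covariance
  pres <- extract_values(w$stack, w$occ)
  cells <- attr(pres, "cell")
  tab <- table(cells)
  X <- stack_matrix(w$stack)[as.integer(names(tab)), ]
  bg <- suppressMessages(sample_background(w$stack, 5e4, seed = 3))
  Z <- sweep(sweep(X, 2, colMeans(bg)), 2, apply(bg, 2, sd), "/")
  Rs <- ppmrange:::weighted_cov(Z, as.numeric(tab))
  G <- t(U) %*% Rs %*% U
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8)
  expect_true(all(res$eigenvalues >= 0))
  expect_equal(sum(res$variance_share), 100, tolerance = 1e-9)
})

test_that("second factor matches direct Rayleigh-quotient maximization (P = 2, 3)", {
  for (P in 2:3) {
    w <- enfa_world(seed = 40 + P, n_layers = P,
                    beta_linear = c(1, -0.6, 0.3)[1:P])
    res <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 3e4, seed = 4))
    # rebuild the two covariances independently
    pres <- extract_values(w$stack, w$occ)
    tab <- table(attr(pres, "cell"))
    X <- stack_matrix(w$stack)[as.integer(names(tab)), , drop = FALSE]
    bg <- suppressMessages(sample_background(w$stack, 3e4, seed = 4))
    Z <- sweep(sweep(X, 2, colMeans(bg)), 2, apply(bg, 2, sd), "/")
    Zb <- sweep(sweep(unclass(bg), 2, colMeans(bg)), 2, apply(bg, 2, sd), "/")
    Rs <- ppmrange:::weighted_cov(Z, as.numeric(tab))
    Rg <- ppmrange:::weighted_cov(Zb, rep(1, nrow(Zb)))
    u1 <- res$loadings[, "Marg"]
    # basis of the R_s-orthogonal complement of u1
    B <- svd(t(Rs %*% u1), nu = 0, nv = P)$v[, -1, drop = FALSE]
    ray <- function(th) {
      u <- if (P == 2) B[, 1] else cos(th) * B[, 1] + sin(th) * B[, 2]
      drop(t(u) %*% Rg %*% u) / drop(t(u) %*% Rs %*% u)
    }
    lam2_oracle <- if (P == 2) ray(0) else {
      grid <- seq(0, pi, length.out = 721)
      best <- grid[which.max(vapply(grid, ray, numeric(1)))]
      stats::optimize(ray, interval = c(best - 0.02, best + 0.02),
                      maximum = TRUE, tol = 1e-12)$objective
    }
    expect_equal(max(res$eigenvalues[-1]), lam2_oracle, tolerance = 1e-6)
  }
})

test_that("ENFA is invariant to affine predictor changes and occurrence duplication", {
  w <- enfa_world(seed = 35, beta_linear = c(0.7, 0, -0.4))
  r1 <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 2e4, seed = 5))
  st2 <- w$stack
  st2$layers[[2]]$values <- st2$layers[[2]]$values * 13 - 7
  r2 <- suppressMessages(enfa_fit(st2, w$occ, n_background = 2e4, seed = 5))
  expect_equal(r1$M, r2$M, tolerance = 1e-10)
  expect_equal(r1$S, r2$S, tolerance = 1e-10)
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-8)
  # duplicating every occurrence leaves everything unchanged
  occ3 <- rbind(w$occ, w$occ, w$occ)
  r3 <- suppressMessages(enfa_fit(w$stack, occ3, n_background = 2e4, seed = 5))
  expect_equal(r1$M, r3$M, tolerance = 1e-12)
  expect_equal(r1$eigenvalues, r3$eigenvalues, tolerance = 1e-10)
})

test_that("the loadings table orders predictors by absolute marginality", {
  w <- enfa_world(seed = 36, beta_linear = c(0.2, 1, -0.5))
  res <- suppressMessages(enfa_fit(w$stack, w$occ, n_background = 2e4, seed = 6))
  tab <- enfa_loadings_table(res)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(abs(tab$Marg)) <= 0))
  # stable under permutation of the input layer order
  st2 <- raster_stack(w$stack$layers[c(3, 1, 2)])
  res2 <- suppressMessages(enfa_fit(st2, w$occ, n_background = 2e4, seed = 6))
  tab2 <- enfa_loadings_table(res2)
  expect_equal(rownames(tab), rownames(tab2))
  expect_equal(abs(tab$Marg), abs(tab2$Marg), tolerance = 1e-6)
})
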