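test_that("generated layers are standardized and seed-deterministic", {
  sc <- tiny_scenario(seed = 7, n_layers = 3)
  st1 <- generate_predictor_stack(sc)
  st2 <- generate_predictor_stack(sc)
  Z <- stack_matrix(st1)
  expect_true(all(abs(colMeans(Z)) < 1e-8))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-8))
  expect_identical(stack_matrix(st1), stack_matrix(st2))
  # a different seed changes the landscape
  st3 <- generate_predictor_stack(tiny_scenario(seed = 8, n_layers = 3))
  expect_false(identical(stack_matrix(st1), stack_matrix(st3)))
})

test_that("between-layer correlation tracks the requested cross-correlation", {
  # Monte-Carlo over seeds: independent target keeps |r| small, near-unit
  # target forces strong correlation
  # autocorrelation shrinks the effective sample, so keep it mild here
  r_ind <- vapply(1:20, function(s) {
    st <- generate_predictor_stack(synthetic_scenario(
      n_rows = 100, n_cols = 100, n_layers = 2, autocorr_length = 2, seed = s))
    Z <- stack_matrix(st)
    cor(Z[, 1], Z[, 2])
  }, numeric(1))
  expect_lt(median(abs(r_ind)), 0.1)
  expect_lt(max(abs(r_ind)), 0.2)

  C <- matrix(c(1, 0.999, 0.999, 1), 2)
  st <- generate_predictor_stack(synthetic_scenario(
    n_rows = 100, n_cols = 100, n_layers = 2, autocorr_length = 5,
    cross_corr = C, seed = 3))
  Z <- stack_matrix(st)
  expect_gt(cor(Z[, 1], Z[, 2]), 0.9)
})

test_that("non-PSD cross-correlation is rejected with the offending eigenvalue", {
  C <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3 and -1
  expect_error(synthetic_scenario(n_layers = 2, cross_corr = C),
               "positive semi-definite.*-1", ignore.case = TRUE)
  expect_error(synthetic_scenario(n_layers = 2,
                                  cross_corr = matrix(c(1, 0.2, 0.3, 1), 2)),
               "symmetric")
})

test_that("true suitability is a normalized intensity with the cloglog identity", {
  w <- tiny_world(seed = 2)
  raw <- w$truth$raw$values
  expect_equal(sum(raw), 1, tolerance = 1e-12)
  # cloglog preserves the ordering of the linear predictor
  ord_eta <- order(as.vector(w$truth$eta$values))
  expect_identical(ord_eta, order(as.vector(w$truth$cloglog$values)))
  # all-zero coefficients: uniform raw, cloglog = 1 - exp(-1) exactly
  tr0 <- true_suitability(w$stack, c(0, 0), c(0, 0))
  m <- length(tr0$raw$values)
  expect_equal(max(abs(tr0$raw$values - 1 / m)), 0, tolerance = 1e-15)
  expect_equal(max(abs(tr0$cloglog$values - (1 - exp(-1)))), 0,
               tolerance = 1e-12)
  expect_error(true_suitability(w$stack, 0, 0), "match the layer count")
})

test_that("presence sampling follows the intensity surface", {
  st <- generate_predictor_stack(tiny_scenario(seed = 5, n_rows = 10,
                                               n_cols = 10))
  tr0 <- true_suitability(st, c(0, 0), c(0, 0))
  occ <- sample_presences(tr0$raw, 10000, seed = 42)
  g <- tr0$raw
  rc <- cell_of(g, occ$lon, occ$lat)
  counts <- tabulate(rc[, "row"] + (rc[, "col"] - 1L) * 10L, nbins = 100)
  gof <- chisq.test(counts, p = rep(1 / 100, 100))
  expect_gt(gof$p.value, 0.001)

  # all mass in one cell puts every point inside it
  v <- matrix(0, 10, 10); v[4, 7] <- 1
  one <- geo_grid(v, g$origin_lon, g$origin_lat, g$cell_size)
  occ1 <- sample_presences(one, 200, seed = 1)
  rc1 <- cell_of(one, occ1$lon, occ1$lat)
  expect_true(all(rc1[, "row"] == 4 & rc1[, "col"] == 7))

  # determinism and input validation
  expect_identical(sample_presences(tr0$raw, 50, seed = 9),
                   sample_presences(tr0$raw, 50, seed = 9))
  expect_error(sample_presences(tr0$raw, 0), "positive")
})

test_that("multinomial cell counts converge to expectation at large n", {
  st <- generate_predictor_stack(tiny_scenario(seed = 6, n_rows = 8, n_cols = 8))
  tr <- true_suitability(st, c(0.5, -0.3), c(-0.3, -0.2))
  n <- 1e5
  occ <- sample_presences(tr$raw, n, seed = 11)
  rc <- cell_of(tr$raw, occ$lon, occ$lat)
  counts <- tabulate(rc[, "row"] + (rc[, "col"] - 1L) * 8L, nbins = 64)
  expected <- n * as.vector(tr$raw$values)
  z <- (counts - expected) / sqrt(expected * (1 - expected / n))
  # observed/expected ratio near 1 in every cell (3-sigma, Bonferroni slack)
  expect_lt(max(abs(z)), 3 + qnorm(1 - 0.5 / 64))
  expect_lt(abs(sum(counts) / sum(expected) - 1), 1e-12)
})

test_that("asc round-trip preserves grids and stacks", {
  w <- tiny_world(seed = 3)
  d <- withr::local_tempdir()
  f <- file.path(d, "layer.asc")
  g <- w$stack$layers[[1]]
  g$values[2, 3] <- NA
  write_asc(g, f)
  g2 <- read_asc(f)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  expect_equal(g2$cell_size, g$cell_size)
  expect_true(is.na(g2$values[2, 3]))
  write_stack(w$stack, file.path(d, "stk"))
  st2 <- read_stack(file.path(d, "stk"))
  expect_equal(names(st2$layers), names(w$stack$layers))
  expect_equal(stack_matrix(st2), stack_matrix(w$stack), tolerance = 1e-8)
})
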