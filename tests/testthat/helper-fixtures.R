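# Shared fixture builders. Everything is generated in code at test time;
# no data files are read.

# Small standardized landscape with known true coefficients.
tiny_scenario <- function(seed = 1, n_rows = 40, n_cols = 40, n_layers = 2,
                          n_presences = 300,
                          beta_linear = c(1, -0.7)[seq_len(n_layers)],
                          beta_quadratic = c(-0.8, -0.4)[seq_len(n_layers)]) {
  synthetic_scenario(n_rows = n_rows, n_cols = n_cols, n_layers = n_layers,
                     autocorr_length = 3, n_presences = n_presences,
                     beta_linear = beta_linear,
                     beta_quadratic = beta_quadratic, seed = seed)
}

# Generate stack + truth + presences + extracted values in one call.
tiny_world <- function(seed = 1, ...) {
  sc <- tiny_scenario(seed = seed, ...)
  st <- generate_predictor_stack(sc)
  tr <- true_suitability(st, sc$beta_linear, sc$beta_quadratic)
  occ <- sample_presences(tr$raw, sc$n_presences, seed = seed + 1000)
  list(scenario = sc, stack = st, truth = tr, occ = occ,
       pres = extract_values(st, occ))
}

# Fit a model on a tiny world; background = all cells.
tiny_fit <- function(world, rm = 1, classes = c("linear", "quadratic"),
                     tol = 1e-7) {
  bg <- stack_matrix(world$stack)
  Fc <- build_features(rbind(world$pres, bg), feature_spec(classes))
  spec <- attr(Fc, "spec")
  np <- nrow(world$pres)
  fit <- ppm_fit(Fc[seq_len(np), , drop = FALSE],
                 Fc[-seq_len(np), , drop = FALSE],
                 rm = rm, spec = spec, tol = tol, max_iter = 20000)
  list(fit = fit, bg = bg,
       Fp = Fc[seq_len(np), , drop = FALSE],
       Fb = Fc[-seq_len(np), , drop = FALSE])
}

# Exact maximum feasible subset size for the thinning problem:
# branch-and-bound maximum independent set on the conflict graph.
mis_size <- function(A) {
  n <- nrow(A)
  rec <- function(avail, acc) {
    if (!length(avail)) return(acc)
    # bound: even taking every remaining vertex cannot beat the best
    best <- rec(avail[-1], acc)                         # exclude first
    v <- avail[1]
    rest <- avail[-1][!A[v, avail[-1]]]
    with_v <- rec(rest, acc + 1L)                       # include first
    max(best, with_v)
  }
  rec(seq_len(n), 0L)
}

# Points clustered tightly enough that 4 km thinning bites.
random_conflict_points <- function(n, scale_deg = 0.08) {
  data.frame(lon = runif(n, 0, scale_deg), lat = runif(n, 0, scale_deg))
}
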