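#' Default pipeline configuration
#'
#' Returns the bundled synthetic end-to-end configuration: a 100 x 100
#' three-layer landscape with 500 presences, 4 km thinning, the full
#' 18-candidate tuning grid, evaluation, binary range estimation, ENFA
#' and a two-period stability analysis on perturbed ("past") layer
#' stacks. Any element can be overridden via `...` before passing the
#' result to [run_pipeline()].
#'
#' @param ... named overrides of top-level config entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    scenario = list(n_rows = 100, n_cols = 100, n_layers = 3,
                    autocorr_length = 5, n_presences = 500),
    occurrences_csv = NULL,          # path; NULL = simulate from scenario
    predictor_dir = NULL,            # path of .asc layers; NULL = simulate
    thin_km = 4, thin_trials = 20,
    vif_max = 10, rho_max = 0.7,
    rm_grid = seq(1, 5, by = 0.5),
    class_grid = list(L = "linear", LQ = c("linear", "quadratic")),
    background_n = 10000,
    checkerboard = c(2, 2),
    enfa_background_n = 100000,
    n_boot = 1000,
    test_fraction = 0.25,
    past_shifts = c(lgm = -0.6, mid_holocene = -0.25),
    seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full presence-only modelling pipeline
#'
#' Executes, in order: data simulation (or loading), occurrence cleaning
#' and spatial thinning, collinearity-based predictor selection,
#' AICc-tuned point-process model fitting, evaluation (AUC, omission,
#' bootstrap partial ROC, cross-validated CBI), binary range and EOO
#' estimation, ENFA, and projection onto past-period stacks with niche
#' overlap and stability mapping. One master seed is expanded
#' deterministically into per-stage seeds, so a single integer reproduces
#' the whole run; the report embeds the configuration and all stage
#' seeds.
#'
#' @param config configuration list (see [default_config()]) or the path
#'   of a YAML file holding one.
#' @param outdir optional output directory; when given, occurrences
#'   (CSV), layers and suitability (.asc), the candidate table (CSV) and
#'   the run report (JSON) are written there.
#' @param seed optional master seed overriding `config$seed`.
#' @return the run report (named list, invisibly identical to the JSON).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  if (!is.null(seed)) cfg$seed <- seed
  seeds <- expand_seeds(cfg$seed, 8)
  names(seeds) <- c("simulate", "thin", "background", "tune", "evaluate",
                    "enfa", "past", "folds")

  # --- inputs: simulate or load ------------------------------------------
  if (is.null(cfg$predictor_dir)) {
    sc <- do.call(synthetic_scenario,
                  c(cfg$scenario, list(seed = seeds[["simulate"]])))
    stack <- generate_predictor_stack(sc)
    truth <- true_suitability(stack, sc$beta_linear, sc$beta_quadratic)
    occ_raw <- sample_presences(truth$raw, sc$n_presences,
                                seed = seeds[["simulate"]])
  } else {
    if (!dir.exists(cfg$predictor_dir))
      stop("predictor directory not found: ", cfg$predictor_dir)
    stack <- read_stack(cfg$predictor_dir)
    truth <- NULL
    if (is.null(cfg$occurrences_csv) || !file.exists(cfg$occurrences_csv))
      stop("occurrence CSV not found: ", cfg$occurrences_csv)
    occ_raw <- utils::read.csv(cfg$occurrences_csv)
  }

  # --- clean + thin -------------------------------------------------------
  occ <- clean_occurrences(occ_raw)
  occ_thin <- thin_occurrences(occ, min_dist_km = cfg$thin_km,
                               n_trials = cfg$thin_trials,
                               seed = seeds[["thin"]])

  # --- predictor selection ------------------------------------------------
  pres_all <- extract_values(stack, occ_thin)
  sel <- select_uncorrelated(pres_all, vif_max = cfg$vif_max,
                             rho_max = cfg$rho_max)
  use_stack <- raster_stack(stack$layers[sel$retained])
  pres_values <- pres_all[, sel$retained, drop = FALSE]

  # --- background + tuning ------------------------------------------------
  bg <- sample_background(use_stack, cfg$background_n,
                          seed = seeds[["background"]])
  grid_values <- stack_matrix(use_stack)
  grid_ok <- !is.na(rowSums(grid_values))
  folds <- checkerboard_partition(as.data.frame(occ_thin),
                                  stack_grid(use_stack),
                                  cfg$checkerboard[1], cfg$checkerboard[2])
  tuned <- ppm_tune(pres_values, bg, grid_values[grid_ok, , drop = FALSE],
                    rm_grid = cfg$rm_grid, class_grid = cfg$class_grid,
                    folds = folds)
  model <- tuned$model

  # --- evaluation ---------------------------------------------------------
  pres_scores <- predict(model, pres_values, type = "cloglog")
  bg_scores <- predict(model, unclass(bg), type = "cloglog")
  cell_scores <- rep(NA_real_, nrow(grid_values))
  cell_scores[grid_ok] <- predict(model, grid_values[grid_ok, , drop = FALSE],
                                  type = "cloglog", clamp = TRUE)
  is_test <- with_seed(seeds[["folds"]],
                       seq_len(nrow(pres_values)) %in%
                         sample.int(nrow(pres_values),
                                    ceiling(cfg$test_fraction * nrow(pres_values))))
  report_eval <- evaluate_model(pres_scores[!is_test], pres_scores[is_test],
                                bg_scores, cell_scores[grid_ok],
                                seed = seeds[["evaluate"]],
                                n_boot = cfg$n_boot)

  # --- binary range + EOO -------------------------------------------------
  g <- stack_grid(use_stack)
  suit <- geo_grid(matrix(cell_scores, grid_nrow(g), grid_ncol(g)),
                   g$origin_lon, g$origin_lat, g$cell_size)
  thr10 <- presence_threshold(pres_scores[!is_test], "p10")
  range_map <- binarize(suit, thr10)
  range_area <- area_km2(range_map)
  hull <- mcp(occ)
  eoo <- eoo_area(hull)

  # --- ENFA (all cleaned, unfiltered occurrences) -------------------------
  enfa <- enfa_fit(use_stack, occ, n_background = cfg$enfa_background_n,
                   seed = seeds[["enfa"]])

  # --- past projections + stability --------------------------------------
  shift_names <- names(cfg$past_shifts)
  past_suit <- list(); past_bin <- list(); overlap <- list()
  for (i in seq_along(cfg$past_shifts)) {
    shifted <- use_stack
    delta <- cfg$past_shifts[[i]]
    shifted$layers <- lapply(use_stack$layers, function(l)
      geo_grid(l$values + delta, l$origin_lon, l$origin_lat, l$cell_size))
    ps <- project_model(model, shifted)
    past_suit[[shift_names[i]]] <- ps
    past_bin[[shift_names[i]]] <- binarize(ps, thr10)
    overlap[[shift_names[i]]] <- schoeners_d(suit, ps)
  }
  stab <- stability_map(range_map, past_bin)
  class_counts <- table(factor(stab$class$values, levels = 1:4,
                               labels = stab$code_book))

  report <- list(
    package = "ppmrange",
    seed = cfg$seed, stage_seeds = as.list(seeds),
    config = cfg[setdiff(names(cfg), c("class_grid"))],
    occurrences = list(report = as.list(attr(occ, "report")),
                       n_thinned = nrow(occ_thin)),
    predictors = list(n_candidates = ncol(pres_all),
                      retained = sel$retained,
                      dropped = sel$audit$variable),
    model = list(rm = model$rm, classes = model$spec$classes,
                 k_nonzero = sum(model$beta != 0),
                 beta = as.list(model$beta),
                 entropy = model$entropy, converged = model$converged,
                 aicc = tuned$table$aicc[tuned$selected],
                 n_candidates = nrow(tuned$table)),
    evaluation = unclass(report_eval)[c("auc_train", "auc_test", "auc_diff",
                                        "threshold_mtp", "threshold_10tp",
                                        "or_mtp", "or_10tp", "proc_mean",
                                        "proc_sd", "proc_p", "cbi_mean")],
    geography = list(threshold_10tp = thr10, range_area_km2 = range_area,
                     eoo_km2 = eoo),
    enfa = list(M = enfa$M, S = enfa$S,
                marginality = as.list(enfa$marginality),
                variance_share = as.list(enfa$variance_share)),
    paleo = list(schoeners_d = overlap,
                 stability_cells = as.list(class_counts)))
  if (!is.null(truth)) {
    true_raw <- as.vector(truth$raw$values)
    fit_raw <- rep(NA_real_, length(true_raw))
    fit_raw[grid_ok] <- predict(model, grid_values[grid_ok, , drop = FALSE],
                                type = "raw", clamp = TRUE)
    report$truth <- list(
      spearman_raw = stats::cor(true_raw[grid_ok], fit_raw[grid_ok],
                                method = "spearman"))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(occ_thin),
                     file.path(outdir, "occurrences_thinned.csv"),
                     row.names = FALSE)
    write_stack(use_stack, file.path(outdir, "predictors"))
    write_asc(suit, file.path(outdir, "suitability_cloglog.asc"))
    write_asc(range_map, file.path(outdir, "range_binary.asc"))
    write_asc(stab$code, file.path(outdir, "stability_code.asc"))
    utils::write.csv(tuned$table, file.path(outdir, "candidates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
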