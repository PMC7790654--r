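#' Variance inflation factors
#'
#' VIF of column `j` is `1/(1 - R2_j)` where `R2_j` is the coefficient of
#' determination of an ordinary least-squares regression of column `j` on
#' all remaining columns plus an intercept. Perfect collinearity is
#' reported as `Inf`, not an error.
#'
#' @param m numeric matrix or data frame of predictor values (rows =
#'   samples, columns = predictors); at least 2 columns.
#' @param j optional single column (index or name); default all columns.
#' @return named numeric vector of VIFs (or a single value when `j` given).
#' @export
vif <- function(m, j = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("VIF needs at least two columns")
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  one <- function(k) {
    fit <- stats::lm.fit(cbind(1, m[, -k, drop = FALSE]), m[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((m[, k] - mean(m[, k]))^2)
    if (tss == 0) return(Inf)               # constant column
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  if (!is.null(j)) {
    if (is.character(j)) j <- match(j, colnames(m))
    return(one(j))
  }
  stats::setNames(vapply(seq_len(ncol(m)), one, numeric(1)), colnames(m))
}

#' Collinearity-based predictor selection
#'
#' Two-stage screen used before model fitting. Stage 1 (stepwise VIF):
#' while the largest VIF is `>= vif_max`, drop that column (so a column
#' with VIF exactly at the threshold is dropped, i.e. only VIF < `vif_max`
#' survive). Stage 2 (pairwise Spearman): while any remaining pair has
#' `|rho| > rho_max`, take the worst pair and drop the member with the
#' larger mean absolute Spearman correlation to all other remaining
#' columns (the more redundant variable). Ties favour the
#' earlier column, which is retained.
#'
#' @param m numeric matrix/data frame of predictor values at samples.
#' @param vif_max VIF threshold (default 10).
#' @param rho_max absolute Spearman correlation threshold (default 0.7).
#' @return list with `retained` (column names, original order), `audit`
#'   (data frame of every drop: stage, variable, statistic), and the final
#'   `vif` and `spearman` diagnostics.
#' @export
select_uncorrelated <- function(m, vif_max = 10, rho_max = 0.7) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  audit <- data.frame(stage = character(), variable = character(),
                      statistic = numeric(), stringsAsFactors = FALSE)
  keep <- colnames(m)

  # stage 1: stepwise VIF elimination
  while (length(keep) >= 2L) {
    v <- vif(m[, keep, drop = FALSE])
    if (max(v) < vif_max) break
    worst <- which(v == max(v))
    drop <- keep[worst[length(worst)]]      # tie: earlier column wins (stays)
    audit <- rbind(audit, data.frame(stage = "vif", variable = drop,
                                     statistic = max(v)))
    keep <- setdiff(keep, drop)
  }

  # stage 2: pairwise Spearman elimination
  while (length(keep) >= 2L) {
    rho <- stats::cor(m[, keep, drop = FALSE], method = "spearman")
    arho <- abs(rho); diag(arho) <- 0
    if (max(arho) <= rho_max) break
    worst <- which(arho == max(arho), arr.ind = TRUE)[1L, ]
    pair <- sort(unname(worst))
    mean_abs <- rowMeans(arho[pair, , drop = FALSE]) * length(keep) / (length(keep) - 1)
    drop_i <- if (mean_abs[2] >= mean_abs[1]) pair[2] else pair[1]
    drop <- keep[drop_i]
    audit <- rbind(audit, data.frame(stage = "spearman", variable = drop,
                                     statistic = max(arho)))
    keep <- setdiff(keep, drop)
  }

  final_vif <- if (length(keep) >= 2L) vif(m[, keep, drop = FALSE]) else NULL
  final_rho <- if (length(keep) >= 2L)
    stats::cor(m[, keep, drop = FALSE], method = "spearman") else NULL
  list(retained = keep, audit = audit, vif = final_vif, spearman = final_rho)
}
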