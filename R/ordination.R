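# Stage 3: redundancy analysis (RDA) of the releves-by-trait-states matrix
# constrained by observation time (factor) and environment (soil
# temperature, soil relative humidity, canopy height), with permutation
# model tests and adjusted-R^2 variation partitioning.
#
# RDA here is covariance-based: responses are centered (optionally scaled),
# fitted by least squares on the centered predictors, and the constrained
# axes are the principal components of the fitted values.

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- stats::model.matrix(~., data = X)[, -1, drop = FALSE]
  }
  as.matrix(X)
}

#' Redundancy analysis
#'
#' @param Y Numeric response matrix (releves x trait states).
#' @param X Predictor matrix or data frame (factors are dummy-coded).
#' @param scale Scale response columns to unit variance (correlation-based
#'   RDA); default `FALSE` (centering only, since all F columns share the
#'   [0, 1] scale).
#' @return Object of class `rda_lite`: eigenvalues of the constrained axes,
#'   site scores and response loadings, total/constrained/residual variance,
#'   per-axis percentages of total and of constrained variance, `r2`,
#'   `adj_r2`, `pseudo_f`, and the predictor rank (rank-deficient columns
#'   are dropped with a warning).
#' @export
rda_fit <- function(Y, X, scale = FALSE) {
  Y <- as.matrix(Y)
  X <- as_predictor_matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) tb_error("tb_config_error", "Y and X row counts differ")
  Yc <- base::scale(Y, center = TRUE, scale = scale)
  if (scale) Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  Xc <- base::scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  r <- qrX$rank
  if (r < ncol(Xc)) {
    warning(sprintf("predictor matrix rank-deficient: rank %d of %d columns",
                    r, ncol(Xc)))
  }
  if (n <= r + 1) {
    tb_error("tb_config_error", "need n > rank(X) + 1 observations")
  }
  fitted <- qr.fitted(qrX, Yc)
  sv <- svd(fitted)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig[1], 0) * 1e-12 & seq_along(eig) <= r
  eig <- eig[keep]
  total <- sum(Yc^2) / (n - 1)
  constrained <- sum(sv$d^2) / (n - 1)
  r2 <- if (total > 0) constrained / total else 0
  res <- structure(list(
    eig = eig,
    site_scores = sv$u[, keep, drop = FALSE] %*%
      diag(sv$d[keep], sum(keep)),
    loadings = sv$v[, keep, drop = FALSE],
    total_var = total,
    constrained_var = constrained,
    residual_var = total - constrained,
    pct_total = 100 * eig / total,
    pct_constrained = 100 * eig / sum(eig),
    r2 = r2,
    adj_r2 = adjusted_r2(r2, n, r),
    rank = r,
    n = n,
    pseudo_f = (constrained / r) / ((total - constrained) / (n - 1 - r))
  ), class = "rda_lite")
  rownames(res$site_scores) <- rownames(Y)
  rownames(res$loadings) <- colnames(Y)
  res
}

#' @export
print.rda_lite <- function(x, ...) {
  cat(sprintf(
    "rda_lite: %d axes | R2 = %.3f, adj R2 = %.3f, pseudo-F = %.2f\n",
    length(x$eig), x$r2, x$adj_r2, x$pseudo_f))
  if (length(x$eig) > 0) {
    k <- seq_len(min(3, length(x$eig)))
    cat(sprintf("  axes %s: %% total = %s; %% constrained = %s\n",
                paste(k, collapse = ","),
                paste(sprintf("%.1f", x$pct_total[k]), collapse = ", "),
                paste(sprintf("%.1f", x$pct_constrained[k]), collapse = ", ")))
  }
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; may be negative.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number (rank) of predictors.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) {
    tb_error("tb_config_error", "adjusted R2 undefined: n <= p + 1")
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

project_out <- function(M, Z) {
  # residuals of (column-centered) M on [1, Z]
  Mc <- base::scale(M, center = TRUE, scale = FALSE)
  if (is.null(Z) || ncol(Z) == 0) return(Mc)
  Zc <- base::scale(Z, center = TRUE, scale = FALSE)
  qr.resid(qr(Zc), Mc)
}

#' Partial redundancy analysis
#'
#' Both the response and the predictors are residualized on the conditioning
#' block before the RDA. The reported `r2` is the semipartial fraction: the
#' conditional (unique) constrained variance of X given Z, relative to the
#' *total* variance of Y, so that `r2(X | Z) = r2([X Z]) - r2(Z)` exactly.
#'
#' @param Y Response matrix.
#' @param X Predictor block of interest.
#' @param Z Conditioning block (`NULL` or zero columns reduces to
#'   [rda_fit()]).
#' @param scale Scale response columns.
#' @return An `rda_lite` object with extra fields `rank_conditioning` and
#'   `semipartial = TRUE`.
#' @export
partial_rda <- function(Y, X, Z = NULL, scale = FALSE) {
  Y <- as.matrix(Y)
  X <- as_predictor_matrix(X)
  if (!is.null(Z)) Z <- as_predictor_matrix(Z)
  if (is.null(Z) || ncol(Z) == 0) {
    out <- rda_fit(Y, X, scale = scale)
    out$rank_conditioning <- 0L
    out$semipartial <- TRUE
    return(out)
  }
  n <- nrow(Y)
  Yc <- base::scale(Y, center = TRUE, scale = scale)
  if (scale) Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  Zc <- base::scale(Z, center = TRUE, scale = FALSE)
  Xc <- base::scale(X, center = TRUE, scale = FALSE)
  qrZ <- qr(Zc)
  rZ <- qrZ$rank
  qrW <- qr(cbind(Zc, Xc))
  rX <- qrW$rank - rZ  # rank X adds beyond Z, robust to X inside span(Z)
  if (rX < ncol(Xc)) {
    warning(sprintf(
      "conditioned predictor block adds rank %d of %d columns", rX, ncol(Xc)
    ))
  }
  if (n <= rX + rZ + 1) {
    tb_error("tb_config_error", "need n > rank(X) + rank(Z) + 1")
  }
  # P_[ZX] - P_Z projects onto the part of X orthogonal to Z, so the
  # semipartial identity r2(X|Z) = r2([X Z]) - r2(Z) holds exactly
  fitted <- qr.fitted(qrW, Yc) - qr.fitted(qrZ, Yc)
  sv <- svd(fitted)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig[1], 0) * 1e-12 & seq_along(eig) <= max(rX, 1)
  if (rX == 0) keep[] <- FALSE
  total <- sum(Yc^2) / (n - 1)
  constrained <- if (rX == 0) 0 else sum(sv$d^2) / (n - 1)
  resid_var <- sum((Yc - qr.fitted(qrW, Yc))^2) / (n - 1)
  r2 <- if (total > 0) constrained / total else 0
  structure(list(
    eig = eig[keep],
    site_scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep)),
    loadings = sv$v[, keep, drop = FALSE],
    total_var = total,
    constrained_var = constrained,
    residual_var = resid_var,
    pct_total = 100 * eig[keep] / total,
    pct_constrained = if (any(keep)) 100 * eig[keep] / sum(eig[keep])
                      else numeric(0),
    r2 = r2,
    adj_r2 = NA_real_,  # partition-level adjustment happens by differencing
    rank = rX,
    rank_conditioning = rZ,
    n = n,
    semipartial = TRUE,
    pseudo_f = if (rX > 0)
      (constrained / rX) / (resid_var / (n - 1 - rX - rZ)) else NA_real_
  ), class = "rda_lite")
}

rda_stat <- function(qrW, qrZ, Yc, rX, rZ) {
  # partial pseudo-F of X given Z, where qrW spans [Z X]
  n <- nrow(Yc)
  ss_full <- sum(qr.fitted(qrW, Yc)^2)
  ss_z <- if (is.null(qrZ)) 0 else sum(qr.fitted(qrZ, Yc)^2)
  ss_res <- max(sum(Yc^2) - ss_full, 0)
  ((ss_full - ss_z) / rX) / (ss_res / (n - 1 - rX - rZ))
}

#' Permutation test for (partial) RDA
#'
#' Pseudo-F = (constrained variance / rank) / (residual variance / residual
#' df). Under a conditioning block Z, the test permutes the residuals of Y
#' under the reduced (Z-only) model and adds back the Z fit; without Z, rows
#' of the centered response are permuted freely. The Monte Carlo p-value
#' uses the add-one estimator. With `exact = TRUE` all `n!` row permutations
#' are enumerated (n <= 7) and `p = #[F* >= F_obs] / n!`.
#'
#' @param Y Response matrix.
#' @param X Predictor block tested.
#' @param Z Optional conditioning block.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param scale Scale response columns.
#' @param exact Enumerate all row permutations (small n only).
#' @return List with `p_value`, `pseudo_f`, `n_perm`.
#' @export
permutation_test_rda <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL,
                                 scale = FALSE, exact = FALSE) {
  Y <- as.matrix(Y)
  X <- as_predictor_matrix(X)
  Z <- if (is.null(Z)) NULL else as_predictor_matrix(Z)
  n <- nrow(Y)
  Yc <- base::scale(Y, center = TRUE, scale = scale)
  if (scale) Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  Xc <- base::scale(X, center = TRUE, scale = FALSE)
  if (is.null(Z) || ncol(Z) == 0) {
    qrZ <- NULL
    rZ <- 0L
    fit_z <- matrix(0, n, ncol(Yc))
    resid_z <- Yc
    qrW <- qr(Xc)
  } else {
    Zc <- base::scale(Z, center = TRUE, scale = FALSE)
    qrZ <- qr(Zc)
    rZ <- qrZ$rank
    fit_z <- qr.fitted(qrZ, Yc)
    resid_z <- Yc - fit_z
    qrW <- qr(cbind(Zc, Xc))
  }
  rX <- qrW$rank - rZ
  if (rX < 1) tb_error("tb_config_error", "X adds no rank beyond Z")
  if (n <= qrW$rank + 1) {
    tb_error("tb_config_error", "need n > rank([Z X]) + 1")
  }
  f_obs <- rda_stat(qrW, qrZ, Yc, rX, rZ)
  stat_for <- function(perm) {
    Ystar <- fit_z + resid_z[perm, , drop = FALSE]
    # re-center: permutation preserves column means of Yc (= 0), but guard
    rda_stat(qrW, qrZ, Ystar, rX, rZ)
  }
  if (exact) {
    if (factorial(n) > 2e5) {
      tb_error("tb_config_error", "exact enumeration infeasible for this n")
    }
    perms <- multiset_permutations(seq_len(n))
    stats <- vapply(perms, stat_for, 0)
    return(list(p_value = mean(stats >= f_obs - 1e-12), pseudo_f = f_obs,
                n_perm = length(perms)))
  }
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (stat_for(sample.int(n)) >= f_obs - 1e-12) ge <- ge + 1L
  }
  list(p_value = (1 + ge) / (1 + n_perm), pseudo_f = f_obs, n_perm = n_perm)
}

#' Predictor blocks for one community
#'
#' Builds the two aligned predictor blocks for the community's releves:
#' `time` as a dummy-coded unordered factor (12 levels, 10 for a community
#' with skipped times) and `environment` as centered soil temperature, soil
#' relative humidity and canopy height.
#'
#' @param tm A [build_trait_matrix()] result.
#' @param study The source `flowering_study` (for environmental records).
#' @param community Community label.
#' @return List with matrices `Y`, `time`, `env` and the releve `rows`.
#' @export
predictor_blocks <- function(tm, study, community) {
  in_cm <- tm$rows$community == community
  rows <- tm$rows[in_cm, , drop = FALSE]
  Y <- tm$F[in_cm, , drop = FALSE]
  tf <- factor(rows$time_index)
  time_block <- stats::model.matrix(~ tf)[, -1, drop = FALSE]
  colnames(time_block) <- paste0("time_", levels(tf)[-1])
  ekey <- paste(study$env$plot_id, study$env$time_index)
  idx <- match(paste(rows$plot_id, rows$time_index), ekey)
  env_block <- as.matrix(study$env[idx, c("soil_temperature",
                                          "soil_relative_humidity",
                                          "canopy_height")])
  rownames(env_block) <- rownames(time_block) <- rownames(Y)
  list(Y = Y, time = time_block, env = env_block, rows = rows)
}

#' Variation partitioning between time and environment
#'
#' Adjusted-R^2 partition of the explained variance of `Y` into the fraction
#' unique to the time block, unique to the environment block, their shared
#' fraction (obtained by subtraction and possibly negative), and the
#' residual. Only the full model and the two unique fractions are testable
#' by permutation; the shared fraction is not.
#'
#' @param Y Response matrix.
#' @param block_time,block_env Predictor blocks (matrices or data frames).
#' @param n_perm Permutations for the model tests (default 999); `0` skips
#'   testing.
#' @param seed Integer seed.
#' @param scale Scale response columns.
#' @return Object of class `variation_partition`: adjusted-R^2 fractions
#'   `full`, `unique_time`, `unique_env`, `shared`, `residual`, the
#'   unadjusted R^2s, and p-values `p_full`, `p_unique_time`,
#'   `p_unique_env`.
#' @export
variation_partition <- function(Y, block_time, block_env, n_perm = 999,
                                seed = 1L, scale = FALSE) {
  Y <- as.matrix(Y)
  Xt <- as_predictor_matrix(block_time)
  Xe <- as_predictor_matrix(block_env)
  fit_t <- rda_fit(Y, Xt, scale = scale)
  fit_e <- rda_fit(Y, Xe, scale = scale)
  fit_te <- rda_fit(Y, cbind(Xt, Xe), scale = scale)
  full <- fit_te$adj_r2
  unique_time <- full - fit_e$adj_r2
  unique_env <- full - fit_t$adj_r2
  shared <- full - unique_time - unique_env
  p_full <- p_ut <- p_ue <- NA_real_
  if (n_perm > 0) {
    p_full <- permutation_test_rda(Y, cbind(Xt, Xe), n_perm = n_perm,
                                   seed = seed, scale = scale)$p_value
    p_ut <- permutation_test_rda(Y, Xt, Z = Xe, n_perm = n_perm,
                                 seed = seed + 1L, scale = scale)$p_value
    p_ue <- permutation_test_rda(Y, Xe, Z = Xt, n_perm = n_perm,
                                 seed = seed + 2L, scale = scale)$p_value
  }
  structure(list(
    full = full, unique_time = unique_time, unique_env = unique_env,
    shared = shared, residual = 1 - full,
    r2_full = fit_te$r2, r2_time = fit_t$r2, r2_env = fit_e$r2,
    adj_r2_time = fit_t$adj_r2, adj_r2_env = fit_e$adj_r2,
    p_full = p_full, p_unique_time = p_ut, p_unique_env = p_ue,
    n = nrow(Y), n_perm = n_perm
  ), class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat(sprintf(
    paste0("variation_partition (adj R2): full %.3f (p %s) = time %.3f",
           " (p %s) + env %.3f (p %s) + shared %.3f; residual %.3f\n"),
    x$full, format(x$p_full), x$unique_time, format(x$p_unique_time),
    x$unique_env, format(x$p_unique_env), x$shared, x$residual))
  invisible(x)
}

#' Variation partition as a percentage table
#'
#' @param x A `variation_partition`.
#' @return Data frame with `fraction`, `adj_r2_pct` (percent of total
#'   variance, 1-decimal reporting handled by [write_results()]) and
#'   `p_value`.
#' @export
varpart_table <- function(x) {
  data.frame(
    fraction = c("full", "unique_time", "unique_env", "shared", "residual"),
    adj_r2_pct = 100 * c(x$full, x$unique_time, x$unique_env, x$shared,
                         x$residual),
    p_value = c(x$p_full, x$p_unique_time, x$p_unique_env, NA, NA),
    stringsAsFactors = FALSE
  )
}
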