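test_that("univariate RDA equals squared Pearson correlation", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
    fit <- rda_fit(matrix(y), matrix(x))
    expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("perfect fits and orthogonal predictors give R2 of 1 and 0", {
  set.seed(1)
  x <- rnorm(20)
  fit1 <- rda_fit(matrix(x), matrix(x))
  expect_equal(fit1$r2, 1)
  expect_length(fit1$eig, 1L)
  # construct X exactly orthogonal to the centered response
  y <- rnorm(20)
  yc <- y - mean(y)
  xo <- residuals(lm(rnorm(20) ~ yc))
  fit0 <- rda_fit(matrix(y), matrix(xo))
  expect_equal(fit0$r2, 0, tolerance = 1e-12)
})

test_that("variance decomposes and axis percentages sum to 100", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  X <- matrix(rnorm(40 * 3), 40, 3)
  fit <- rda_fit(Y, X)
  expect_equal(fit$constrained_var + fit$residual_var, fit$total_var,
               tolerance = 1e-10)
  expect_equal(sum(fit$pct_constrained), 100, tolerance = 1e-10)
  expect_equal(sum(fit$eig), fit$constrained_var, tolerance = 1e-12)
})

test_that("rank-deficient predictors are dropped with a warning", {
  set.seed(4)
  X <- matrix(rnorm(30), 30, 1)
  X2 <- cbind(X, 2 * X)
  Y <- matrix(rnorm(60), 30, 2)
  expect_warning(fit <- rda_fit(Y, X2), "rank-deficient")
  expect_equal(fit$rank, 1L)
})

test_that("the Ezekiel adjustment matches hand-computed values", {
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(0.5, 11, 1), 0.44444444, tolerance = 1e-6)
  expect_equal(adjusted_r2(1, 25, 4), 1)
  expect_equal(adjusted_r2(0, 10, 3), -0.5)
  expect_error(adjusted_r2(0.5, 5, 4), class = "tb_config_error")
})

test_that("partial RDA reduces to plain RDA without conditioning", {
  set.seed(5)
  Y <- matrix(rnorm(25 * 3), 25, 3)
  X <- matrix(rnorm(25 * 2), 25, 2)
  p <- partial_rda(Y, X, NULL)
  f <- rda_fit(Y, X)
  expect_equal(p$r2, f$r2)
  expect_equal(p$eig, f$eig)
})

test_that("conditioning away the predictors leaves a zero unique fraction", {
  set.seed(6)
  Z <- matrix(rnorm(30 * 2), 30, 2)
  X <- Z %*% matrix(c(1, 2, -1, 0.5), 2, 2)  # X inside span(Z)
  Y <- matrix(rnorm(30 * 3), 30, 3)
  expect_warning(p <- partial_rda(Y, X, Z))
  expect_equal(p$r2, 0, tolerance = 1e-10)
})

test_that("semipartial fractions satisfy r2(X|Z) = r2([X Z]) - r2(Z)", {
  for (seed in 1:8) {
    set.seed(seed)
    Y <- matrix(rnorm(35 * 4), 35, 4)
    X <- matrix(rnorm(35 * 2), 35, 2)
    Z <- matrix(rnorm(35 * 3), 35, 3)
    lhs <- partial_rda(Y, X, Z)$r2
    rhs <- rda_fit(Y, cbind(X, Z))$r2 - rda_fit(Y, Z)$r2
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("R2, adjusted R2 and pseudo-F are invariant to rotating the response", {
  set.seed(7)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  X <- matrix(rnorm(30 * 2), 30, 2)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))  # orthonormal rotation
  f1 <- rda_fit(Y, X)
  f2 <- rda_fit(Y %*% Q, X)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  expect_equal(f2$adj_r2, f1$adj_r2, tolerance = 1e-12)
  expect_equal(f2$pseudo_f, f1$pseudo_f, tolerance = 1e-12)
  p1 <- permutation_test_rda(Y, X, n_perm = 49, seed = 8)
  p2 <- permutation_test_rda(Y %*% Q, X, n_perm = 49, seed = 8)
  expect_equal(p2$p_value, p1$p_value)
})

test_that("variation partitioning is additive and handles degenerate blocks", {
  set.seed(9)
  Y <- matrix(rnorm(40 * 5), 40, 5)
  A <- matrix(rnorm(40 * 2), 40, 2)
  B <- matrix(rnorm(40 * 2), 40, 2)
  vp <- variation_partition(Y, A, B, n_perm = 0)
  expect_equal(vp$unique_time + vp$unique_env + vp$shared, vp$full,
               tolerance = 1e-12)
  expect_equal(vp$residual, 1 - vp$full, tolerance = 1e-12)
  # identical blocks: unique fractions vanish, shared carries the model
  suppressWarnings(vp2 <- variation_partition(Y, A, A, n_perm = 0))
  expect_equal(vp2$unique_time, 0, tolerance = 1e-10)
  expect_equal(vp2$unique_env, 0, tolerance = 1e-10)
  expect_equal(vp2$shared, vp2$full, tolerance = 1e-10)
  # orthogonalized blocks: shared ~ 0
  B_orth <- qr.resid(qr(cbind(1, A)), B)
  vp3 <- variation_partition(Y, A, B_orth, n_perm = 0)
  expect_lt(abs(vp3$shared), 0.02)
})

test_that("results agree with vegan as an independent reference", {
  skip_if_not_installed("vegan")
  set.seed(10)
  n <- 48
  Y <- matrix(rnorm(n * 5), n, 5)
  Xt <- stats::model.matrix(~ factor(rep(1:6, n / 6)))[, -1]
  Xe <- matrix(rnorm(n * 3), n, 3)
  mine <- rda_fit(Y, cbind(Xt, Xe))
  ref <- vegan::rda(Y ~ ., data = as.data.frame(cbind(Xt, Xe)))
  expect_equal(mine$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-10)
  expect_equal(mine$adj_r2, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-10)
  expect_equal(mine$eig, unname(ref$CCA$eig[seq_along(mine$eig)]),
               tolerance = 1e-8)
  pf <- permutation_test_rda(Y, Xt, Z = Xe, n_perm = 99, seed = 1)
  av <- stats::anova(vegan::rda(Y, Xt, Xe), permutations = 99)
  expect_equal(pf$pseudo_f, av$F[1], tolerance = 1e-8)
  vp <- variation_partition(Y, Xt, Xe, n_perm = 0)
  ref_vp <- vegan::varpart(Y, Xt, Xe)$part$indfract$Adj.R.square
  expect_equal(c(vp$unique_time, vp$unique_env, vp$shared, vp$residual),
               ref_vp, tolerance = 1e-10)
})

test_that("exact permutation p matches full enumeration on 5 rows", {
  set.seed(11)
  Y <- matrix(rnorm(10), 5, 2)
  X <- matrix(rnorm(5), 5, 1)
  got <- permutation_test_rda(Y, X, exact = TRUE)
  # independent enumeration of all 120 row orders
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  fstat <- function(Yp) {
    fit <- qr.fitted(qr(Xc), Yp)
    ssf <- sum(fit^2); sst <- sum(Yp^2)
    (ssf / 1) / ((sst - ssf) / (5 - 2))
  }
  perms <- oracle_label_arrangements(1:5)
  stats <- vapply(perms, function(p) fstat(Yc[p, ]), 0)
  expect_equal(got$n_perm, 120)
  expect_equal(got$p_value, mean(stats >= fstat(Yc) - 1e-12))
})

test_that("a noiseless linear response attains the minimal Monte Carlo p", {
  set.seed(12)
  X <- matrix(rnorm(20), 20, 1)
  Y <- cbind(2 * X, -X)
  p <- permutation_test_rda(Y, X, n_perm = 199, seed = 13)$p_value
  expect_equal(p, 1 / 200)
})

test_that("predictor blocks align with the community's releves", {
  st <- generate_study(small_config(51))
  tm <- build_trait_matrix(st)
  bl <- predictor_blocks(tm, st, "flat")
  expect_equal(nrow(bl$Y), 6 * 4)  # 6 plots x (6 - 2 skipped) times
  expect_equal(ncol(bl$time), 3)   # 4 levels -> 3 dummies
  expect_equal(colnames(bl$env),
               c("soil_temperature", "soil_relative_humidity",
                 "canopy_height"))
  expect_false(anyNA(bl$env))
})
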