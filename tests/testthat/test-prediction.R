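# linear predictor and BLUP

test_that("plmm fit obeys its path and bookkeeping invariants", {
  td <- toy_design(n = 35, p = 30, seed = 31, eta_true = 0.5, n_causal = 3)
  d <- td$design
  fit <- plmm(d)
  # lambda_max sparsity: only the intercept is nonzero (q = 0 here)
  expect_equal(sum(fit$beta_original[, 1] != 0), 1L)
  expect_equal(rownames(fit$beta_original)[1], "(Intercept)")
  # stored original-scale linear predictors match raw-data predictions
  Xraw <- plmmfit:::raw_rows(d, seq_len(d$n))
  lp <- matrix(fit$beta_original[1, ], d$n, length(fit$lambda),
               byrow = TRUE) + Xraw %*% as.matrix(fit$beta_original[-1, ])
  expect_equal(unname(lp), unname(fit$linear_predictors), tolerance = 1e-8)
  # beta_original reproduces the rotated-scale fit: standardize, rotate,
  # predict equals the rotated linear predictor
  pc <- build_preconditioner(fit$eig, fit$eta)
  rot <- rotate_data(pc, cbind(1, d$X_std), d$y)
  lp_rot <- rot$X_tilde %*% as.matrix(fit$beta_std)
  Fm <- pc$w * t(pc$U)
  expect_equal(unname(as.matrix(lp_rot)),
               unname(Fm %*% fit$linear_predictors), tolerance = 1e-8)
})

test_that("linear prediction: null model, bookkeeping, row equivariance", {
  td <- toy_design(n = 30, p = 20, seed = 37, eta_true = 0.4)
  d <- td$design
  fit <- plmm(d)
  Xraw <- plmmfit:::raw_rows(d, seq_len(d$n))
  # beta = 0 at the path head: prediction is the constant intercept
  p1 <- predict(fit, Xraw[1:5, ], type = "linear", idx = 1)
  expect_equal(p1, rep(fit$beta_original[1, 1], 5), ignore_attr = TRUE)
  # one training row reproduces its stored linear predictor
  p40 <- predict(fit, Xraw[3, , drop = FALSE], type = "linear", idx = 40)
  expect_equal(as.numeric(p40), fit$linear_predictors[3, 40],
               tolerance = 1e-8)
  # permuting rows permutes predictions
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(predict(fit, Xraw[perm, ], type = "linear", idx = 40),
               predict(fit, Xraw[1:5, ], type = "linear", idx = 40)[perm])
  # feature mismatch errors with the missing names
  expect_error(predict(fit, Xraw[, -3], type = "linear"),
               "missing model features", class = "plmmfit_usage_error")
})

test_that("predictions are invariant to feature order in newdata", {
  td <- toy_design(n = 25, p = 15, seed = 41, eta_true = 0.5)
  fit <- plmm(td$design)
  Xraw <- plmmfit:::raw_rows(td$design, 1:8)
  shuf <- Xraw[, sample(ncol(Xraw))]
  expect_equal(predict(fit, shuf, type = "blup", idx = 30),
               predict(fit, Xraw, type = "blup", idx = 30))
})

test_that("BLUP identities: eta 0 reduction and training-sample recovery", {
  td <- toy_design(n = 30, p = 25, seed = 43, eta_true = 0.6)
  d <- td$design
  Xraw <- plmmfit:::raw_rows(d, seq_len(d$n))
  # eta = 0: the adjustment vanishes for new samples
  fit0 <- plmm(d, eta = 0)
  expect_identical(predict(fit0, Xraw[1:6, ], type = "blup"),
                   predict(fit0, Xraw[1:6, ], type = "linear"))
  # X2 = X1 as the same observational units: BLUP returns y1 at every lambda
  fit <- plmm(d)
  pb <- predict(fit, Xraw, type = "blup", same_samples = TRUE)
  expect_equal(unname(pb), matrix(d$y, d$n, length(fit$lambda)),
               tolerance = 1e-10)
  expect_error(predict(fit, Xraw[1:3, ], type = "blup", same_samples = TRUE),
               class = "plmmfit_usage_error")
})

test_that("BLUP matches the dense partitioned-covariance oracle", {
  set.seed(414)
  spec <- sim_spec(n_samples = 60, n_features = 200, n_causal = 3,
                   eta_true = 0.5, n_families = 15, seed = 47)
  sim <- simulate_dataset(spec)
  d_all <- create_design(sim$genotypes, sim$outcome_table)
  train <- 1:50; test <- 51:60
  d1 <- plmmfit:::restandardize_rows(d_all, train)
  fit <- plmm(d1)
  X2raw <- plmmfit:::raw_rows(d_all, test, match(d1$col_names,
                                                 d_all$col_names))
  idx <- c(1, 25, 50)
  pb <- predict(fit, X2raw, type = "blup", idx = idx)
  X2s <- plmmfit:::standardize_newdata(fit, X2raw)
  X1s <- d1$X_std
  for (k in seq_along(idx)) {
    lp2 <- predict(fit, X2raw, type = "linear", idx = idx[k])
    oracle <- blup_oracle(X1s, X2s, d1$y, fit$linear_predictors[, idx[k]],
                          lp2, fit$eta)
    expect_equal(as.numeric(pb[, k]), oracle, tolerance = 1e-8)
  }
  # eigen-route inverse equals the direct dense inverse
  K <- compute_grm(d1)
  S11 <- fit$eta * K + (1 - fit$eta) * diag(d1$n)
  v <- rnorm(d1$n)
  dinv <- 1 / (fit$eta * fit$eig$S + 1 - fit$eta)
  expect_equal(as.numeric(fit$eig$U %*% (dinv * crossprod(fit$eig$U, v))),
               as.numeric(solve(S11, v)), tolerance = 1e-8)
})

test_that("BLUP improves in-sample fit under strong structure", {
  # data from the structured model with eta >= 0.5: the correlation
  # adjustment should not hurt R^2 for related held-in samples
  set.seed(415)
  gains <- numeric(10)
  for (r in 1:10) {
    spec <- sim_spec(n_samples = 60, n_features = 150, n_causal = 2,
                     eta_true = 0.7, n_families = 15, seed = 700 + r)
    sim <- simulate_dataset(spec)
    d_all <- create_design(sim$genotypes, sim$outcome_table)
    train <- 1:48; test <- 49:60   # whole families span the split
    d1 <- plmmfit:::restandardize_rows(d_all, train)
    fit <- plmm(d1)
    X2 <- plmmfit:::raw_rows(d_all, test, match(d1$col_names,
                                                d_all$col_names))
    l <- 20
    mse_b <- mean((d_all$y[test] - predict(fit, X2, "blup", idx = l))^2)
    mse_l <- mean((d_all$y[test] - predict(fit, X2, "linear", idx = l))^2)
    gains[r] <- mse_l - mse_b
  }
  expect_gt(mean(gains), 0)
})
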