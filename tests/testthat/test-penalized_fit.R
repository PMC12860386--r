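# thresholding rules, lambda path, coordinate-descent solver, formatting

test_that("soft threshold and one-dimensional updates match hand arithmetic", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)

  # MCP firm rule at v = 1, alpha = 1: S(1, 0.5)/(1 - 1/3) = 0.75
  expect_equal(scalar_update(1, 0.5, "MCP", gamma = 3), 0.75)
  # identity (unbiased) branch: |z| = 2 > gamma*lambda = 1.5
  expect_equal(scalar_update(2, 0.5, "MCP", gamma = 3), 2)
  # lambda = 0: no shrinkage for every family
  for (pen in c("lasso", "MCP", "SCAD")) {
    expect_equal(scalar_update(1.3, 0, pen), 1.3)
  }
  # SCAD pieces at v = 1: inner soft threshold, middle firm, outer identity
  expect_equal(scalar_update(1.2, 1, "SCAD", gamma = 3.7), 0.2)
  z_mid <- 2.5    # lambda(v+1) = 2 < |z| <= gamma*lambda = 3.7
  expect_equal(scalar_update(z_mid, 1, "SCAD", gamma = 3.7),
               soft_threshold(z_mid, 3.7 / 2.7) / (1 - 1 / 2.7))
  expect_equal(scalar_update(5, 1, "SCAD", gamma = 3.7), 5)
  # elastic-net lasso: S(z, alpha*lambda)/(1 + lambda*(1-alpha))
  expect_equal(scalar_update(2, 1, "lasso", alpha = 0.5),
               soft_threshold(2, 0.5) / 1.5)
  expect_error(scalar_update(1, 1, "MCP", gamma = 1),
               class = "plmmfit_usage_error")
  expect_error(scalar_update(1, 1, "SCAD", gamma = 2),
               class = "plmmfit_usage_error")
})

test_that("lambda path is log-spaced and pins all-zero at lambda_max", {
  set.seed(406)
  n <- 30; p <- 12
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  pf <- c(0, rep(1, p))
  lam <- lambda_path(X, y, pf, n_lambda = 100, lambda_min_ratio = 0.01)
  expect_length(lam, 100L)
  ratios <- lam[-1] / lam[-100]
  expect_equal(ratios, rep(ratios[1], 99), tolerance = 1e-10)
  expect_equal(lam[100], lam[1] * 0.01, tolerance = 1e-10)
  # hand check of lambda_max from the KKT bound
  r0 <- stats::lm.fit(X[, 1, drop = FALSE], y)$residuals
  expect_equal(lam[1], max(abs(crossprod(X[, -1], r0)) / n))

  fit <- fit_path(X, y, lambda = lam, penalty_factor = pf)
  expect_true(all(fit$beta[-1, 1] == 0))            # all penalized zero
  expect_true(any(fit$beta[-1, 2] != 0))            # a hair below: active
  fit_eps <- fit_path(X, y, lambda = lam[1] * (1 - 1e-6), penalty_factor = pf)
  expect_true(any(fit_eps$beta[-1, 1] != 0))
  expect_error(lambda_path(X, y, rep(0, p + 1)), class = "plmmfit_usage_error")
})

test_that("orthonormal-design lasso matches its closed form", {
  set.seed(407)
  n <- 32; p <- 4
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))[, 1:p] * sqrt(n)  # (1/n)X'X = I
  y <- rnorm(n)
  lam <- 0.08
  fit <- fit_path(Q, y, lambda = lam, tol = 1e-10)
  closed <- soft_threshold(as.numeric(crossprod(Q, y)) / n, lam)
  expect_equal(as.numeric(fit$beta), closed, tolerance = 1e-8)
})

test_that("solver matches the proximal-gradient oracle and certifies KKT", {
  set.seed(408)
  for (alpha in c(1, 0.6)) {
    n <- 25; p <- 10
    X <- matrix(rnorm(n * p), n, p) %*% diag(runif(p, 0.5, 2))
    y <- X[, 1] * 0.8 + rnorm(n)
    lam <- lambda_path(X, y, alpha = alpha, n_lambda = 8,
                       lambda_min_ratio = 0.05)
    fit <- fit_path(X, y, lambda = lam, alpha = alpha, tol = 1e-9)
    kk <- check_kkt(X, y, fit$beta, lam, alpha = alpha)
    expect_true(all(kk$ok))
    for (l in c(3, 8)) {
      b_o <- prox_grad_lasso(X, y, lam[l], alpha = alpha)
      expect_lt(abs(en_objective(X, y, fit$beta[, l], lam[l], alpha,
                                 rep(1, p)) -
                    en_objective(X, y, b_o, lam[l], alpha, rep(1, p))), 1e-7)
    }
  }
})

test_that("penalized objective is non-increasing across sweeps", {
  set.seed(409)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  for (pen in c("lasso", "MCP", "SCAD")) {
    fit <- fit_path(X, y, penalty = pen, n_lambda = 12,
                    track_objective = TRUE)
    for (tr in fit$objective) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
    }
  }
})

test_that("MCP converges to the lasso as gamma grows", {
  set.seed(410)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 2] - 0.5 * X[, 5] + rnorm(n)
  lam <- lambda_path(X, y, n_lambda = 10)
  f_lasso <- fit_path(X, y, "lasso", lambda = lam, tol = 1e-9)
  f_mcp <- fit_path(X, y, "MCP", gamma = 1e6, lambda = lam, tol = 1e-9)
  expect_lt(max(abs(f_lasso$beta - f_mcp$beta)), 1e-4)
})

test_that("unpenalized columns are always active and solved exactly", {
  set.seed(411)
  n <- 30; p <- 6
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  y <- 2 + rnorm(n)
  pf <- c(0, rep(1, p))
  fit <- fit_path(X, y, lambda = 100, penalty_factor = pf)  # huge lambda
  expect_true(all(fit$beta[-1] == 0))
  expect_equal(fit$beta[1], mean(y), tolerance = 1e-8)
})

test_that("coefficients back-transform exactly to the raw scale", {
  # hand case: single feature, center 1, scale 2, beta_std = 1
  b <- format_coefficients(matrix(c(0.3, 1), 2, 1), centers = 1, scales = 2)
  expect_equal(as.numeric(b), c(0.3 - 0.5, 0.5))

  # null model: intercept passes through
  b0 <- format_coefficients(matrix(c(1.7, 0, 0), 3, 1), c(3, -2), c(1.5, 4))
  expect_equal(as.numeric(b0), c(1.7, 0, 0))

  # prediction equivalence on random data
  set.seed(412)
  n <- 20; p <- 5
  raw <- matrix(rnorm(n * p, 5, 3), n, p)
  centers <- colMeans(raw)
  scales <- sqrt(colMeans(sweep(raw, 2, centers)^2))
  Xs <- sweep(sweep(raw, 2, centers), 2, scales, "/")
  beta_std <- rbind(0.7, matrix(rnorm(p * 3), p, 3))
  beta_orig <- format_coefficients(beta_std, centers, scales)
  pred_std <- beta_std[1, ] + Xs %*% beta_std[-1, ]
  pred_raw <- matrix(beta_orig[1, ], n, 3, byrow = TRUE) +
    raw %*% beta_orig[-1, ]
  expect_equal(pred_raw, pred_std, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(format_coefficients(beta_std, centers, rep(0, p)),
               class = "plmmfit_integrity_error")
})

test_that("KKT certification passes on many random lasso/elastic-net fits", {
  set.seed(413)
  for (r in 1:20) {
    n <- sample(20:50, 1); p <- sample(5:25, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + X %*% (rbinom(p, 1, 0.2) * rnorm(p))
    alpha <- sample(c(1, 0.7), 1)
    fit <- fit_path(X, y, alpha = alpha, n_lambda = 20, tol = 1e-8)
    kk <- check_kkt(X, y, fit$beta, fit$lambda, alpha = alpha)
    expect_true(all(kk$ok))
  }
})

test_that("lasso path agrees with an independent reference implementation", {
  # glmnet solves the same objective; compare at matched lambda with
  # standardization disabled on both sides
  set.seed(420)
  n <- 60; p <- 20
  X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))  # mean-sq 1
  y <- X %*% c(1, -0.8, rep(0, p - 2)) + rnorm(n)
  Xa <- cbind(1, X)
  pf <- c(0, rep(1, p))
  lam <- lambda_path(Xa, y, pf, n_lambda = 12, lambda_min_ratio = 0.05)
  ours <- fit_path(Xa, y, lambda = lam, penalty_factor = pf, tol = 1e-10)
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       thresh = 1e-14)
  ref <- rbind(gn$a0, as.matrix(gn$beta))
  expect_equal(unname(ours$beta), unname(ref), tolerance = 1e-4)
})
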