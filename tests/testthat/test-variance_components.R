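# eta estimation, preconditioner, rotation

test_that("rotated-profile likelihood matches a dense REML evaluation", {
  set.seed(401)
  td <- toy_design(n = 30, p = 60, seed = 17, eta_true = 0.5)
  d <- td$design
  eig <- grm_eigen(d)
  K <- compute_grm(d)
  X0 <- matrix(1, d$n, 1)
  for (eta in c(0.05, 0.3, 0.7, 0.95)) {
    fast <- plmmfit:::profile_loglik(eta, eig$S, crossprod(eig$U, d$y),
                                     crossprod(eig$U, X0))
    dense <- dense_reml_loglik(eta, K, d$y, X0)
    expect_equal(fast, dense, tolerance = 1e-8)
  }
  # and the maximizer agrees with a dense grid search within 0.02
  vc <- estimate_eta(eig, d$y)
  grid <- seq(0, 0.999, length.out = 200)
  dense_ll <- vapply(grid, dense_reml_loglik, numeric(1), K = K, y = d$y,
                     X0 = X0)
  expect_lt(abs(vc$eta - grid[which.max(dense_ll)]), 0.02)
})

test_that("eta estimates separate null from fully structured outcomes", {
  set.seed(402)
  eta0 <- eta1 <- numeric(20)
  for (r in 1:20) {
    td <- toy_design(n = 200, p = 60, seed = 500 + r, eta_true = 0)
    eig <- grm_eigen(td$design)
    # independent outcome: truth eta = 0
    y0 <- rnorm(200)
    eta0[r] <- estimate_eta(eig, y0)$eta
    # pure structure: y = u with u ~ N(0, K), K full rank here (p < n
    # makes K rank-deficient, so add the noise-free draw on its range)
    z <- rnorm(200)
    u <- eig$U %*% (sqrt(pmax(eig$S, 0)) * z)
    eta1[r] <- estimate_eta(eig, as.numeric(u))$eta
  }
  expect_lt(mean(eta0), 0.15)
  expect_gt(mean(eta1), 0.85)
})

test_that("eta estimate obeys its invariants and degenerate-input errors", {
  td <- toy_design(n = 40, p = 30, seed = 19, eta_true = 0.6)
  eig <- grm_eigen(td$design)
  vc <- estimate_eta(eig, td$design$y)
  expect_gte(vc$eta, 0); expect_lte(vc$eta, 1)
  expect_equal(vc$eta, vc$sigma2_s / (vc$sigma2_s + vc$sigma2_e),
               tolerance = 1e-10)
  # profile value at the optimum is >= both endpoints
  ll_opt <- plmmfit:::profile_loglik(vc$eta, eig$S,
                                     crossprod(eig$U, td$design$y),
                                     crossprod(eig$U, matrix(1, eig$n, 1)))
  expect_gte(ll_opt, vc$loglik_profile$loglik[1] - 1e-9)
  expect_gte(ll_opt, vc$loglik_profile$loglik[nrow(vc$loglik_profile)] - 1e-9)
  expect_error(estimate_eta(eig, rep(1, eig$n)),
               class = "plmmfit_integrity_error")
})

test_that("preconditioner whitens Sigma_unit across an eta grid", {
  set.seed(403)
  for (rep in 1:3) {
    td <- toy_design(n = 20 + 5 * rep, p = 35, seed = 600 + rep)
    K <- compute_grm(td$design)
    eig <- eigendecompose(K)
    for (eta in c(0, 0.1, 0.5, 0.9, 0.99)) {
      pc <- build_preconditioner(eig, eta)
      Fm <- pc$w * t(pc$U)
      Sig <- eta * K + (1 - eta) * diag(eig$n)
      expect_lt(max(abs(Fm %*% Sig %*% t(Fm) - diag(eig$n))), 1e-8)
      expect_true(all(is.finite(pc$w)) && all(pc$w > 0))
    }
  }
  # hand values: eta = 0 -> w = 1; eta = 1 with s = 2 -> w = 1/sqrt(2)
  eig_toy <- structure(list(U = diag(2), S = c(2, 1), n = 2L, p = NA),
                       class = "eigen_relatedness")
  expect_equal(build_preconditioner(eig_toy, 0)$w, c(1, 1))
  expect_equal(build_preconditioner(eig_toy, 1)$w[1], 1 / sqrt(2))
  # singularity guard: eta = 1 with a zero eigenvalue
  eig_sing <- structure(list(U = diag(2), S = c(2, 0), n = 2L, p = NA),
                        class = "eigen_relatedness")
  expect_error(build_preconditioner(eig_sing, 1),
               class = "plmmfit_numeric_error")
})

test_that("rotation decorrelates and is statistically a no-op at eta = 0", {
  set.seed(404)
  td <- toy_design(n = 25, p = 10, seed = 23)
  d <- td$design
  eig <- grm_eigen(d)
  pc0 <- build_preconditioner(eig, 0)
  X_aug <- cbind(1, d$X_std)
  rot <- rotate_data(pc0, X_aug, d$y)
  # orthogonal rotation: least-squares coefficients are unchanged
  b_rot <- qr.coef(qr(rot$X_tilde[, 1:6]), rot$y_tilde)
  b_raw <- qr.coef(qr(X_aug[, 1:6]), d$y)
  expect_equal(b_rot, b_raw, tolerance = 1e-8, ignore_attr = TRUE)
  # rotated intercept column is generally not constant
  pc5 <- build_preconditioner(eig, 0.5)
  rot5 <- rotate_data(pc5, X_aug, d$y)
  expect_gt(stats::sd(rot5$X_tilde[, 1]), 1e-6)
  expect_error(rotate_data(pc5, X_aug[1:3, ], d$y),
               class = "plmmfit_usage_error")
})

test_that("rotated outcomes have identity covariance under the true model", {
  # empirical whitening check: y ~ N(0, Sigma_unit), y_tilde = F y
  set.seed(405)
  n <- 10
  td <- toy_design(n = n, p = 30, seed = 29)
  K <- compute_grm(td$design)
  eig <- eigendecompose(K)
  eta <- 0.6
  pc <- build_preconditioner(eig, eta)
  Sig <- eta * K + (1 - eta) * diag(n)
  ch <- chol(Sig)
  Y <- matrix(rnorm(2000 * n), 2000, n) %*% ch      # rows ~ N(0, Sigma)
  Yt <- t(apply(Y, 1, function(y) as.numeric(pc$w * crossprod(pc$U, y))))
  emp <- crossprod(Yt) / 2000
  expect_lt(max(abs(emp - diag(n))), 0.25)
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.1)
})
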