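# Shared fixtures and independent oracles. Oracles are deliberately written
# with different algorithms from the implementation they check (proximal
# gradient vs coordinate descent; dense solve vs eigen-route inverse).

# small genotype fixture covering all four 2-bit PLINK codes and byte padding
toy_genotypes <- function(n = 7, p = 5, seed = 11, missing_rate = 0.15) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    dos <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    dos[runif(n * p) < missing_rate] <- NA
    dos[1, 1] <- 0; dos[2, 1] <- 1; dos[3, 1] <- 2; dos[4, 1] <- NA
    ids <- sprintf("ind%02d", seq_len(n))
    genotype_matrix(dos, ids, sprintf("var%02d", seq_len(p)))
  })
}

toy_design <- function(n = 40, p = 25, seed = 3, eta_true = 0.5,
                       n_causal = 2, missing_rate = 0, n_families = n,
                       n_populations = 1, divergence = 0) {
  spec <- sim_spec(n_samples = n, n_features = p, n_causal = n_causal,
                   eta_true = eta_true, missing_rate = missing_rate,
                   n_families = n_families, n_populations = n_populations,
                   fst_like_divergence = divergence, seed = seed)
  sim <- simulate_dataset(spec)
  list(design = create_design(sim$genotypes, sim$outcome_table),
       sim = sim, spec = spec)
}

# penalized objective for lasso / elastic net with penalty factors
en_objective <- function(X, y, b, lambda, alpha, pf) {
  r <- y - X %*% b
  sum(r^2) / (2 * nrow(X)) +
    lambda * sum(pf * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
}

# independent solver: proximal gradient (ISTA with backtracking-free fixed
# step from the exact Lipschitz constant), run to tight tolerance
prox_grad_lasso <- function(X, y, lambda, alpha = 1, pf = rep(1, ncol(X)),
                            max_iter = 50000, tol = 1e-12) {
  n <- nrow(X)
  G <- crossprod(X) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha) * max(pf)
  step <- 1 / L
  b <- rep(0, ncol(X))
  obj_old <- en_objective(X, y, b, lambda, alpha, pf)
  for (it in seq_len(max_iter)) {
    r <- y - X %*% b
    grad <- -crossprod(X, r) / n + lambda * (1 - alpha) * pf * b
    z <- b - step * as.numeric(grad)
    b <- sign(z) * pmax(abs(z) - step * lambda * alpha * pf, 0)
    if (it %% 50 == 0) {
      obj <- en_objective(X, y, b, lambda, alpha, pf)
      if (obj_old - obj < tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  b
}

# dense-algebra BLUP oracle: the partitioned-covariance formula evaluated
# with explicit matrices and solve(), no eigendecomposition shortcuts
blup_oracle <- function(X1_std_pen, X2_std_pen, y1, lp1, lp2, eta) {
  p <- ncol(X1_std_pen)
  K11 <- tcrossprod(X1_std_pen) / p
  K21 <- tcrossprod(X2_std_pen, X1_std_pen) / p
  S11 <- eta * K11 + (1 - eta) * diag(nrow(X1_std_pen))
  as.numeric(lp2 + eta * K21 %*% solve(S11, y1 - lp1))
}

# dense GLS log-likelihood (REML), no rotation: direct -1/2 log|Sigma| form
dense_reml_loglik <- function(eta, K, y, X0) {
  n <- length(y)
  q0 <- ncol(X0)
  Sigma <- eta * K + (1 - eta) * diag(n)
  Si <- solve(Sigma)
  XtSiX <- crossprod(X0, Si %*% X0)
  b <- solve(XtSiX, crossprod(X0, Si %*% y))
  r <- y - X0 %*% b
  rss <- as.numeric(crossprod(r, Si %*% r))
  sigma2 <- rss / (n - q0)
  -0.5 * ((n - q0) * log(sigma2) +
          as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
          as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus) +
          (n - q0))
}

expect_design_standardized <- function(d) {
  X <- if (d$storage_mode == "in_memory") d$X_std else
    plmmfit:::design_matrix(d)
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_lt(max(abs(colMeans(X^2) - 1)), 1e-10)
}
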