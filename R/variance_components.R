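# Null-model restricted (REML) profile log-likelihood on the U'-rotated
# scale. For a given eta, Sigma_unit = eta*K + (1-eta)*I has eigenvalues
# d_i = eta*s_i + 1 - eta in the eigenbasis U, so after rotating y and the
# unpenalized block by U' the model is heteroskedastic-independent and each
# likelihood evaluation is O(n q^2): a weighted least-squares fit with
# weights 1/d, with the total variance profiled out in closed form.
# REML rather than plain ML: because the design columns are centered, the
# all-ones vector is a zero-eigenvector of K and the intercept fits that
# rotated coordinate exactly, so the ML profile diverges to eta = 1
# (0 residual against a -log d reward). The REML term
# log|X0' Sigma^{-1} X0| cancels that divergence exactly.
profile_loglik <- function(eta, S, y_rot, X_rot) {
  n <- length(y_rot)
  q0 <- ncol(X_rot)
  d <- eta * S + 1 - eta
  sw <- sqrt(1 / d)
  Xw <- X_rot * sw
  yw <- y_rot * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)          # = r' Sigma_unit^{-1} r
  sigma2 <- rss / (n - q0)
  xtx <- crossprod(Xw)
  ldet_x <- determinant(xtx, logarithm = TRUE)$modulus
  -0.5 * ((n - q0) * log(sigma2) + sum(log(d)) + as.numeric(ldet_x) +
          (n - q0))
}

#' Estimate the structure proportion of variance (eta)
#'
#' Estimates eta = sigma2_s / (sigma2_s + sigma2_e), the proportion of
#' outcome variance attributable to the latent structure captured by K,
#' by maximizing the restricted (REML) profile Gaussian log-likelihood of
#' the *null* model (intercept plus unpenalized covariates only) under
#' y ~ N(X0 b, sigma2_total * (eta*K + (1-eta)*I)).
#' After rotation by U' each evaluation is closed-form; eta is located by a
#' 100-point grid scan over 0 to 0.999 followed by golden-section
#' refinement. REML is used instead of plain ML because centered design
#' columns make the all-ones vector a zero-eigenvector of K, which the
#' intercept fits exactly; the ML profile then diverges to eta = 1, while
#' the REML correction removes the degeneracy.
#'
#' @param eig an [eigendecompose()] result for the training K.
#' @param y numeric outcome vector.
#' @param X_unpen optional n x q matrix of unpenalized covariates (an
#'   intercept is always added internally).
#' @param eta_cap upper bound for eta (keeps the preconditioner finite when
#'   K is singular).
#' @param grid_n number of grid points in the initial scan.
#' @return an object of class `variance_components` with `eta`, `sigma2_s`,
#'   `sigma2_e`, and `loglik_profile` (data.frame of eta vs profile
#'   log-likelihood).
#' @export
estimate_eta <- function(eig, y, X_unpen = NULL, eta_cap = 0.999,
                         grid_n = 100L) {
  n <- eig$n
  if (length(y) != n) err_usage("length(y) does not match eigendecomposition")
  if (stats::sd(y) < 1e-12) err_integrity("outcome is constant; eta is undefined")
  X0 <- cbind(intercept = rep(1, n), X_unpen)
  y_rot <- crossprod(eig$U, y)
  X_rot <- crossprod(eig$U, X0)

  grid <- seq(0, eta_cap, length.out = grid_n)
  ll <- vapply(grid, profile_loglik, numeric(1), S = eig$S,
               y_rot = y_rot, X_rot = X_rot)
  i_best <- which.max(ll)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(grid_n, i_best + 1L)]
  opt <- stats::optimize(profile_loglik, c(lo, hi), S = eig$S,
                         y_rot = y_rot, X_rot = X_rot, maximum = TRUE,
                         tol = 1e-6)
  eta <- opt$maximum
  # keep the grid optimum if refinement did not improve on it
  if (opt$objective < ll[i_best]) eta <- grid[i_best]

  d <- eta * eig$S + 1 - eta
  w <- sqrt(1 / d)
  fit <- stats::lm.fit(X_rot * w, as.numeric(y_rot) * w)
  sigma2_total <- sum(fit$residuals^2) / (n - ncol(X0))
  structure(list(
    eta = eta,
    sigma2_s = eta * sigma2_total,
    sigma2_e = (1 - eta) * sigma2_total,
    sigma2_total = sigma2_total,
    loglik_profile = data.frame(eta = grid, loglik = ll)
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: eta = %.4f (sigma2_s = %.4g, sigma2_e = %.4g)\n",
    x$eta, x$sigma2_s, x$sigma2_e))
  invisible(x)
}

#' Build the whitening preconditioner F = Sigma^(-1/2)
#'
#' With Sigma_unit = eta*K + (1-eta)*I = U diag(eta*s + 1 - eta) U', the
#' preconditioner is F = diag(w) U' with rotation weights
#' w_i = (eta*s_i + 1 - eta)^(-1/2), so that F Sigma_unit F' = I.
#'
#' @param eig an [eigendecompose()] result.
#' @param eta fraction in the closed interval 0 to 1.
#' @return an object of class `plmm_preconditioner` with `U`, `w`, `eta`.
#' @export
build_preconditioner <- function(eig, eta) {
  if (eta < 0 || eta > 1) err_usage("eta must be in [0, 1]")
  d <- eta * eig$S + 1 - eta
  if (any(d <= 1e-12)) {
    err_numeric(paste(
      "eta*s + 1 - eta is numerically zero for some eigenvalue;",
      "cap eta below 1 (e.g. 0.999) when K is singular"))
  }
  structure(list(U = eig$U, w = 1 / sqrt(d), eta = eta),
            class = "plmm_preconditioner")
}

#' Rotate (precondition) the data
#'
#' Applies F = diag(w) U' to the augmented design and the outcome:
#' X_tilde = F X_aug, y_tilde = F y. On the rotated scale the errors of the
#' mixed model are independent with unit variance, so ordinary penalized
#' regression applies. Rows lose their sample identity; columns keep their
#' feature identity, so coefficients retain their meaning. `X_aug` must
#' carry an explicit leading all-ones intercept column: F 1 is generally not
#' constant, so the intercept has to be rotated like any other column.
#'
#' @param pc a [build_preconditioner()] object.
#' @param X_aug n x (1+q+p) matrix whose first column is all ones.
#' @param y numeric outcome vector.
#' @return list with `X_tilde` and `y_tilde`.
#' @export
rotate_data <- function(pc, X_aug, y) {
  n <- nrow(pc$U)
  if (nrow(X_aug) != n || length(y) != n) {
    err_usage("X_aug / y dimensions do not match the preconditioner")
  }
  list(X_tilde = pc$w * crossprod(pc$U, X_aug),
       y_tilde = as.numeric(pc$w * crossprod(pc$U, y)))
}
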