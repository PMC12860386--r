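#' Fit a penalized linear mixed model
#'
#' The full pipeline on a model-ready design: (i) *prep* — compute the
#' relatedness matrix K = (1/p) X X' from the standardized penalized
#' features, eigendecompose it, estimate the structure proportion eta by
#' profile maximum likelihood under the null model, and build the whitening
#' preconditioner F = Sigma^(-1/2); (ii) *fit* — rotate the intercept-
#' augmented design and the outcome by F and run coordinate descent over a
#' descending lambda path; (iii) *format* — return coefficients on the scale
#' of the original data. For file-backed designs the rotated matrix is
#' written to a backing file in column chunks and the solver streams column
#' blocks, so the design is never fully in memory.
#'
#' @param design a [create_design()] object.
#' @param penalty `"lasso"` (default), `"MCP"`, or `"SCAD"`.
#' @param gamma concavity parameter (default 3 for MCP, 3.7 for SCAD).
#' @param alpha elastic-net mixing fraction in (0, 1]; 1 = pure lasso.
#' @param eta fix the structure proportion instead of estimating it
#'   (e.g. `eta = 0` reduces the fit to a plain penalized regression on the
#'   standardized, unrotated data).
#' @param eig a precomputed [eigendecompose()] result (skips the GRM work).
#' @param lambda user lambda sequence; computed by [lambda_path()] if NULL.
#' @param n_lambda,lambda_min_ratio path controls when `lambda` is NULL.
#' @param tol,max_iter coordinate-descent controls.
#' @param chunk_features columns per chunk in streaming passes.
#' @param eta_cap upper bound on eta (keeps F finite when K is singular).
#' @param cache_dir optional directory for the GRM eigendecomposition cache
#'   (see [grm_eigen()]); repeated fits on the same design skip the O(n^3)
#'   work.
#' @param track_objective record the penalized objective per sweep.
#' @return an object of class `plmm_fit` with, among others,
#'   `beta_original` (sparse (1+q+p) x L coefficient matrix on the raw
#'   scale), `beta_std` (standardized scale), `lambda`, `eta`, `vc`
#'   (variance components), `eig`, `linear_predictors` (n x L, original
#'   scale), `convergence`, and the design metadata needed for prediction.
#' @export
plmm <- function(design, penalty = "lasso", gamma = default_gamma(penalty),
                 alpha = 1, eta = NULL, eig = NULL, lambda = NULL,
                 n_lambda = 100L, lambda_min_ratio = NULL, tol = 1e-4,
                 max_iter = 10000L, chunk_features = 2048L, eta_cap = 0.999,
                 cache_dir = NULL, track_objective = FALSE) {
  d <- design
  if (!inherits(d, "plmm_design")) err_usage("design must be a plmm_design")
  n <- d$n; q <- d$q; p <- d$p
  if (p < 1L) err_usage("design has no penalized features")

  ## ---- prep step ----
  if (is.null(eig)) eig <- grm_eigen(d, chunk_features, cache_dir)
  vc <- NULL
  if (is.null(eta)) {
    X_unpen <- if (q > 0) design_cols(d, seq_len(q)) else NULL
    vc <- estimate_eta(eig, d$y, X_unpen, eta_cap = eta_cap)
    eta <- vc$eta
  }
  eta <- min(eta, eta_cap)
  pc <- build_preconditioner(eig, eta)

  ## ---- rotation (explicit intercept column first, then q + p columns) ----
  m_aug <- 1L + q + p
  pf_aug <- c(0, d$penalty_factor)
  Ut_w <- pc$w * t(pc$U)                      # F = diag(w) U'
  y_tilde <- as.numeric(Ut_w %*% d$y)

  if (d$storage_mode == "in_memory") {
    X_tilde <- Ut_w %*% cbind(1, d$X_std)
    get_cols <- function(j) X_tilde[, j, drop = FALSE]
  } else {
    rot_path <- tempfile(fileext = ".fbm")
    fbm_create(rot_path, n, m_aug)
    fbm_append_cols(rot_path, Ut_w %*% matrix(1, n, 1))
    for (j0 in chunk_starts(q + p, chunk_features)) {
      j1 <- min(j0 + chunk_features - 1L, q + p)
      fbm_append_cols(rot_path, Ut_w %*% design_cols(d, j0:j1))
    }
    get_cols <- function(j) fbm_read_cols(rot_path, n, j)
  }

  ## ---- fit step ----
  if (is.null(lambda)) {
    lambda <- lambda_path_engine(get_cols, n, m_aug, y_tilde, pf_aug,
                                 n_lambda, lambda_min_ratio, alpha,
                                 chunk = chunk_features)
  }
  fitres <- fit_path_engine(get_cols, n, m_aug, y_tilde, pf_aug, lambda,
                            penalty, gamma, alpha, tol, max_iter,
                            chunk = chunk_features,
                            track_objective = track_objective)
  beta_std <- fitres$beta
  rownames(beta_std) <- c("(Intercept)", d$col_names)

  ## ---- format step ----
  beta_original <- format_coefficients(beta_std, d$centers, d$scales)

  # linear predictors on the original scale: intercept_std + X_std beta_std
  lp <- matrix(rep(beta_std[1L, ], each = n), n)
  for (j0 in chunk_starts(q + p, chunk_features)) {
    j1 <- min(j0 + chunk_features - 1L, q + p)
    bs <- beta_std[1L + (j0:j1), , drop = FALSE]
    nz <- which(rowSums(bs != 0) > 0)
    if (length(nz)) {
      lp <- lp + design_cols(d, (j0:j1)[nz]) %*% bs[nz, , drop = FALSE]
    }
  }

  structure(list(
    beta_original = Matrix::Matrix(beta_original, sparse = TRUE),
    beta_std = Matrix::Matrix(beta_std, sparse = TRUE),
    lambda = lambda, eta = eta, vc = vc, eig = eig,
    penalty = penalty, gamma = gamma, alpha = alpha,
    linear_predictors = lp, y = d$y,
    convergence = data.frame(lambda = lambda, iterations = fitres$iters,
                             converged = fitres$converged),
    objective = fitres$objective,
    design = d, n = n, q = q, p = p,
    col_names = d$col_names, centers = d$centers, scales = d$scales
  ), class = "plmm_fit")
}

#' @export
print.plmm_fit <- function(x, ...) {
  nz <- Matrix::colSums(x$beta_original[-1L, , drop = FALSE] != 0)
  cat(sprintf(
    "plmm_fit: %s penalty, %d lambda values, eta = %.3f\n  nonzero coefficients: %d (lambda_max) to %d (lambda_min)\n",
    x$penalty, length(x$lambda), x$eta, nz[1L], nz[length(nz)]))
  invisible(x)
}

#' Summarize a fit at one point on the path
#'
#' @param object a [plmm()] fit.
#' @param idx index into the lambda sequence (default: last).
#' @param ... unused.
#' @return data.frame of nonzero coefficients at `lambda[idx]` on the
#'   original data scale.
#' @export
summary.plmm_fit <- function(object, idx = length(object$lambda), ...) {
  if (idx < 1L || idx > length(object$lambda)) err_usage("idx out of range")
  b <- object$beta_original[, idx]
  nz <- which(b != 0 | seq_along(b) == 1L)
  out <- data.frame(term = rownames(object$beta_original)[nz],
                    estimate = as.numeric(b[nz]))
  attr(out, "lambda") <- object$lambda[idx]
  attr(out, "eta") <- object$eta
  class(out) <- c("summary.plmm_fit", "data.frame")
  out
}

#' @export
print.summary.plmm_fit <- function(x, ...) {
  cat(sprintf("lambda = %.5g, eta = %.3f: %d nonzero term(s)\n",
              attr(x, "lambda"), attr(x, "eta"), nrow(x) - 1L))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot coefficient paths
#'
#' Coefficient profiles of the penalized features (original scale) against
#' log(lambda).
#'
#' @param x a [plmm()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.plmm_fit <- function(x, ...) {
  b <- as.matrix(x$beta_original)
  pen <- which(c(0, x$design$penalty_factor) > 0)
  graphics::matplot(log(x$lambda), t(b[pen, , drop = FALSE]), type = "l",
                    lty = 1, xlab = expression(log(lambda)),
                    ylab = "coefficient (original scale)", ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
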