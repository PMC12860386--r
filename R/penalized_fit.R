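#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the proximal operator of the absolute value;
#' the elementary update of lasso coordinate descent.
#'
#' @param z numeric.
#' @param t threshold, `t >= 0`.
#' @return numeric of the same length as `z`.
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) err_usage("threshold must be >= 0")
  sign(z) * pmax(abs(z) - t, 0)
}

penalty_code <- function(penalty) {
  switch(penalty, lasso = 0L, MCP = 1L, SCAD = 2L,
         err_usage(sprintf("unknown penalty '%s' (use lasso, MCP, or SCAD)",
                           penalty)))
}

default_gamma <- function(penalty) switch(penalty, MCP = 3, SCAD = 3.7, 0)

check_penalty_spec <- function(penalty, gamma, alpha) {
  if (alpha <= 0 || alpha > 1) err_usage("alpha must be in (0, 1]")
  if (penalty == "MCP" && gamma <= 1) err_usage("MCP requires gamma > 1")
  if (penalty == "SCAD" && gamma <= 2) err_usage("SCAD requires gamma > 2")
  invisible(TRUE)
}

#' One-dimensional penalized update
#'
#' The exact minimizer of the one-dimensional coordinate-descent
#' subproblem `v/2 b^2 - z b + P(b)` for the lasso, MCP, or SCAD penalty,
#' each with an optional elastic-net ridge component. With unit curvature
#' (`v = 1`), `alpha = 1` and penalty factor 1 these reduce to the familiar
#' soft/firm-thresholding rules: lasso `S(z, lambda)`; MCP
#' `S(z, lambda)/(1 - 1/gamma)` for `|z| <= gamma*lambda`, else `z`; SCAD the
#' analogous three-piece rule.
#'
#' @param z partial-residual inner product `(1/n) x_j' r + v * b_j`.
#' @param lambda regularization level (scaled by `penalty_factor`).
#' @param penalty `"lasso"`, `"MCP"`, or `"SCAD"`.
#' @param gamma concavity parameter (> 1 for MCP, > 2 for SCAD).
#' @param alpha elastic-net mixing fraction in (0, 1]; 1 = no ridge.
#' @param penalty_factor per-column multiplier of `lambda` (0 = unpenalized).
#' @param v column curvature `(1/n) x_j' x_j`.
#' @return scalar update.
#' @export
scalar_update <- function(z, lambda, penalty = "lasso",
                          gamma = default_gamma(penalty), alpha = 1,
                          penalty_factor = 1, v = 1) {
  if (lambda < 0) err_usage("lambda must be >= 0")
  check_penalty_spec(penalty, gamma, alpha)
  l1 <- alpha * lambda * penalty_factor
  l2 <- (1 - alpha) * lambda * penalty_factor
  den <- v + l2
  fam <- penalty_code(penalty)
  if (fam == 0L || l1 == 0) {
    if (l1 == 0 && l2 == 0) return(z / v)
    return(soft_threshold(z, l1) / den)
  }
  if (fam == 1L) {                      # MCP firm rule
    if (abs(z) <= gamma * l1 * den) {
      return(soft_threshold(z, l1) / (den - 1 / gamma))
    }
    return(z / den)
  }
  # SCAD three-piece rule
  if (abs(z) <= l1 * (den + 1)) return(soft_threshold(z, l1) / den)
  if (abs(z) <= gamma * l1 * den) {
    return(soft_threshold(z, gamma * l1 / (gamma - 1)) / (den - 1 / (gamma - 1)))
  }
  z / den
}

# Residual of y on the unpenalized block (penalty_factor == 0 columns,
# which includes the rotated intercept). Shared by lambda-path construction
# and the fitting engine so the two agree exactly at lambda_max.
null_fit <- function(X0, y) {
  if (is.null(X0) || ncol(X0) == 0L) {
    return(list(coef = numeric(0), residuals = y))
  }
  f <- stats::lm.fit(X0, y)
  list(coef = f$coefficients, residuals = f$residuals)
}

lambda_path_engine <- function(get_cols, n, m, y_tilde, penalty_factor,
                               n_lambda, lambda_min_ratio, alpha,
                               chunk = 2048L) {
  pen <- which(penalty_factor > 0)
  if (!length(pen)) err_usage("all columns are unpenalized; no lambda path")
  unpen <- which(penalty_factor == 0)
  r0 <- null_fit(if (length(unpen)) get_cols(unpen) else NULL, y_tilde)$residuals
  lam_max <- 0
  for (j0 in chunk_starts(length(pen), chunk)) {
    j1 <- min(j0 + chunk - 1L, length(pen))
    idx <- pen[j0:j1]
    z <- abs(crossprod(get_cols(idx), r0)) / n
    lam_max <- max(lam_max, max(z / (alpha * penalty_factor[idx])))
  }
  if (lam_max <= 0) lam_max <- 1e-3
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (n > length(pen)) 0.01 else 0.05
  }
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Regularization path of lambda values
#'
#' `lambda_max` is the smallest value at which every penalized coefficient
#' is zero: the maximum over penalized columns of
#' `|(1/n) x_j' r0| / (alpha * pf_j)`, where `r0` is the outcome
#' residualized on the unpenalized block (including the rotated intercept).
#' The path is log-spaced over `n_lambda` values down to
#' `lambda_max * lambda_min_ratio` (default ratio 0.01 when n exceeds the
#' number of penalized columns, else 0.05).
#'
#' @param X_tilde rotated design matrix.
#' @param y_tilde rotated outcome.
#' @param penalty_factor per-column multipliers (0 = unpenalized).
#' @param n_lambda path length.
#' @param lambda_min_ratio ratio of smallest to largest lambda.
#' @param alpha elastic-net mixing fraction.
#' @return descending numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X_tilde, y_tilde, penalty_factor = rep(1, ncol(X_tilde)),
                        n_lambda = 100L, lambda_min_ratio = NULL, alpha = 1) {
  lambda_path_engine(function(j) X_tilde[, j, drop = FALSE], nrow(X_tilde),
                     ncol(X_tilde), y_tilde, penalty_factor, n_lambda,
                     lambda_min_ratio, alpha)
}

# Core path fitter over a column accessor. Ever-active screening: solve by
# coordinate descent on the current candidate set, then scan all columns for
# KKT violations (|(1/n) x_j' r| > alpha*lambda*pf_j for zero coefficients)
# in chunks, add violators, and re-solve; warm starts across lambda. The
# same code path serves in-memory and file-backed data, so the two give
# identical results.
fit_path_engine <- function(get_cols, n, m, y_tilde, penalty_factor,
                            lambda, penalty = "lasso",
                            gamma = default_gamma(penalty), alpha = 1,
                            tol = 1e-4, max_iter = 10000L, chunk = 2048L,
                            track_objective = FALSE) {
  check_penalty_spec(penalty, gamma, alpha)
  fam <- penalty_code(penalty)
  L <- length(lambda)
  pf <- penalty_factor
  y_scale <- sqrt(mean(y_tilde^2))

  v <- numeric(m)
  for (j0 in chunk_starts(m, chunk)) {
    j1 <- min(j0 + chunk - 1L, m)
    blk <- get_cols(j0:j1)
    v[j0:j1] <- colSums(blk^2) / n
  }

  unpen <- which(pf == 0)
  beta <- numeric(m)
  if (length(unpen)) {
    X0 <- get_cols(unpen)
    nf <- null_fit(X0, y_tilde)
    beta[unpen] <- nf$coef
    r <- nf$residuals
    E <- unpen
    XE <- X0
  } else {
    r <- y_tilde
    E <- integer(0)
    XE <- matrix(numeric(0), n, 0)
  }

  B <- matrix(0, m, L)
  iters <- integer(L)
  converged <- logical(L)
  objective <- if (track_objective) vector("list", L) else NULL

  for (l in seq_len(L)) {
    lam <- lambda[l]
    repeat {
      if (ncol(XE)) {
        res <- cd_solve(XE, r, beta[E], v[E], pf[E], lam, alpha, gamma, fam,
                        tol, max_iter, y_scale, track_objective)
        beta[E] <- res$beta
        r <- res$r
        iters[l] <- iters[l] + res$iter
        converged[l] <- res$converged
        if (track_objective) {
          objective[[l]] <- c(objective[[l]], res$objective)
        }
      } else converged[l] <- TRUE
      # KKT scan over every column for violations among zero coefficients
      viol <- integer(0)
      for (j0 in chunk_starts(m, chunk)) {
        j1 <- min(j0 + chunk - 1L, m)
        idx <- j0:j1
        z <- as.numeric(crossprod(get_cols(idx), r)) / n
        cand <- idx[pf[idx] > 0 & beta[idx] == 0 &
                    abs(z) > alpha * lam * pf[idx] * (1 + 1e-9) + 1e-12]
        viol <- c(viol, setdiff(cand, E))
      }
      if (!length(viol)) break
      XE <- cbind(XE, get_cols(viol))
      E <- c(E, viol)
    }
    B[, l] <- beta
  }
  if (any(!converged)) {
    warning(sprintf("coordinate descent did not converge at %d lambda value(s)",
                    sum(!converged)))
  }
  list(beta = B, iters = iters, converged = converged, objective = objective,
       v = v)
}

#' Fit a penalized regression path by coordinate descent
#'
#' Minimizes `(1/2n) ||y - X b||^2 + P_lambda(b)` over a descending lambda
#' sequence with warm starts, for the lasso, MCP, or SCAD penalty with an
#' optional elastic-net ridge component. Columns need not be unit-scale
#' (rotation changes column scales): per-column curvatures
#' `v_j = (1/n) x_j' x_j` enter every update, so the stated objective is
#' solved exactly rather than a re-standardized surrogate.
#'
#' @param X design matrix (typically the rotated `X_tilde`).
#' @param y outcome (typically the rotated `y_tilde`).
#' @param penalty `"lasso"` (default), `"MCP"`, or `"SCAD"`.
#' @param lambda descending sequence; computed via [lambda_path()] if NULL.
#' @param gamma concavity parameter (default 3 for MCP, 3.7 for SCAD).
#' @param alpha elastic-net mixing fraction in (0, 1].
#' @param penalty_factor per-column lambda multipliers (0 = unpenalized).
#' @param n_lambda,lambda_min_ratio path controls when `lambda` is NULL.
#' @param tol relative convergence tolerance.
#' @param max_iter maximum coordinate-descent sweeps per lambda.
#' @param track_objective record the penalized objective after every sweep
#'   (debugging aid; the trace must be non-increasing).
#' @return list with `beta` (ncol(X) x L), `lambda`, `iters`, `converged`,
#'   `objective`, `v`.
#' @export
fit_path <- function(X, y, penalty = "lasso", lambda = NULL,
                     gamma = default_gamma(penalty), alpha = 1,
                     penalty_factor = rep(1, ncol(X)), n_lambda = 100L,
                     lambda_min_ratio = NULL, tol = 1e-4, max_iter = 10000L,
                     track_objective = FALSE) {
  get_cols <- function(j) X[, j, drop = FALSE]
  if (is.null(lambda)) {
    lambda <- lambda_path_engine(get_cols, nrow(X), ncol(X), y,
                                 penalty_factor, n_lambda, lambda_min_ratio,
                                 alpha)
  }
  res <- fit_path_engine(get_cols, nrow(X), ncol(X), y, penalty_factor,
                         lambda, penalty, gamma, alpha, tol, max_iter,
                         track_objective = track_objective)
  res$lambda <- lambda
  res
}

#' Check Karush-Kuhn-Tucker conditions of a lasso / elastic-net path
#'
#' For each lambda, verifies that zero penalized coefficients satisfy
#' `|(1/n) x_j' r| <= alpha*lambda*pf_j + tol` and active ones satisfy
#' `|(1/n) x_j' r - alpha*lambda*pf_j*sign(b_j) - lambda*(1-alpha)*pf_j*b_j|
#' <= tol`.
#'
#' @param X,y the (rotated) data the path was fit on.
#' @param beta coefficient matrix (ncol(X) x L).
#' @param lambda the lambda sequence.
#' @param alpha elastic-net mixing fraction used in the fit.
#' @param penalty_factor per-column multipliers used in the fit.
#' @param tol certification tolerance.
#' @return list with `ok` (logical per lambda) and `max_violation`.
#' @export
check_kkt <- function(X, y, beta, lambda, alpha = 1,
                      penalty_factor = rep(1, ncol(X)), tol = 1e-6) {
  n <- nrow(X)
  L <- length(lambda)
  maxv <- numeric(L)
  for (l in seq_len(L)) {
    r <- y - X %*% beta[, l]
    z <- as.numeric(crossprod(X, r)) / n
    viol <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      lpj <- lambda[l] * penalty_factor[j]
      if (penalty_factor[j] == 0) {
        viol[j] <- abs(z[j])
      } else if (beta[j, l] == 0) {
        viol[j] <- max(0, abs(z[j]) - alpha * lpj)
      } else {
        viol[j] <- abs(z[j] - alpha * lpj * sign(beta[j, l]) -
                       (1 - alpha) * lpj * beta[j, l])
      }
    }
    maxv[l] <- max(viol)
  }
  list(ok = maxv <= tol, max_violation = maxv)
}

#' Back-transform coefficients to the original data scale
#'
#' Converts coefficients estimated on the standardized scale to the raw
#' scale: `b_orig_j = b_std_j / scale_j` and
#' `intercept_orig = intercept_std - sum_j b_std_j * center_j / scale_j`,
#' so that predictions from raw data equal predictions from standardized
#' data exactly.
#'
#' @param beta_std (1+q+p) x L matrix whose first row is the intercept.
#' @param centers,scales per-column standardization constants (length q+p).
#' @return matrix of the same shape on the raw scale.
#' @export
format_coefficients <- function(beta_std, centers, scales) {
  beta_std <- as.matrix(beta_std)
  if (nrow(beta_std) != length(centers) + 1L ||
      length(centers) != length(scales)) {
    err_integrity("centers/scales do not match the coefficient matrix")
  }
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    err_integrity("missing or non-positive scale for a retained column")
  }
  body_std <- beta_std[-1L, , drop = FALSE]
  body_orig <- body_std / scales
  intercept <- beta_std[1L, ] - colSums(body_std * (centers / scales))
  out <- rbind(intercept, body_orig)
  rownames(out) <- c("(Intercept)",
                     if (is.null(rownames(body_std))) {
                       rep("", nrow(body_std))
                     } else rownames(body_std))
  out
}
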