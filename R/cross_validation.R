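#' Assign samples to cross-validation folds
#'
#' Uniformly random balanced partition (fold sizes differ by at most one),
#' deterministic given the seed. The global RNG state is left untouched.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n); `k = n` gives leave-one-out.
#' @param seed integer seed (NULL: use the current RNG state).
#' @return integer vector of fold labels in 1..k.
#' @export
assign_folds <- function(n, k, seed = NULL) {
  if (k < 2L || k > n) err_usage("k must satisfy 2 <= k <= n")
  with_seed(seed, {
    labels <- rep_len(seq_len(k), n)
    sample(labels)
  })
}

# Reconstruct raw-scale values of selected rows/columns from the
# standardized design: raw = x_std * scale + center. Exact because
# standardization is affine. With `restore_missing`, entries that were
# imputed at design time are set back to NA (from the stored missingness
# pattern) so downstream standardization re-imputes with its own means.
raw_rows <- function(d, rows, cols = seq_len(d$q + d$p), chunk = 2048L,
                     restore_missing = FALSE) {
  out <- matrix(NA_real_, length(rows), length(cols))
  for (j0 in chunk_starts(length(cols), chunk)) {
    j1 <- min(j0 + chunk - 1L, length(cols))
    idx <- cols[j0:j1]
    blk <- design_cols(d, idx)[rows, , drop = FALSE]
    out[, j0:j1] <- sweep(sweep(blk, 2, d$scales[idx], "*"), 2,
                          d$centers[idx], "+")
  }
  if (restore_missing && !is.null(d$missing_idx)) {
    for (jj in seq_along(cols)) {
      nas <- match(d$missing_idx[[cols[jj]]], rows)
      nas <- nas[!is.na(nas)]
      if (length(nas)) out[nas, jj] <- NA_real_
    }
  }
  colnames(out) <- d$col_names[cols]
  out
}

# Build a fresh design from a row subset: raw values are reconstructed
# (with original missingness restored) and every column is re-standardized
# and re-imputed using ONLY the subset rows, so no information from
# held-out rows enters the training centers/scales or imputations (nor,
# downstream, K or eta). Columns that are constant within the subset are
# dropped.
restandardize_rows <- function(d, rows, chunk = 2048L) {
  filebacked <- d$storage_mode == "filebacked"
  n <- length(rows)
  m <- d$q + d$p
  centers <- scales <- rep(NA_real_, m)
  keep <- logical(m)
  bpath <- NULL
  cols_list <- list()
  if (filebacked) {
    bpath <- tempfile(fileext = ".fbm")
    fbm_create(bpath, n, 0)   # p updated in sidecar only at the end
  }
  kept_total <- 0L
  for (j0 in chunk_starts(m, chunk)) {
    j1 <- min(j0 + chunk - 1L, m)
    idx <- j0:j1
    raw <- raw_rows(d, rows, idx, chunk, restore_missing = TRUE)
    std <- matrix(NA_real_, n, 0)
    for (jj in seq_along(idx)) {
      s <- standardize_column(raw[, jj])
      if (s$constant) next
      keep[idx[jj]] <- TRUE
      centers[idx[jj]] <- s$center
      scales[idx[jj]] <- s$scale
      std <- cbind(std, s$x_std)
    }
    kept_total <- kept_total + ncol(std)
    if (filebacked) fbm_append_cols(bpath, std) else cols_list[[length(cols_list) + 1L]] <- std
  }
  kept_idx <- which(keep)
  q_new <- sum(kept_idx <= d$q)
  structure(list(
    X_std = if (filebacked) NULL else do.call(cbind, cols_list),
    y = d$y[rows],
    centers = centers[kept_idx], scales = scales[kept_idx],
    penalty_factor = d$penalty_factor[kept_idx],
    kept_feature_ids = d$col_names[kept_idx[kept_idx > d$q]],
    unpenalized_ids = d$col_names[kept_idx[kept_idx <= d$q]],
    col_names = d$col_names[kept_idx],
    dropped_features = data.frame(
      id = d$col_names[!keep], reason = rep("zero_variance", sum(!keep))),
    sample_order = d$sample_order[rows],
    n = n, q = q_new, p = length(kept_idx) - q_new,
    storage_mode = d$storage_mode, backing_path = bpath
  ), class = "plmm_design")
}

#' Cross-validate a penalized linear mixed model
#'
#' k-fold cross-validation in which *every* model-fitting step is repeated
#' inside each fold: training rows are re-standardized, the relatedness
#' matrix, eta estimate, and preconditioner are recomputed from training
#' rows only, the path is refit on the rotated training data, and held-out
#' outcomes are predicted (BLUP by default). Leaving preconditioning outside
#' the folds would leak held-out information into the training model and
#' bias the error estimate. The lambda sequence is computed once from the
#' full data and shared across folds so errors are comparable per lambda.
#'
#' @param design a [create_design()] object.
#' @param penalty,gamma,alpha,eta,n_lambda,lambda_min_ratio,tol,max_iter,eta_cap
#'   as in [plmm()]; fixing `eta = 0` gives a correctly cross-validated
#'   plain penalized regression (the naive-comparison baseline).
#' @param k number of folds (default 5; `k = n` gives leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @param predict_method `"blup"` (default) or `"linear"`.
#' @param cores folds fitted in parallel with this many processes; results
#'   are identical to the serial run.
#' @param chunk_features columns per chunk in streaming passes.
#' @param cache_dir optional GRM eigendecomposition cache (see [grm_eigen()]).
#' @return an object of class `cv_plmm`: `lambda`, `cve` (mean squared
#'   prediction error per lambda), `cvse` (its standard error over folds),
#'   `rmspe`, `fold_assignments`, `lambda_min_index`, `lambda_min`,
#'   `lambda_1se_index`, per-fold metadata `fits` (eta, convergence), the
#'   full-data `fit`, and `seed`.
#' @export
cv_plmm <- function(design, penalty = "lasso",
                    gamma = default_gamma(penalty), alpha = 1, k = 5L,
                    seed = NULL, n_lambda = 100L, lambda_min_ratio = NULL,
                    predict_method = c("blup", "linear"), eta = NULL,
                    tol = 1e-4, max_iter = 10000L, cores = 1L,
                    chunk_features = 2048L, eta_cap = 0.999,
                    cache_dir = NULL) {
  predict_method <- match.arg(predict_method)
  d <- design
  n <- d$n
  folds <- assign_folds(n, k, seed)
  min_fold_train <- n - max(tabulate(folds, k))
  if (min_fold_train < d$q + 2L) {
    err_usage("a fold leaves fewer training rows than unpenalized columns + 2")
  }

  fit_full <- plmm(d, penalty = penalty, gamma = gamma, alpha = alpha,
                   eta = eta, n_lambda = n_lambda,
                   lambda_min_ratio = lambda_min_ratio, tol = tol,
                   max_iter = max_iter, chunk_features = chunk_features,
                   eta_cap = eta_cap, cache_dir = cache_dir)
  lambda <- fit_full$lambda

  run_fold <- function(i) {
    test <- which(folds == i)
    train <- which(folds != i)
    d_tr <- restandardize_rows(d, train, chunk_features)
    fit_tr <- plmm(d_tr, penalty = penalty, gamma = gamma, alpha = alpha,
                   eta = eta, lambda = lambda, tol = tol,
                   max_iter = max_iter, chunk_features = chunk_features,
                   eta_cap = eta_cap, cache_dir = cache_dir)
    X2 <- raw_rows(d, test, match(d_tr$col_names, d$col_names),
                   chunk_features, restore_missing = TRUE)
    pred <- predict(fit_tr, X2, type = predict_method)
    pred <- matrix(pred, nrow = length(test))
    sqerr <- (d$y[test] - pred)^2
    list(mse = colMeans(sqerr), eta = fit_tr$eta,
         converged = all(fit_tr$convergence$converged),
         beta_original = fit_tr$beta_original)
  }

  fold_res <- if (cores > 1L) {
    parallel::mclapply(seq_len(k), run_fold, mc.cores = cores)
  } else {
    lapply(seq_len(k), run_fold)
  }

  mse_mat <- do.call(rbind, lapply(fold_res, `[[`, "mse"))  # k x L
  cve <- colMeans(mse_mat)
  cvse <- apply(mse_mat, 2, stats::sd) / sqrt(k)
  lambda_min_index <- which.min(cve)
  within_1se <- which(cve <= cve[lambda_min_index] + cvse[lambda_min_index])
  lambda_1se_index <- min(within_1se)

  structure(list(
    lambda = lambda, cve = cve, cvse = cvse, rmspe = sqrt(cve),
    fold_assignments = folds, lambda_min_index = lambda_min_index,
    lambda_min = lambda[lambda_min_index],
    lambda_1se_index = lambda_1se_index,
    fits = data.frame(fold = seq_len(k),
                      eta = vapply(fold_res, `[[`, numeric(1), "eta"),
                      converged = vapply(fold_res, `[[`, logical(1), "converged")),
    fold_mse = mse_mat,
    fit = fit_full, k = k, seed = seed, predict_method = predict_method
  ), class = "cv_plmm")
}

#' @export
print.cv_plmm <- function(x, ...) {
  i <- x$lambda_min_index
  nz <- sum(x$fit$beta_original[-1L, i] != 0)
  cat(sprintf(
    "cv_plmm: %d-fold CV (%s predictions)\n  lambda_min = %.5g (index %d), CVE = %.4g, RMSPE = %.4g, %d nonzero coefficient(s)\n",
    x$k, x$predict_method, x$lambda_min, i, x$cve[i], x$rmspe[i], nz))
  invisible(x)
}

#' @export
summary.cv_plmm <- function(object, ...) {
  data.frame(lambda = object$lambda, cve = object$cve, cvse = object$cvse,
             rmspe = object$rmspe,
             nonzero = Matrix::colSums(object$fit$beta_original[-1L, , drop = FALSE] != 0),
             at_min = seq_along(object$lambda) == object$lambda_min_index)
}

#' Plot cross-validation error
#'
#' CVE against log(lambda) with +/- 1 SE bars and a vertical line at
#' lambda_min.
#'
#' @param x a [cv_plmm()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_plmm <- function(x, ...) {
  ll <- log(x$lambda)
  graphics::plot(ll, x$cve, pch = 19, cex = 0.6,
                 ylim = range(c(x$cve - x$cvse, x$cve + x$cvse)),
                 xlab = expression(log(lambda)),
                 ylab = "cross-validation error", ...)
  graphics::arrows(ll, x$cve - x$cvse, ll, x$cve + x$cvse, angle = 90,
                   code = 3, length = 0.02, col = "grey60")
  graphics::abline(v = ll[x$lambda_min_index], lty = 2, col = "red")
  invisible(x)
}
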