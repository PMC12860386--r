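# Standardize new raw data with TRAINING centers/scales (never its own),
# aligning columns by name to the training design. Missing entries impute
# to the training center (0 on the standardized scale).
standardize_newdata <- function(fit, newdata) {
  newdata <- as.matrix(newdata)
  cn <- fit$col_names
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(cn)) {
      err_usage(sprintf(
        "newdata has %d columns but the model used %d; name the columns to allow alignment",
        ncol(newdata), length(cn)))
    }
    colnames(newdata) <- cn
  }
  miss <- setdiff(cn, colnames(newdata))
  if (length(miss)) {
    err_usage(paste("newdata is missing model features:",
                    paste(utils::head(miss, 10), collapse = ", "),
                    if (length(miss) > 10) sprintf("... (%d total)", length(miss)) else ""))
  }
  X2 <- newdata[, cn, drop = FALSE]
  for (j in seq_along(cn)) {
    nas <- is.na(X2[, j])
    if (any(nas)) X2[nas, j] <- fit$centers[j]
  }
  sweep(sweep(X2, 2, fit$centers, "-"), 2, fit$scales, "/")
}

#' Predict from a penalized linear mixed model
#'
#' Two prediction modes for new samples. `"linear"` is the standard linear
#' predictor `intercept + X2 b_hat` on the original data scale. `"blup"`
#' (the default) is the best linear unbiased predictor, which adds a
#' correlation-based adjustment borrowing strength from training samples
#' related to the new ones:
#' `y2_hat = X2 b_hat + Sigma21 Sigma11^{-1} (y1 - X1 b_hat)`,
#' with `K21 = (1/p) X2_std X1_std'` estimated from the standardized
#' penalized features, `Sigma21 = eta K21`, and
#' `Sigma11^{-1} = U diag(1/(eta s + 1 - eta)) U'` applied through the
#' training eigendecomposition. New data are standardized with the training
#' centers and scales; at `eta = 0` the adjustment vanishes and BLUP equals
#' the linear predictor.
#'
#' @param object a [plmm()] fit.
#' @param newdata m x (q+p) matrix of raw-scale values for the model's
#'   columns (unpenalized covariates and features), aligned by column name.
#' @param type `"blup"` (default) or `"linear"`.
#' @param idx lambda index (or vector of indices); default: whole path.
#' @param same_samples set TRUE when the rows of `newdata` are the training
#'   observations themselves, in order (not merely related individuals). The
#'   noise component of the covariance is then shared too, so
#'   `Sigma21 = eta K21 + (1 - eta) I = Sigma11` and the BLUP returns the
#'   observed training outcomes exactly. For genuinely new samples (the
#'   default, FALSE) only the structure component is shared:
#'   `Sigma21 = eta K21`.
#' @param ... unused.
#' @return numeric matrix (m x length(idx)), dropped to a vector for a
#'   single index.
#' @export
predict.plmm_fit <- function(object, newdata, type = c("blup", "linear"),
                             idx = NULL, same_samples = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(idx)) idx <- seq_along(object$lambda)
  if (any(idx < 1L | idx > length(object$lambda))) err_usage("idx out of range")
  X2_std <- standardize_newdata(object, newdata)
  b_std <- as.matrix(object$beta_std[, idx, drop = FALSE])
  lp2 <- matrix(rep(b_std[1L, ], each = nrow(X2_std)), nrow(X2_std)) +
    X2_std %*% b_std[-1L, , drop = FALSE]

  if (type == "blup" && (object$eta > 0 || same_samples)) {
    q <- object$q; p <- object$p
    pen <- q + seq_len(p)
    X1_std <- design_matrix(object$design)
    K21 <- tcrossprod(X2_std[, pen, drop = FALSE],
                      X1_std[, pen, drop = FALSE]) / p
    resid_train <- object$y - object$linear_predictors[, idx, drop = FALSE]
    dinv <- 1 / (object$eta * object$eig$S + 1 - object$eta)
    s11inv_r <- object$eig$U %*% (dinv * crossprod(object$eig$U, resid_train))
    adj <- object$eta * (K21 %*% s11inv_r)
    if (isTRUE(same_samples)) {
      if (nrow(X2_std) != object$n) {
        err_usage("same_samples = TRUE requires one row per training sample")
      }
      adj <- adj + (1 - object$eta) * s11inv_r
    }
    lp2 <- lp2 + adj
  }
  colnames(lp2) <- paste0("lambda_", idx)
  if (length(idx) == 1L) as.numeric(lp2) else lp2
}
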