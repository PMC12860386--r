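#' Standardize one column with mean imputation
#'
#' Missing entries are imputed to the observed column mean, the column is
#' centered, and scaled so that its mean square is exactly 1 (the population
#' 1/n convention, which makes the relatedness matrix satisfy trace(K) = n).
#' Imputed entries are therefore exactly 0 on the standardized scale.
#'
#' @param x numeric vector (length >= 2).
#' @param missing optional logical mask; defaults to `is.na(x)`.
#' @return list with `x_std`, `center`, `scale`, and `constant` (TRUE when
#'   the column has zero variance, including the all-missing case, in which
#'   case `x_std` is NULL and the column should be dropped).
#' @export
standardize_column <- function(x, missing = is.na(x)) {
  n <- length(x)
  if (n < 2L) err_usage("standardization needs at least 2 observations")
  obs <- !missing
  n_obs <- sum(obs)
  if (n_obs == 0L) {
    return(list(x_std = NULL, center = NA_real_, scale = NA_real_,
                constant = TRUE))
  }
  center <- sum(x[obs]) / n_obs
  ss <- sum((x[obs] - center)^2)      # imputed entries contribute 0
  scale <- sqrt(ss / n)
  if (scale < 1e-12 * max(1, abs(center))) {
    return(list(x_std = NULL, center = center, scale = 0, constant = TRUE))
  }
  x_imp <- x
  x_imp[missing] <- center
  list(x_std = (x_imp - center) / scale, center = center, scale = scale,
       constant = FALSE)
}

#' Build a model-ready design from genotypes and an outcome table
#'
#' Aligns an outcome/covariate table to a [genotype_matrix()] by sample ID,
#' applies quality-control filters, imputes missing dosages to the column
#' mean, and standardizes every retained column to mean 0 and mean square 1.
#' The resulting design has the unpenalized covariate columns first
#' (penalty factor 0) followed by the penalized feature columns (penalty
#' factor 1).
#'
#' Samples are the ID intersection of the two inputs, kept in genotype
#' order; samples without an outcome are dropped with a message. Features
#' whose minor allele frequency (computed from observed, non-missing calls)
#' falls below `maf_min` are dropped with reason `"maf"`; the MAF filter
#' applies only to allele-count columns (all observed values in \{0,1,2\}) —
#' continuous features such as expression bypass it. Constant columns are
#' dropped with reason `"zero_variance"`.
#'
#' @param g a [genotype_matrix()].
#' @param outcome_table data.frame keyed by sample ID.
#' @param outcome_id name of the ID column of `outcome_table`.
#' @param outcome_col name of the numeric outcome column.
#' @param unpenalized character vector of covariate column names in
#'   `outcome_table` to include unpenalized (e.g. sex, age, site).
#' @param maf_min minor-allele-frequency threshold (at least 0, below 0.5); features
#'   below it are dropped.
#' @param filebacked if `TRUE` (or if `g` is file-backed), the standardized
#'   matrix is written to a flat binary backing file in column chunks.
#' @param chunk_features columns per chunk for streaming passes.
#' @param backing_path where to put the backing file (default: tempfile).
#' @return an object of class `plmm_design` with elements `X_std`, `y`,
#'   `centers`, `scales`, `penalty_factor`, `kept_feature_ids`,
#'   `dropped_features`, `sample_order`, `n`, `q` (unpenalized columns),
#'   `p` (penalized columns).
#' @export
create_design <- function(g, outcome_table, outcome_id = "ID",
                          outcome_col = "y", unpenalized = character(),
                          maf_min = 0, filebacked = NULL,
                          chunk_features = 2048L, backing_path = NULL) {
  if (maf_min < 0 || maf_min >= 0.5) err_usage("maf_min must be in [0, 0.5)")
  if (!outcome_id %in% names(outcome_table)) {
    err_usage(sprintf("outcome ID column '%s' not found; available: %s",
                      outcome_id, paste(names(outcome_table), collapse = ", ")))
  }
  if (!outcome_col %in% names(outcome_table)) {
    err_usage(sprintf("outcome column '%s' not found; available: %s",
                      outcome_col, paste(names(outcome_table), collapse = ", ")))
  }
  ids_out <- as.character(outcome_table[[outcome_id]])
  if (anyDuplicated(ids_out)) err_integrity("duplicate IDs in outcome table")
  y_all <- outcome_table[[outcome_col]]
  if (!is.numeric(y_all)) err_usage("outcome column must be numeric")
  missing_cov <- setdiff(unpenalized, names(outcome_table))
  if (length(missing_cov)) {
    err_usage(paste("unpenalized covariates not found in outcome table:",
                    paste(missing_cov, collapse = ", ")))
  }

  gid <- g$sample_ids$iid
  keep_rows <- which(gid %in% ids_out & !is.na(y_all[match(gid, ids_out)]))
  if (length(keep_rows) == 0L) {
    err_integrity("no sample IDs shared between genotypes and outcome table")
  }
  n_dropped <- g$n_samples - length(keep_rows)
  if (n_dropped > 0) {
    message(sprintf("dropping %d sample(s) without an outcome", n_dropped))
  }
  ord <- match(gid[keep_rows], ids_out)   # genotype order is kept
  y <- as.numeric(y_all[ord])
  n <- length(keep_rows)
  if (n < 2L) err_integrity("fewer than 2 aligned samples")

  # unpenalized covariate block
  U <- if (length(unpenalized)) {
    um <- sapply(unpenalized, function(v) {
      col <- outcome_table[[v]][ord]
      if (!is.numeric(col)) col <- as.numeric(as.factor(col))
      col
    })
    matrix(um, nrow = n, dimnames = list(NULL, unpenalized))
  } else matrix(numeric(0), n, 0)

  filebacked <- isTRUE(filebacked) || (is.null(filebacked) &&
                                       g$storage_mode == "filebacked")

  dropped <- data.frame(id = character(), reason = character())
  # covariates first
  u_std <- list(); u_center <- u_scale <- numeric(0); u_keep <- character(0)
  for (v in colnames(U)) {
    s <- standardize_column(U[, v])
    if (s$constant) {
      dropped <- rbind(dropped, data.frame(id = v, reason = "zero_variance"))
    } else {
      u_std[[v]] <- s$x_std
      u_center <- c(u_center, s$center); u_scale <- c(u_scale, s$scale)
      u_keep <- c(u_keep, v)
    }
  }
  q <- length(u_keep)

  # one streaming pass over features for stats + filters (on aligned rows)
  sub_cols <- function(j_idx) gm_columns(g, j_idx)[keep_rows, , drop = FALSE]
  p_all <- g$n_features
  center <- scale <- rep(NA_real_, p_all)
  keep_feat <- logical(p_all)
  reasons <- character(p_all)
  for (j0 in chunk_starts(p_all, chunk_features)) {
    j1 <- min(j0 + chunk_features - 1L, p_all)
    blk <- sub_cols(j0:j1)
    for (jj in seq_len(ncol(blk))) {
      j <- j0 + jj - 1L
      x <- blk[, jj]
      obs <- !is.na(x)
      if (!any(obs)) { reasons[j] <- "zero_variance"; next }
      m <- mean(x[obs])
      sc <- sqrt(sum((x[obs] - m)^2) / n)
      if (sc < 1e-12 * max(1, abs(m))) { reasons[j] <- "zero_variance"; next }
      if (maf_min > 0 && all(x[obs] %in% c(0, 1, 2))) {
        f <- m / 2
        if (min(f, 1 - f) < maf_min) { reasons[j] <- "maf"; next }
      }
      keep_feat[j] <- TRUE
      center[j] <- m; scale[j] <- sc
    }
  }
  if (any(!keep_feat)) {
    dropped <- rbind(dropped, data.frame(id = g$feature_ids[!keep_feat],
                                         reason = reasons[!keep_feat]))
  }
  kept <- which(keep_feat)
  p <- length(kept)
  if (p + q == 0L) err_integrity("no usable columns after filtering")

  centers <- c(u_center, center[kept])
  scales <- c(u_scale, scale[kept])
  col_names <- c(u_keep, g$feature_ids[kept])
  penalty_factor <- c(rep(0, q), rep(1, p))

  # second pass: write/assemble standardized matrix; the missingness
  # pattern of retained columns is kept (sparse row-index list) so that
  # row subsets (e.g. cross-validation folds) can re-impute with their own
  # means instead of inheriting full-data imputations
  missing_idx <- vector("list", q + p)
  for (v in seq_along(u_keep)) {
    missing_idx[[v]] <- which(is.na(U[, u_keep[v]]))
  }
  if (!filebacked) {
    X_std <- matrix(NA_real_, n, q + p, dimnames = list(NULL, col_names))
    for (v in seq_along(u_keep)) X_std[, v] <- u_std[[u_keep[v]]]
    for (j0 in chunk_starts(p, chunk_features)) {
      j1 <- min(j0 + chunk_features - 1L, p)
      blk <- sub_cols(kept[j0:j1])
      for (jj in seq_len(ncol(blk))) {
        j <- j0 + jj - 1L
        x <- blk[, jj]
        nas <- which(is.na(x))
        missing_idx[[q + j]] <- nas
        x[nas] <- center[kept[j]]
        X_std[, q + j] <- (x - center[kept[j]]) / scale[kept[j]]
      }
    }
    storage_mode <- "in_memory"; bpath <- NULL
  } else {
    if (is.null(backing_path)) backing_path <- tempfile(fileext = ".fbm")
    fbm_create(backing_path, n, q + p, feature_ids = col_names,
               sample_ids = gid[keep_rows])
    if (q > 0) {
      fbm_append_cols(backing_path,
                      matrix(unlist(u_std[u_keep]), nrow = n))
    }
    for (j0 in chunk_starts(p, chunk_features)) {
      j1 <- min(j0 + chunk_features - 1L, p)
      blk <- sub_cols(kept[j0:j1])
      for (jj in seq_len(ncol(blk))) {
        j <- j0 + jj - 1L
        x <- blk[, jj]
        nas <- which(is.na(x))
        missing_idx[[q + j]] <- nas
        x[nas] <- center[kept[j]]
        blk[, jj] <- (x - center[kept[j]]) / scale[kept[j]]
      }
      fbm_append_cols(backing_path, blk)
    }
    X_std <- NULL; storage_mode <- "filebacked"; bpath <- backing_path
  }

  structure(list(
    X_std = X_std, y = y, centers = centers, scales = scales,
    penalty_factor = penalty_factor, kept_feature_ids = g$feature_ids[kept],
    unpenalized_ids = u_keep, col_names = col_names,
    dropped_features = dropped, sample_order = gid[keep_rows],
    missing_idx = missing_idx,
    n = n, q = q, p = p, storage_mode = storage_mode, backing_path = bpath
  ), class = "plmm_design")
}

#' @export
print.plmm_design <- function(x, ...) {
  cat(sprintf(
    "plmm_design: %d samples, %d penalized + %d unpenalized columns (%s)\n",
    x$n, x$p, x$q, x$storage_mode))
  if (nrow(x$dropped_features)) {
    tab <- table(x$dropped_features$reason)
    cat("  dropped features:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.plmm_design <- function(x) c(x$n, x$q + x$p)

# Dense access to standardized columns, whatever the storage mode.
design_cols <- function(d, j_idx) {
  if (d$storage_mode == "in_memory") {
    d$X_std[, j_idx, drop = FALSE]
  } else {
    fbm_read_cols(d$backing_path, d$n, j_idx)
  }
}

# Full standardized matrix (used by small-n routines: eigen, BLUP context).
design_matrix <- function(d) {
  if (d$storage_mode == "in_memory") d$X_std
  else {
    m <- design_cols(d, seq_len(d$q + d$p))
    colnames(m) <- d$col_names
    m
  }
}
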