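#' Genomic relatedness matrix from a design
#'
#' Computes K = (1/p) X X' over the standardized *penalized* feature columns
#' of a design, accumulating over column chunks so file-backed data are
#' streamed rather than loaded. Unpenalized covariates (sex, site, ...) do
#' not enter K: they are fixed effects, while K models genetic similarity.
#' With mean-square-1 standardization, trace(K) = n exactly.
#'
#' @param d a [create_design()] object with at least one penalized column.
#' @param chunk_features columns per accumulation chunk.
#' @return symmetric n x n matrix.
#' @export
compute_grm <- function(d, chunk_features = 2048L) {
  if (d$p < 1L) err_usage("design has no penalized features; K is undefined")
  n <- d$n
  K <- matrix(0, n, n)
  pen_idx <- d$q + seq_len(d$p)
  for (j0 in chunk_starts(d$p, chunk_features)) {
    j1 <- min(j0 + chunk_features - 1L, d$p)
    blk <- design_cols(d, pen_idx[j0:j1])
    K <- K + tcrossprod(blk)
  }
  K / d$p
}

#' Eigendecomposition of a relatedness matrix
#'
#' Full symmetric eigendecomposition of K, with eigenvalues sorted in
#' descending order. Small negative eigenvalues (within -1e-8 of zero, a
#' numerical artifact of accumulation) are clipped to 0.
#'
#' @param K symmetric n x n matrix.
#' @param p number of features K was computed from (metadata).
#' @return an object of class `eigen_relatedness` with orthonormal
#'   eigenvectors `U` (n x n) and eigenvalues `S` (length n, descending).
#' @export
eigendecompose <- function(K, p = NA_integer_) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) err_usage("K must be a square matrix")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8) {
    err_integrity(sprintf("K is asymmetric (max |K - K'| = %.3g)", asym))
  }
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  S <- e$values
  S[S < 0 & S > -1e-8] <- 0
  structure(list(U = e$vectors, S = S, n = nrow(K), p = p),
            class = "eigen_relatedness")
}

#' GRM eigendecomposition with optional on-disk cache
#'
#' Convenience wrapper: computes K from the design and eigendecomposes it.
#' When `cache_dir` is given, the result is cached on disk keyed by an MD5
#' content hash of the design (shape, centers, scales, outcome), so repeated
#' fits and cross-validation folds on the same design skip the O(n^3) work.
#'
#' @param d a [create_design()] object.
#' @param chunk_features columns per accumulation chunk.
#' @param cache_dir optional directory for the cache.
#' @return an `eigen_relatedness` object.
#' @export
grm_eigen <- function(d, chunk_features = 2048L, cache_dir = NULL) {
  if (!is.null(cache_dir)) {
    key_obj <- list(n = d$n, q = d$q, p = d$p, centers = d$centers,
                    scales = d$scales, y = d$y, ids = d$kept_feature_ids)
    tf <- tempfile()
    saveRDS(key_obj, tf)
    key <- unname(tools::md5sum(tf))
    unlink(tf)
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir, paste0("eig-", key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  eig <- eigendecompose(compute_grm(d, chunk_features), p = d$p)
  if (!is.null(cache_dir)) saveRDS(eig, cache_file)
  eig
}

#' @export
print.eigen_relatedness <- function(x, ...) {
  cat(sprintf("eigen_relatedness: n = %d (from p = %s features)\n",
              x$n, format(x$p)))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$S, 5), 4), collapse = ", "), "...\n")
  invisible(x)
}
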