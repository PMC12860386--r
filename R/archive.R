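# Serialized artifacts: each pipeline stage is re-runnable from its upstream
# artifact. A directory holds a meta.json plus flat binary float64 arrays
# and TSV tables (sparse coefficient triplets), so archives are readable
# outside R.

write_bin_array <- function(x, path) {
  con <- file(path, "wb")
  writeBin(as.vector(as.numeric(x)), con, size = 8L)
  close(con)
}

read_bin_array <- function(path, n = NA) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = if (is.na(n)) file.size(path) / 8 else n, size = 8L)
}

write_sparse_tsv <- function(m, path) {
  tr <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  utils::write.table(data.frame(row = tr$i, col = tr$j, value = tr$x),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_sparse_tsv <- function(path, nrow, ncol, dimnames = NULL) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t")
  Matrix::sparseMatrix(i = tr$row, j = tr$col, x = tr$value,
                       dims = c(nrow, ncol), dimnames = dimnames)
}

# manifest written next to every CLI artifact: config, package version, and
# content hashes of the files produced
write_manifest <- function(dir, config, files) {
  files <- files[file.exists(files)]
  jsonlite::write_json(
    list(package = "plmmfit",
         version = as.character(utils::packageVersion("plmmfit")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config,
         hashes = as.list(tools::md5sum(files))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Save / load a design archive
#'
#' A design archive is a directory with `meta.json` (shape, column names,
#' centers/scales, penalty factors, sample order, outcome) and `X_std.bin`
#' (flat float64, column-major).
#'
#' @param d a [create_design()] object.
#' @param dir output directory (created if needed).
#' @return `dir` (save) / a `plmm_design` (load), invisibly for save.
#' @export
save_design <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n = d$n, q = d$q, p = d$p, col_names = d$col_names,
               centers = d$centers, scales = d$scales,
               penalty_factor = d$penalty_factor,
               kept_feature_ids = d$kept_feature_ids,
               unpenalized_ids = d$unpenalized_ids,
               sample_order = d$sample_order,
               dropped_features = d$dropped_features, y = d$y)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(file.path(dir, "X_std.bin"), "wb")
  for (j0 in chunk_starts(d$q + d$p, 2048L)) {
    j1 <- min(j0 + 2047L, d$q + d$p)
    writeBin(as.vector(design_cols(d, j0:j1)), con, size = 8L)
  }
  close(con)
  invisible(dir)
}

#' @rdname save_design
#' @export
load_design <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  m <- meta$q + meta$p
  X <- matrix(read_bin_array(file.path(dir, "X_std.bin"), meta$n * m),
              meta$n, m, dimnames = list(NULL, meta$col_names))
  dropped <- as.data.frame(meta$dropped_features)
  if (!nrow(dropped)) dropped <- data.frame(id = character(), reason = character())
  structure(list(
    X_std = X, y = meta$y, centers = meta$centers, scales = meta$scales,
    penalty_factor = meta$penalty_factor,
    kept_feature_ids = meta$kept_feature_ids,
    unpenalized_ids = meta$unpenalized_ids, col_names = meta$col_names,
    dropped_features = dropped, sample_order = meta$sample_order,
    n = meta$n, q = meta$q, p = meta$p,
    storage_mode = "in_memory", backing_path = NULL
  ), class = "plmm_design")
}

#' Save / load a fit archive
#'
#' A fit archive is a directory with `meta.json` (lambda path, eta, penalty
#' settings, convergence, column metadata), sparse coefficient triplets
#' (`beta_original.tsv`, `beta_std.tsv`), flat binary arrays (`y.bin`,
#' `linear_predictors.bin`, eigenvectors `U.bin`, eigenvalues `S.bin`), and
#' an embedded design archive, which together are sufficient to reload the
#' fit and make BLUP predictions.
#'
#' @param fit a [plmm()] fit.
#' @param dir output directory (created if needed).
#' @return `dir` (save) / a `plmm_fit` (load), invisibly for save.
#' @export
save_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(lambda = fit$lambda, eta = fit$eta, penalty = fit$penalty,
               gamma = fit$gamma, alpha = fit$alpha, n = fit$n, q = fit$q,
               p = fit$p, col_names = fit$col_names, centers = fit$centers,
               scales = fit$scales, convergence = fit$convergence,
               eta_profile = if (!is.null(fit$vc)) fit$vc$loglik_profile else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  write_sparse_tsv(fit$beta_original, file.path(dir, "beta_original.tsv"))
  write_sparse_tsv(fit$beta_std, file.path(dir, "beta_std.tsv"))
  write_bin_array(fit$y, file.path(dir, "y.bin"))
  write_bin_array(fit$linear_predictors, file.path(dir, "linear_predictors.bin"))
  write_bin_array(fit$eig$U, file.path(dir, "U.bin"))
  write_bin_array(fit$eig$S, file.path(dir, "S.bin"))
  save_design(fit$design, file.path(dir, "design"))
  invisible(dir)
}

#' @rdname save_fit
#' @export
load_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  L <- length(meta$lambda)
  rows <- c("(Intercept)", meta$col_names)
  d <- load_design(file.path(dir, "design"))
  n <- meta$n
  eig <- structure(list(
    U = matrix(read_bin_array(file.path(dir, "U.bin"), n * n), n, n),
    S = read_bin_array(file.path(dir, "S.bin"), n), n = n, p = meta$p
  ), class = "eigen_relatedness")
  structure(list(
    beta_original = read_sparse_tsv(file.path(dir, "beta_original.tsv"),
                                    length(rows), L, list(rows, NULL)),
    beta_std = read_sparse_tsv(file.path(dir, "beta_std.tsv"),
                               length(rows), L, list(rows, NULL)),
    lambda = meta$lambda, eta = meta$eta, vc = NULL, eig = eig,
    penalty = meta$penalty, gamma = meta$gamma, alpha = meta$alpha,
    linear_predictors = matrix(
      read_bin_array(file.path(dir, "linear_predictors.bin"), n * L), n, L),
    y = read_bin_array(file.path(dir, "y.bin"), n),
    convergence = as.data.frame(meta$convergence),
    design = d, n = n, q = meta$q, p = meta$p,
    col_names = meta$col_names, centers = meta$centers,
    scales = meta$scales
  ), class = "plmm_fit")
}
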