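# Internal helpers: classed conditions, RNG scoping, and the flat-binary
# file-backed matrix layer used by the out-of-core path.

stop_plmm <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "plmmfit_error"), call = call))
}

# condition classes map to CLI exit codes: usage 2, integrity 3, numerical 4
err_format    <- function(msg) stop_plmm(msg, "plmmfit_format_error")
err_integrity <- function(msg) stop_plmm(msg, "plmmfit_integrity_error")
err_usage     <- function(msg) stop_plmm(msg, "plmmfit_usage_error")
err_numeric   <- function(msg) stop_plmm(msg, "plmmfit_numeric_error")

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

chunk_starts <- function(p, chunk) {
  if (p == 0L) return(integer(0))
  seq.int(1L, p, by = max(1L, as.integer(chunk)))
}

## ---- file-backed matrix (fbm) -------------------------------------------
## Layout: one flat binary file of float64 in column-major order (column j
## occupies bytes (j-1)*n*8 ... j*n*8-1), plus a JSON sidecar with the shape,
## ids and dtype. Missing values are stored as NaN. Column-major order
## matches the access pattern of standardization, K accumulation and
## coordinate descent, which all read column blocks.

fbm_sidecar_path <- function(path) paste0(path, ".json")

fbm_create <- function(path, n, p, feature_ids = NULL, sample_ids = NULL,
                       extra = list()) {
  con <- file(path, "wb")
  close(con)
  meta <- c(list(n = n, p = p, dtype = "float64", order = "column_major",
                 feature_ids = feature_ids, sample_ids = sample_ids), extra)
  jsonlite::write_json(meta, fbm_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

fbm_meta <- function(path) {
  jsonlite::read_json(fbm_sidecar_path(path), simplifyVector = TRUE)
}

# append columns; must be called with contiguous j starting where the file ends
fbm_append_cols <- function(path, x) {
  con <- file(path, "ab")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L)
  invisible(path)
}

# random access to an arbitrary set of columns; contiguous runs are read in
# single seek+readBin calls
fbm_read_cols <- function(path, n, j_idx) {
  j_idx <- as.integer(j_idx)
  out <- matrix(NA_real_, n, length(j_idx))
  if (length(j_idx) == 0L) return(out)
  con <- file(path, "rb")
  on.exit(close(con))
  runs <- split(seq_along(j_idx), cumsum(c(1L, diff(j_idx) != 1L)))
  for (run in runs) {
    j0 <- j_idx[run[1L]]
    m <- length(run)
    seek(con, where = (j0 - 1) * n * 8, origin = "start")
    vals <- readBin(con, what = "double", n = n * m, size = 8L)
    out[, run] <- vals
  }
  out
}

fbm_ncols_on_disk <- function(path, n) {
  file.size(path) / (8 * n)
}

is_wholenumber <- function(x, tol = 1e-8) {
  ok <- !is.na(x)
  all(abs(x[ok] - round(x[ok])) < tol)
}
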