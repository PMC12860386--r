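#' Genotype matrix container
#'
#' A `genotype_matrix` holds an n samples x p features dosage matrix together
#' with sample and feature identifiers. Dosages are allele counts in
#' \{0, 1, 2\} (or `NA` for missing) when read from PLINK filesets, but
#' arbitrary numeric features (e.g. gene expression) are allowed when read
#' from delimited text. Storage is either a plain in-memory matrix or a
#' file-backed flat binary (float64, column-major) that is read in column
#' blocks so the full matrix need never be resident in memory.
#'
#' @param dosages numeric matrix (samples x features), `NA` = missing.
#' @param sample_ids data.frame with columns `fid` and `iid`, or a character
#'   vector used for both.
#' @param feature_ids character vector of unique feature names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, feature_ids) {
  dosages <- as.matrix(dosages)
  if (is.character(sample_ids)) {
    sample_ids <- data.frame(fid = sample_ids, iid = sample_ids)
  }
  if (nrow(dosages) != nrow(sample_ids)) {
    err_integrity("number of rows of dosages does not match sample_ids")
  }
  if (ncol(dosages) != length(feature_ids)) {
    err_integrity("number of columns of dosages does not match feature_ids")
  }
  if (anyDuplicated(feature_ids)) {
    err_integrity("feature_ids must be unique")
  }
  structure(list(
    n_samples = nrow(dosages), n_features = ncol(dosages),
    sample_ids = sample_ids, feature_ids = as.character(feature_ids),
    storage_mode = "in_memory", backing_path = NULL,
    dosages = dosages
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d features (%s)\n",
              x$n_samples, x$n_features, x$storage_mode))
  if (x$storage_mode == "filebacked")
    cat("  backing file:", x$backing_path, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(x$n_samples, x$n_features)

#' Read a block of columns from a genotype matrix
#'
#' Returns the requested columns as a dense numeric matrix regardless of the
#' storage mode. This is the single access path used by standardization,
#' relatedness accumulation, and the fitting engine, so file-backed and
#' in-memory data flow through identical arithmetic.
#'
#' @param g a [genotype_matrix()].
#' @param j_idx integer column indices.
#' @return numeric matrix with `length(j_idx)` columns (`NA` = missing).
#' @export
gm_columns <- function(g, j_idx) {
  if (length(j_idx) && (min(j_idx) < 1L || max(j_idx) > g$n_features)) {
    err_usage("column index out of range")
  }
  if (g$storage_mode == "in_memory") {
    g$dosages[, j_idx, drop = FALSE]
  } else {
    m <- fbm_read_cols(g$backing_path, g$n_samples, j_idx)
    m[is.nan(m)] <- NA_real_
    m
  }
}

## ---- PLINK 1 .bed codec ---------------------------------------------------
## SNP-major layout: per variant, ceil(n/4) bytes; 2 bits per sample, least
## significant bits first. Codes (A1 allele counts): 00 -> 2, 10 -> 1,
## 11 -> 0, 01 -> missing.

.bed_magic <- as.raw(c(0x6C, 0x1B))

# 256 x 4 lookup: dosage of the s-th sample (s = 1..4) encoded in byte b+1
bed_decode_table <- function(count_allele = c("A1", "A2")) {
  count_allele <- match.arg(count_allele)
  code_map <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)  # 2-bit value -> dosage
  if (count_allele == "A2") code_map <- c(`0` = 0, `1` = NA_real_, `2` = 1, `3` = 2)
  tab <- matrix(NA_real_, 256L, 4L)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      tab[b + 1L, s + 1L] <- code_map[[as.character(code)]]
    }
  }
  tab
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes a `.bed`/`.bim`/`.fam` fileset (SNP-major mode) into a
#' [genotype_matrix()]. Dosages are counts of the A1 allele by default
#' (2-bit code 00 -> 2 copies, 10 -> 1, 11 -> 0, 01 -> missing), flipped to
#' A2 counts with `count_allele = "A2"`.
#'
#' @param prefix path prefix of the fileset, or the path of the `.bed` file.
#' @param filebacked if `TRUE`, decoded dosages are written once to a flat
#'   binary backing file and subsequently accessed in column blocks, so the
#'   full matrix is never held in memory.
#' @param chunk_features number of variants decoded per chunk in the
#'   file-backed path.
#' @param backing_path where to put the backing file (default: tempfile).
#' @param count_allele which allele to count, `"A1"` (default) or `"A2"`.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix, filebacked = FALSE, chunk_features = 1024L,
                       backing_path = NULL, count_allele = "A1") {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) err_usage(paste("missing file:", f))
  }
  fam_tb <- utils::read.table(fam, header = FALSE, colClasses = "character")
  n <- nrow(fam_tb)
  sample_ids <- data.frame(fid = fam_tb[[1]], iid = fam_tb[[2]])
  bim_tb <- if (file.size(bim) > 0) {
    utils::read.table(bim, header = FALSE, colClasses = "character")
  } else data.frame(V1 = character(), V2 = character())
  p <- nrow(bim_tb)
  feature_ids <- if (p) as.character(bim_tb[[2]]) else character(0)
  if (anyDuplicated(feature_ids)) err_integrity(".bim variant ids are not unique")

  bpv <- ceiling(n / 4)  # bytes per variant row
  con <- file(bed, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 3L)
  if (length(hdr) < 3L || hdr[1] != .bed_magic[1] || hdr[2] != .bed_magic[2]) {
    bad <- if (length(hdr) < 1L) "truncated file"
      else if (hdr[1] != .bed_magic[1]) sprintf("byte 1 is 0x%02X (expected 0x6C)", as.integer(hdr[1]))
      else sprintf("byte 2 is 0x%02X (expected 0x1B)", as.integer(hdr[2]))
    err_format(paste0(".bed magic number check failed: ", bad))
  }
  if (hdr[3] == as.raw(0x00)) {
    err_format(".bed is in individual-major mode (0x00), which is not supported; re-export in SNP-major mode")
  }
  if (hdr[3] != as.raw(0x01)) {
    err_format(sprintf(".bed mode byte is 0x%02X (expected 0x01)", as.integer(hdr[3])))
  }
  payload_len <- file.size(bed) - 3
  if (payload_len != p * bpv) {
    err_integrity(sprintf(
      ".bed payload is %d bytes but .bim/.fam imply %d variants x %d bytes = %d",
      payload_len, p, bpv, p * bpv))
  }

  tab <- bed_decode_table(count_allele)
  decode_chunk <- function(raw_bytes, n_var) {
    # raw -> (4*bpv) x n_var dosage block, then truncate padding rows
    b <- matrix(as.integer(raw_bytes), nrow = bpv, ncol = n_var)
    out <- matrix(NA_real_, n, n_var)
    for (s in 1:4) {
      rows <- seq.int(s, by = 4L, length.out = bpv)
      keep <- rows <= n
      out[rows[keep], ] <- tab[b[keep, , drop = FALSE] + 1L, s]
    }
    out
  }

  if (!filebacked || p == 0L) {
    dos <- matrix(NA_real_, n, p)
    for (j0 in chunk_starts(p, chunk_features)) {
      j1 <- min(j0 + chunk_features - 1L, p)
      raw_bytes <- readBin(con, "raw", n = (j1 - j0 + 1L) * bpv)
      dos[, j0:j1] <- decode_chunk(raw_bytes, j1 - j0 + 1L)
    }
    colnames(dos) <- feature_ids
    g <- genotype_matrix(dos, sample_ids, feature_ids)
  } else {
    if (is.null(backing_path)) backing_path <- tempfile(fileext = ".fbm")
    fbm_create(backing_path, n, p, feature_ids = feature_ids,
               sample_ids = sample_ids$iid)
    for (j0 in chunk_starts(p, chunk_features)) {
      j1 <- min(j0 + chunk_features - 1L, p)
      raw_bytes <- readBin(con, "raw", n = (j1 - j0 + 1L) * bpv)
      fbm_append_cols(backing_path, decode_chunk(raw_bytes, j1 - j0 + 1L))
    }
    g <- structure(list(
      n_samples = n, n_features = p, sample_ids = sample_ids,
      feature_ids = feature_ids, storage_mode = "filebacked",
      backing_path = backing_path, dosages = NULL
    ), class = "genotype_matrix")
  }
  g$bim <- bim_tb
  g$fam <- fam_tb
  g
}

#' Write a PLINK 1 binary fileset
#'
#' Encodes a [genotype_matrix()] (dosages in \{0,1,2,NA\}) as a SNP-major
#' `.bed` with companion `.bim`/`.fam`. When the object has no variant
#' metadata, `.bim` defaults are chr = 1, cM = 0, bp = feature index,
#' A1 = "A", A2 = "B"; `.fam` defaults are fid/iid with zero parents,
#' unknown sex, and phenotype -9. [read_plink()] inverts the encoding
#' exactly.
#'
#' @param g a [genotype_matrix()] with dosages in \{0,1,2,NA\}.
#' @param prefix output path prefix.
#' @param chunk_features variants encoded per chunk.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, chunk_features = 1024L) {
  n <- g$n_samples; p <- g$n_features
  bpv <- ceiling(n / 4)
  # dosage -> 2-bit code (A1 counts): 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(d) {
    code <- rep(1L, length(d))           # missing
    ok <- !is.na(d)
    if (!is_wholenumber(d)) err_format("non-integer dosage cannot be PLINK-encoded")
    dd <- round(d[ok])
    if (any(dd < 0 | dd > 2)) err_format("dosages outside {0,1,2} cannot be PLINK-encoded")
    code[ok] <- c(3L, 2L, 0L)[dd + 1L]
    code
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(.bed_magic, as.raw(0x01)), con)
  for (j0 in chunk_starts(p, chunk_features)) {
    j1 <- min(j0 + chunk_features - 1L, p)
    block <- gm_columns(g, j0:j1)
    codes <- matrix(code_of(block), nrow = n)
    # pad to 4*bpv samples with code 0 (padding bits, ignored on read)
    if (4L * bpv > n) {
      codes <- rbind(codes, matrix(0L, 4L * bpv - n, ncol(codes)))
    }
    s1 <- codes[seq.int(1L, 4L * bpv, 4L), , drop = FALSE]
    s2 <- codes[seq.int(2L, 4L * bpv, 4L), , drop = FALSE]
    s3 <- codes[seq.int(3L, 4L * bpv, 4L), , drop = FALSE]
    s4 <- codes[seq.int(4L, 4L * bpv, 4L), , drop = FALSE]
    bytes <- s1 + s2 * 4L + s3 * 16L + s4 * 64L   # LSB-first packing
    writeBin(as.raw(bytes), con)
  }
  close(con)

  # [[ ]] access: plain $ would partial-match other fields (e.g. $family)
  bim <- if (!is.null(g[["bim"]]) && nrow(g[["bim"]]) == p && p > 0) {
    g[["bim"]]
  } else {
    data.frame(chr = rep(1L, p), id = g$feature_ids, cm = rep(0L, p),
               bp = seq_len(p), a1 = rep("A", p), a2 = rep("B", p))
  }
  fam <- if (!is.null(g[["fam"]]) && nrow(g[["fam"]]) == n) {
    g[["fam"]]
  } else {
    data.frame(fid = g$sample_ids$fid, iid = g$sample_ids$iid,
               pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  }
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a delimited sample-by-feature matrix
#'
#' Parses a rectangular delimited text file with a header row into a
#' [genotype_matrix()]. One column holds sample IDs; all other columns are
#' parsed as numeric features. Values need not be allele counts: continuous
#' features such as gene expression are accepted. Empty cells and `"NA"`
#' become missing.
#'
#' @param path file path.
#' @param id_column name of the sample-ID column.
#' @param delimiter field delimiter (default `","`).
#' @return a [genotype_matrix()].
#' @export
read_delimited <- function(path, id_column = "ID", delimiter = ",") {
  if (!file.exists(path)) err_usage(paste("file not found:", path))
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    err_format(sprintf("ragged table: line %d has %d fields (expected %d)",
                       bad, nf[bad], nf[1L]))
  }
  tb <- utils::read.table(path, header = TRUE, sep = delimiter,
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!id_column %in% names(tb)) {
    err_usage(sprintf("ID column '%s' not found; available columns: %s",
                      id_column, paste(names(tb), collapse = ", ")))
  }
  ids <- as.character(tb[[id_column]])
  if (anyDuplicated(ids)) {
    err_integrity(sprintf("duplicate sample IDs in '%s' (e.g. %s)", path,
                          ids[duplicated(ids)][1L]))
  }
  feat <- tb[, setdiff(names(tb), id_column), drop = FALSE]
  x <- vapply(feat, function(col) {
    if (is.character(col)) suppressWarnings(as.numeric(col)) else as.numeric(col)
  }, numeric(nrow(tb)))
  x <- matrix(x, nrow = nrow(tb),
              dimnames = list(NULL, setdiff(names(tb), id_column)))
  genotype_matrix(x, ids, colnames(x))
}
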