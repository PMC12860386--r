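# column standardization, alignment, QC filters

test_that("standardize_column matches hand-computed values", {
  # raw [0,1,2,1]: center 1, scale sqrt(mean((x-1)^2)) = sqrt(0.5)
  s <- standardize_column(c(0, 1, 2, 1))
  expect_equal(s$center, 1)
  expect_equal(s$scale, sqrt(0.5))
  expect_equal(s$x_std, c(-sqrt(2), 0, sqrt(2), 0))

  expect_equal(standardize_column(c(0, 2))$x_std, c(-1, 1))

  # impute-then-standardize equals the complete-case rule on imputed data
  s3 <- standardize_column(c(0, NA, 2))
  expect_equal(s3$center, 1)
  expect_equal(s3$scale, sqrt(2 / 3))
  expect_equal(s3$x_std, c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(s3$x_std[2], 0)     # imputed entries are exactly 0

  expect_true(standardize_column(c(5, 5, 5))$constant)
  expect_true(standardize_column(c(NA_real_, NA_real_))$constant)
})

test_that("create_design standardizes, aligns by ID, and is order-invariant", {
  g <- toy_genotypes(n = 12, p = 6, seed = 2, missing_rate = 0.1)
  y <- rnorm(12)
  tb <- data.frame(ID = g$sample_ids$iid, y = y,
                   age = rnorm(12), sex = rep(c(0, 1), 6))
  d <- create_design(g, tb, unpenalized = c("sex", "age"))
  expect_s3_class(d, "plmm_design")
  expect_equal(d$q, 2L)
  expect_equal(d$y, y)
  expect_design_standardized(d)
  expect_equal(d$penalty_factor, c(0, 0, rep(1, d$p)))
  # mean-square-1 scaling: sum over columns of (1/n) x'x equals column count
  expect_equal(sum(colMeans(d$X_std^2)), d$q + d$p, tolerance = 1e-12)

  # reversed outcome rows give the identical design
  d2 <- create_design(g, tb[12:1, ], unpenalized = c("sex", "age"))
  expect_equal(d2$X_std, d$X_std)
  expect_equal(d2$y, d$y)
  expect_equal(d2$sample_order, d$sample_order)
})

test_that("samples without an outcome are dropped; empty overlap errors", {
  g <- toy_genotypes(n = 10, p = 4, seed = 4, missing_rate = 0)
  tb <- data.frame(ID = g$sample_ids$iid[1:7], y = rnorm(7))
  expect_message(d <- create_design(g, tb), "dropping 3")
  expect_equal(d$n, 7L)
  expect_equal(d$sample_order, g$sample_ids$iid[1:7])

  tb_bad <- data.frame(ID = paste0("zz", 1:5), y = rnorm(5))
  expect_error(create_design(g, tb_bad), class = "plmmfit_integrity_error")
  tb_dup <- data.frame(ID = rep("ind01", 2), y = rnorm(2))
  expect_error(create_design(g, tb_dup), class = "plmmfit_integrity_error")
})

test_that("MAF filter drops rare dosage columns but not continuous ones", {
  n <- 20
  dos <- cbind(rep(c(0, 1), 10),          # common
               c(1, rep(0, n - 1)),       # freq 1/40 = 0.025
               rnorm(n, 10, 2))           # continuous: bypasses MAF filter
  g <- genotype_matrix(dos, sprintf("s%02d", 1:n), c("common", "rare", "expr"))
  tb <- data.frame(ID = g$sample_ids$iid, y = rnorm(n))
  d <- create_design(g, tb, maf_min = 0.05)
  expect_true("rare" %in% d$dropped_features$id)
  expect_equal(d$dropped_features$reason[d$dropped_features$id == "rare"],
               "maf")
  expect_true(all(c("common", "expr") %in% d$kept_feature_ids))

  # the rule is strict: maf below the threshold drops, at/above it keeps
  d2 <- create_design(g, tb, maf_min = 0.025)   # rare column has maf 0.025
  expect_false("rare" %in% d2$dropped_features$id)
  expect_error(create_design(g, tb, maf_min = 0.5),
               class = "plmmfit_usage_error")
})

test_that("constant columns are dropped with reason zero_variance", {
  dos <- cbind(rep(1, 8), c(0, 1, 2, 0, 1, 2, 0, 1))
  g <- genotype_matrix(dos, paste0("s", 1:8), c("const", "ok"))
  tb <- data.frame(ID = g$sample_ids$iid, y = rnorm(8))
  d <- create_design(g, tb)
  expect_equal(d$dropped_features,
               data.frame(id = "const", reason = "zero_variance"))
  expect_equal(d$kept_feature_ids, "ok")
})

test_that("create_design is idempotent on an already-aligned clean pair", {
  g <- toy_genotypes(n = 15, p = 5, seed = 9, missing_rate = 0)
  tb <- data.frame(ID = g$sample_ids$iid, y = rnorm(15))
  d1 <- create_design(g, tb)
  # feed the standardized data back through as continuous features
  g2 <- genotype_matrix(d1$X_std, d1$sample_order, d1$col_names)
  d2 <- create_design(g2, tb)
  expect_equal(d2$X_std, d1$X_std, tolerance = 1e-12)
  expect_equal(d2$centers, rep(0, d1$p), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d2$scales, rep(1, d1$p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("imputed entries are exactly zero on the standardized scale", {
  g <- toy_genotypes(n = 20, p = 8, seed = 6, missing_rate = 0.2)
  tb <- data.frame(ID = g$sample_ids$iid, y = rnorm(20))
  d <- create_design(g, tb)
  raw <- gm_columns(g, match(d$kept_feature_ids, g$feature_ids))
  expect_true(all(d$X_std[is.na(raw)] == 0))
})
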