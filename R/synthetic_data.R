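#' Simulation specification
#'
#' Bundles the knobs of the synthetic genotype/phenotype generator: sample
#' and feature counts, sparse causal effects, the structure proportion of
#' outcome variance (eta), family blocks, ancestry groups with
#' Balding-Nichols-style allele-frequency divergence, missingness, and an
#' optional structure-confounding mode.
#'
#' @param n_samples,n_features matrix dimensions.
#' @param n_causal number of causal features (effect `beta_effect` each, on
#'   the standardized scale).
#' @param beta_effect causal effect size.
#' @param eta_true proportion of (non-genetic-effect) outcome variance due
#'   to structure, in the closed interval 0 to 1.
#' @param n_families number of family blocks (`n_samples` = all singletons);
#'   members of a family are simulated as full siblings sharing two
#'   pseudo-parents.
#' @param n_populations number of ancestry groups; families are assigned to
#'   groups round-robin.
#' @param fst_like_divergence Balding-Nichols divergence parameter F in
#'   0 to 1 (excluding 1): population allele frequencies are drawn from
#'   Beta(f(1-F)/F, (1-f)(1-F)/F) around the ancestral frequency f.
#' @param maf_range ancestral allele frequencies are uniform on this range
#'   (subset of (0, 0.5]).
#' @param missing_rate fraction of entries set missing uniformly at random.
#' @param confounded if TRUE, the structure component of the phenotype is a
#'   per-population batch shift, so null features whose frequencies diverge
#'   across populations become spurious proxies for the outcome.
#' @param seed integer seed; all generation is deterministic given it.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 100L, n_features = 1000L, n_causal = 0L,
                     beta_effect = 0.5, eta_true = 0.5,
                     n_families = n_samples, n_populations = 1L,
                     fst_like_divergence = 0, maf_range = c(0.05, 0.45),
                     missing_rate = 0, confounded = FALSE, seed = 1L) {
  if (n_causal > n_features) err_usage("n_causal must be <= n_features")
  if (eta_true < 0 || eta_true > 1) err_usage("eta_true must be in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    err_usage("maf_range must be within (0, 0.5]")
  }
  if (n_families > n_samples || n_families < 1L) {
    err_usage("n_families must be in 1..n_samples")
  }
  if (fst_like_divergence < 0 || fst_like_divergence >= 1) {
    err_usage("fst_like_divergence must be in the half-open interval 0 to 1 (excluding 1)")
  }
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate structured genotypes
#'
#' Draws allele-count genotypes with family blocks and ancestry strata.
#' Ancestral allele frequencies are uniform on `maf_range`; each population
#' perturbs them by a Balding-Nichols Beta draw governed by
#' `fst_like_divergence`. Families are full-sibling blocks: two pseudo-parent
#' genotypes are drawn from the population frequency and each member
#' receives one Mendelian allele from each parent, so within-family
#' correlation exceeds between-family correlation. Missing entries are
#' placed uniformly at random. Deterministic given `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return a [genotype_matrix()] with extra fields `population` and `family`
#'   (integer labels per sample).
#' @export
simulate_genotypes <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features
    n_fam <- spec$n_families; n_pop <- spec$n_populations
    fam_sizes <- rep(n %/% n_fam, n_fam) +
      c(rep(1L, n %% n_fam), rep(0L, n_fam - n %% n_fam))
    family <- rep(seq_len(n_fam), fam_sizes)
    fam_pop <- rep_len(seq_len(n_pop), n_fam)
    population <- fam_pop[family]

    f_anc <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
    Fst <- spec$fst_like_divergence
    fpop <- matrix(rep(f_anc, n_pop), nrow = n_pop, byrow = TRUE)
    if (n_pop > 1L && Fst > 0) {
      for (k in seq_len(n_pop)) {
        a <- f_anc * (1 - Fst) / Fst
        b <- (1 - f_anc) * (1 - Fst) / Fst
        fpop[k, ] <- stats::rbeta(p, a, b)
      }
      fpop <- pmin(pmax(fpop, 1e-3), 1 - 1e-3)
    }

    dos <- matrix(NA_real_, n, p)
    row <- 1L
    for (fm in seq_len(n_fam)) {
      sz <- fam_sizes[fm]
      fq <- fpop[fam_pop[fm], ]
      if (sz == 1L) {
        dos[row, ] <- stats::rbinom(p, 2L, fq)
      } else {
        g_mother <- stats::rbinom(p, 2L, fq)
        g_father <- stats::rbinom(p, 2L, fq)
        for (s in seq_len(sz)) {
          a1 <- stats::rbinom(p, 1L, g_mother / 2)
          a2 <- stats::rbinom(p, 1L, g_father / 2)
          dos[row + s - 1L, ] <- a1 + a2
        }
      }
      row <- row + sz
    }
    if (spec$missing_rate > 0) {
      dos[stats::runif(n * p) < spec$missing_rate] <- NA_real_
    }

    ids <- data.frame(fid = sprintf("F%04d", family),
                      iid = sprintf("S%05d", seq_len(n)))
    feat <- sprintf("snp%05d", seq_len(p))
    colnames(dos) <- feat
    g <- genotype_matrix(dos, ids, feat)
    g$population <- population
    g$family <- family
    g
  })
}

#' Simulate a phenotype under the structured linear mixed model
#'
#' Generates `y = X_causal beta + u + e` with total non-feature variance 1:
#' the structure component `u` has variance `eta_true` and the noise `e`
#' has variance `1 - eta_true`. In the default mode `u` is drawn from
#' N(0, eta_true * K) through the eigendecomposition of the realized
#' relatedness matrix (`u = U diag(sqrt(eta_true * s)) z`). In the
#' `confounded` mode `u` is instead a per-population batch shift scaled to
#' variance `eta_true`, which null features track through their diverged
#' allele frequencies — the adversarial setting for a naive (unrotated)
#' regression. Causal features are a seeded random subset with effects
#' `beta_effect` on the standardized scale. Deterministic given
#' `spec$seed + 1`.
#'
#' @param g a [simulate_genotypes()] result (or any [genotype_matrix()]).
#' @param spec the same [sim_spec()].
#' @return list with `y` and `truth` (causal ids, beta, eta_true, and the
#'   realized structure component `u`).
#' @export
simulate_phenotype <- function(g, spec) {
  with_seed(spec$seed + 1L, {
    n <- g$n_samples; p <- g$n_features
    X <- gm_columns(g, seq_len(p))
    Xs <- matrix(0, n, p)
    ok <- logical(p)
    for (j in seq_len(p)) {
      s <- standardize_column(X[, j])
      if (!s$constant) { Xs[, j] <- s$x_std; ok[j] <- TRUE }
    }
    eta <- spec$eta_true

    causal <- if (spec$n_causal > 0) {
      sort(sample(which(ok), spec$n_causal))
    } else integer(0)
    beta <- rep(spec$beta_effect, length(causal))
    signal <- if (length(causal)) {
      Xs[, causal, drop = FALSE] %*% beta
    } else rep(0, n)

    if (eta > 0) {
      if (isTRUE(spec$confounded)) {
        pop <- g$population
        if (is.null(pop)) err_usage("confounded mode needs population labels")
        shift <- stats::rnorm(max(pop))[pop]
        shift <- shift - mean(shift)
        u <- shift / sqrt(mean(shift^2)) * sqrt(eta)
      } else {
        K <- tcrossprod(Xs[, ok, drop = FALSE]) / sum(ok)
        e <- eigen(K, symmetric = TRUE)
        s_clip <- pmax(e$values, 0)
        u <- as.numeric(e$vectors %*% (sqrt(eta * s_clip) * stats::rnorm(n)))
      }
    } else u <- rep(0, n)

    eps <- stats::rnorm(n, sd = sqrt(1 - eta))
    y <- as.numeric(signal + u + eps)
    list(y = y,
         truth = list(causal_idx = causal,
                      causal_ids = g$feature_ids[causal],
                      beta = beta, eta_true = eta, u = u,
                      population = g$population, family = g$family))
  })
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: simulates genotypes and a phenotype and returns them
#' with an outcome table ready for [create_design()].
#'
#' @param spec a [sim_spec()].
#' @return list with `genotypes`, `outcome_table` (ID + y), and `truth`.
#' @export
simulate_dataset <- function(spec) {
  g <- simulate_genotypes(spec)
  ph <- simulate_phenotype(g, spec)
  list(genotypes = g,
       outcome_table = data.frame(ID = g$sample_ids$iid, y = ph$y),
       truth = ph$truth)
}
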