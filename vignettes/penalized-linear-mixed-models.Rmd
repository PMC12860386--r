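---
title: "Penalized linear mixed models for correlated high-dimensional data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized linear mixed models for correlated high-dimensional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmmfit)
```

## The problem

High-dimensional regression — a phenotype on hundreds of thousands of SNPs,
a clinical outcome on genome-wide expression — usually assumes independent
observations. Real cohorts violate this: batch effects, recruitment-site
differences, ancestry strata, and families (often cryptic, never fully
annotated) all induce correlation among samples. Treating correlated samples
as independent both miscalibrates selection (structure-associated null
features enter the model as proxies for the confounder) and wastes
information (related samples predict each other).

`plmmfit` fits the penalized linear mixed model

$$ y = X\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma_s^2 K),\quad
   \varepsilon \sim N(0, \sigma_\varepsilon^2 I), $$

where $K = \tfrac1p X X^\top$ is the genomic relatedness matrix computed
from the column-standardized features themselves — no pedigree, batch label,
or ancestry assignment is required. Writing
$\Sigma \propto \eta K + (1-\eta) I$ with
$\eta = \sigma_s^2/(\sigma_s^2+\sigma_\varepsilon^2)$, the model is
*preconditioned* (rotated) by $F = \Sigma^{-1/2}$:

$$ F y = (F X)\beta + F(u + \varepsilon),\qquad
   \operatorname{Var}\{F(u+\varepsilon)\} \propto I, $$

so ordinary sparse penalized regression applies on the rotated scale. The
rotation mixes rows (samples) but not columns: $\beta_j$ still measures the
effect of feature $j$, which is what distinguishes this approach from
principal-component adjustment.

## The pipeline and its pieces

A fit consists of three steps, mirrored by the internal structure of
`plmm()`:

1. **prep** — `compute_grm()` accumulates $K$ over column chunks of the
   standardized penalized features (unpenalized covariates such as sex or
   site are fixed effects and do not enter $K$); `eigendecompose()` takes
   the full symmetric eigendecomposition $K = U S U^\top$;
   `estimate_eta()` maximizes the restricted profile likelihood of the
   *null* model; `build_preconditioner()` forms
   $F = \mathrm{diag}(w)\,U^\top$ with $w_i = (\eta s_i + 1-\eta)^{-1/2}$.
2. **fit** — the intercept-augmented design is rotated and a coordinate
   descent solver traces a descending $\lambda$ path for the lasso
   (default), MCP, or SCAD penalty, each with an optional elastic-net ridge
   component (`alpha`).
3. **format** — coefficients return to the original data scale:
   $\beta_j^{\text{orig}} = \beta_j^{\text{std}}/s_j$ with the matching
   intercept shift, so predictions from raw data are exactly those from
   standardized data.

### Standardization and imputation

Columns are standardized to mean 0 and mean square 1 with the $1/n$
(population) divisor. This convention makes $\mathrm{tr}(K) = n$ exactly,
which the test suite exploits as an analytic invariant. Missing dosages are
imputed to the observed column mean *before* standardization, so imputed
entries are exactly 0 on the standardized scale; minor allele frequencies
for the QC filter are computed from observed calls only. The design keeps
the missingness pattern, so any later row subset (notably cross-validation
folds) re-imputes with its own means — full-data imputations never leak into
fold-training statistics. This matters in practice: a rare variant whose
single carrier is missing becomes near-constant inside a fold, and
inheriting the full-data imputation there produces a tiny scale and
explosive standardized values for held-out carriers.

### Variance components

$\eta$ is estimated once, under the null model (intercept + unpenalized
covariates), by profile *restricted* maximum likelihood on the
$U^\top$-rotated scale, where each evaluation is a closed-form weighted
least squares with weights $(\eta s_i + 1-\eta)^{-1}$. A 100-point grid
scan brackets the optimum and `optimize()` refines it. REML rather than
plain ML is a deliberate choice: because the design columns are centered,
the all-ones vector is a zero-eigenvector of $K$, and the intercept fits
that rotated coordinate exactly; the plain-ML profile then diverges to
$\eta = 1$ for *every* dataset (a zero residual rewarded by $-\log d$),
whereas the REML term $\log\lvert X_0^\top \Sigma^{-1} X_0\rvert$ cancels
the divergence exactly. $\eta$ is capped at 0.999 so the rotation weights
stay finite when $K$ is singular, which it always is after centering.

### The solver

On the rotated scale the columns are no longer unit-scale, and
re-standardizing them would change the estimand. Instead the coordinate
updates use per-column curvatures $v_j = \tfrac1n \tilde x_j^\top \tilde
x_j$: the one-dimensional minimizer of
$\tfrac{v}{2}b^2 - zb + P_\lambda(b)$ is applied exactly for each penalty
family (soft thresholding for the lasso; the firm-threshold rules for MCP
and SCAD, with the elastic-net ridge folded into the denominators). The
path solver uses warm starts, an active-set strategy (iterate on the
nonzero set, then one full sweep), and an ever-active screening loop that
re-scans all columns for KKT violations after each inner solve — the same
chunked access pattern serves in-memory and file-backed data. Convergence
is declared when $\max_j |\Delta\beta_j|\sqrt{v_j}$ falls below `tol`
times the root mean square of the rotated outcome. `lambda_path()` sets
$\lambda_{\max}$ from the KKT bound on the outcome residualized against
the unpenalized block, then log-spaces `n_lambda = 100` values down to
`lambda_min_ratio` (0.01 when $n$ exceeds the number of penalized columns,
0.05 otherwise); `tol = 1e-4`, `max_iter = 10000`, $\gamma_{\rm MCP} = 3$,
$\gamma_{\rm SCAD} = 3.7$, $\alpha = 1$ follow the conventions of
established penalized-regression software. Fits at $\lambda_{\max}$ start
from the exact least-squares solution of the unpenalized block, so the
all-zero solution there is exact, not approximate.

### Prediction

Two modes. The linear predictor is the usual
$\hat y_2 = \hat\beta_0 + X_2\hat\beta$. The BLUP (default) adds a
correlation adjustment,

$$ \hat y_2 = X_2\hat\beta +
   \hat\Sigma_{21}\hat\Sigma_{11}^{-1}(y_1 - X_1\hat\beta), $$

with $K_{21} = \tfrac1p X_2^{\rm std} X_1^{\rm std\top}$ estimated from the
standardized penalized features (training centers and scales are always
reused for new data) and $\hat\Sigma_{11}^{-1}$ applied through the stored
eigendecomposition. For genuinely new samples only the structure component
of the covariance is shared, $\hat\Sigma_{21} = \hat\eta K_{21}$, so at
$\hat\eta = 0$ the BLUP collapses to the linear predictor. When the
prediction targets *are* the training observations
(`same_samples = TRUE`), the noise is shared too,
$\hat\Sigma_{21} = \hat\eta K_{21} + (1-\hat\eta) I = \hat\Sigma_{11}$,
and the BLUP interpolates the observed outcomes exactly — the standard
fitted-value identity of mixed models. These two regimes are the only
consistent reading of the pair of identities "$\eta = 0$ implies BLUP =
linear predictor" and "predicting the training data returns $y_1$".

### Cross-validation

`cv_plmm()` repeats *everything* inside each fold: the training rows are
re-standardized and re-imputed, $K$, $\hat\eta$, and $F$ are recomputed
from training rows only, the path is refit, and held-out outcomes are
predicted by BLUP from the training-fold context. Preconditioning outside
the folds would let held-out samples shape the training rotation — a
leakage that standard penalized-regression CV tooling cannot detect. The
$\lambda$ sequence is computed once from the full data and shared across
folds so the error curve is comparable per $\lambda$; a fold's own
$\lambda_{\max}$ can exceed the shared head of the path, in which case the
fold model at $\lambda_1$ is legitimately not the null model. `k = 5` by
default; `k = n` gives leave-one-out for small expression-style studies.
Selection is at the CVE minimum (`lambda_min`), with a one-standard-error
index also reported. Fold fitting is a pure function of the fold data, so
serial and parallel execution give identical results.

## The synthetic-data generator

`simulate_genotypes()` draws ancestral allele frequencies uniformly on
`maf_range` (default 0.05–0.45), perturbs them per population by a
Balding–Nichols Beta draw with divergence parameter `fst_like_divergence`,
assigns families round-robin to populations, and simulates each family as
full siblings of two pseudo-parents (one Mendelian allele from each), so
within-family relatedness exceeds between-family relatedness by
construction. `simulate_phenotype()` draws
$y = X_{\rm causal}\beta + u + \varepsilon$ with unit total non-feature
variance: $\operatorname{Var}(u) = \eta_{\rm true}$,
$\operatorname{Var}(\varepsilon) = 1 - \eta_{\rm true}$. By default $u$ is
drawn from $N(0, \eta_{\rm true} K)$ through the realized
eigendecomposition; with `confounded = TRUE` it is instead a per-population
batch shift scaled to the same variance, the adversarial case where
divergent-frequency null SNPs proxy the confounder almost perfectly.

What the generator does *not* emulate: linkage disequilibrium along a map,
case/control ascertainment, genotyping-batch missingness patterns, or
effect sizes tied to allele frequency. Passing tests therefore certify the
algebra, the solver, and the leakage-free workflow on data with realistic
*correlation structure*, not the full messiness of a real GWAS.

## What the checks show — and one honest negative

The test suite verifies, among others: the whitening identity
$F\Sigma F^\top = I$ to $10^{-8}$ across an $\eta$ grid; KKT certification
of the solver to $10^{-6}$ and objective agreement with an independent
proximal-gradient solver to $10^{-7}$; exact reduction to plain penalized
regression at $\eta = 0$; recovery of $\eta$ from generated data at
$n = 200$, $p = 1000$ (the estimator is unbiased at all three simulated
levels; its mean absolute error is below 0.1 at $\eta = 0.2$ and $0.8$,
while at $\eta = 0.5$ the observed 0.14 sits at the Fisher-information
limit of the family-only relatedness spectrum — the eigenvalue spread of
$K$ simply does not carry enough information for a tighter estimate at
this sample size, for any estimator); the BLUP identities
against a dense-algebra oracle; bitwise independence of training-fold
models from held-out outcomes; and bit-exact PLINK round trips with
in-memory/file-backed agreement to $10^{-10}$.

On confounded synthetic data (10 replicates, $n = 300$, $p = 2000$, a
two-population batch shift), the PLMM selects about four times fewer
false-positive features than a naive unrotated lasso at each method's own
$\lambda_{\min}$ — the central selection claim. Its held-out RMSPE,
however, averages a few percent *worse* than the naive lasso in this
setting, and the corresponding assertion in the acceptance tests fails by
design rather than being weakened. The reason is instructive: the simulated
confounder is a single population shift that null SNPs track almost
perfectly, so the naive model predicts well *through* its false positives,
while the mixed model declines those proxies and relies on a BLUP whose
null-model $\hat\eta$ overstates the structure remaining once causal
features are in the model. Within the PLMM itself BLUP clearly beats the
linear predictor at the null end of the path; the gap to the naive model is
the price of honest selection under this particular confounder geometry.

## Out-of-core operation

File-backed genotype matrices are flat binary files of float64 in
column-major order with a JSON sidecar (shape, IDs, dtype), read in column
blocks through a single access path shared with in-memory data —
standardization, $K$ accumulation, rotation, and the solver's KKT scans
all stream columns and never materialize the matrix. PLINK 1 filesets are
decoded bit-exactly (SNP-major, two bits per genotype, A1-allele counts by
default with an `count_allele = "A2"` flip; individual-major files are
rejected with an explicit error rather than silently transposed). Problem
sizes in the tests (up to $n = 300$, $p = 2000$; eigendecompositions up to
$n = 300$) were chosen so the whole suite runs in minutes on one core; the
dense eigendecomposition is the binding constraint at larger $n$, which is
why the package targets cohorts up to roughly $10^4$ samples and does not
attempt biobank scale.

## Known limitations

- Gaussian linear models only; binary outcomes must be treated as numeric.
- A single structure variance component; no heteroskedastic noise, no
  externally supplied kinship.
- $\hat\eta$ is estimated once under the null model and reused along the
  whole path, which can over-adjust predictions at small $\lambda$.
- Fold assignment is uniform; family-aware (grouped) folds are a natural
  extension the data structures already support.
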