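---
title: "Methods: sparse PRS with batch screening, penalty factors, and synthetic truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse PRS with batch screening, penalty factors, and synthetic truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery: the
models and algorithms, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the design decisions that were genuinely open. It
states no empirical result that the test suite or the acceptance script does
not itself compute.

## 1. The sparse PRS model

For n individuals with trait $y$, m variant dosages $g_{ij} \in \{0,1,2\}$
and covariates $c_i$ (age, sex, genotyping-array indicator, ten genotype
PCs), the engine minimizes

$$\frac{1}{2n}\,\mathrm{dev}\!\left(y,\; \beta_0 + c_i'\gamma + x_i'\beta\right)
  \;+\; \lambda \sum_j w_j |\beta_j|$$

over a decreasing geometric grid of $\lambda$, where $x_{ij}$ is the
standardized dosage, the deviance is squared error (gaussian) or the
logistic deviance (binomial), covariates and intercept are never penalized,
and $w_j$ is the per-variant penalty factor. Standardizing the penalized
columns (training-set mean and population SD) is what makes a shared
$\lambda w_j$ comparable across variants; covariates are centered only, so
their coefficients stay on their natural scale.

**Penalty factors.** Three levels encode prior medical relevance: 0.5
(ClinVar pathogenic, or protein-truncating), 0.75 (likely pathogenic,
protein-altering, or imputed HLA allelotype), 1.0 (everything else). A
factor below 1 lowers the selection price of a variant by exactly that
ratio: on duplicated columns, the low-penalty copy provably enters the path
at a larger $\lambda$, and the test suite exercises this on constructed
instances. "Medically relevant" is, by construction, equivalent to
$w_j < 1$.

## 2. Batch screening with KKT certification

The full design (potentially very wide) is never given to the solver.
Per $\lambda$:

1. **Screen.** Zero-coefficient variants are ranked by
   $|x_j' r|/(n\,w_j)$ — the gradient of the smooth loss scaled so
   prioritized variants screen in earlier — and the top `batch_size` join
   the active set. Ties break by variant index for determinism. Variants
   with $w_j = 0$ (none under the default rule, but supported) are always
   active.
2. **Solve.** Weighted coordinate descent over the active set, warm-started
   from the previous $\lambda$. The binomial family re-linearizes by outer
   IRLS with inner weighted coordinate descent and step-halving on the
   penalized objective, which guarantees the objective never increases
   across iterations.
3. **Certify.** A KKT check over **all** variants:
   $|x_j' r|/n > \lambda w_j$ for any $\beta_j = 0$ means the screened
   solution is not the full-problem solution; violators are added and the
   segment re-solved until clean. Every coefficient vector the path reports
   is therefore identical (to solver tolerance) to a dense no-screening fit,
   and the suite asserts this against an independent dense-lasso
   implementation at $10^{-6}$.

The per-$\lambda$ validation metric is R² (gaussian) or AUC (binomial); the
path stops after `early_stop_patience` non-improving values, the selected
$\lambda$ maximizes the validation metric with ties broken toward the
sparser model, and the final model is refit on the combined
training + validation set at the selected $\lambda$ **value** (not index):
$\lambda$ is the regularization strength the validation data endorsed, and
re-deriving a grid index on a larger sample would change that strength.
Refit coefficients are de-standardized to per-dosage effect-allele weights,
with training allele frequencies stored for frequency-imputation of missing
or untyped dosages at scoring time ($2\hat p_j$).

### Numerical choices

* `cd_tolerance` (default 1e-7, standardized scale): maximum absolute
  coefficient change per sweep. Oracle-comparison tests use 1e-10.
* KKT slack 1e-7 (additive): below this, "violations" are solver noise.
* Binomial IRLS weights are floored at 1e-5 to guard near-separation; the
  fixed point still satisfies the exact stationarity condition because the
  working response uses the true residual $y - p$.
* In the deeply saturated binomial tail (smallest $\lambda$s at
  `lambda_min_ratio` = 0.01) the problem becomes ill-conditioned and
  *any* two solvers agree only to about $10^{-5}$–$10^{-6}$; the oracle
  tests therefore stop the grid at ratio 0.05, where agreement is
  $\sim 10^{-7}$. This bounds the comparison, not the engine's correctness:
  KKT certification holds at every reported $\lambda$.
* `n_lambda` 100 / `lambda_min_ratio` 0.01 / `batch_size` 1000 defaults
  mirror the conventions of large-scale path solvers; tests shrink the grid
  and batch purely for budget.

## 3. Evaluation of incremental performance

Three models per (trait, population): genotype-only (the PRS itself),
covariate-only (`trait ~ age + sex + array + PCs` fit on the development
set, applied to the target set; constant columns such as a single-array
indicator are dropped), and the full model
`trait ~ 1 + covariate score + PRS`, whose intercept absorbs mean/prevalence
shifts between development and target populations. Significance of the PRS
is the two-sided Wald p of its term in the full model, judged against
p < 0.05/2000 (strict).

Metrics: R² is the squared Pearson correlation between prediction and
observation (not $1 - \mathrm{SSE}/\mathrm{SST}$), so genotype-only scores
need no recalibration; its approximate SE uses the large-sample Wishart
form $\sqrt{4R^2(1-R^2)^2(n-2)^2/((n^2-1)(n+3))}$. Nagelkerke's pseudo-R²
normalizes the likelihood-ratio R² by its maximum, with the intercept-only
null fit on the **evaluation** sample (the alternative — the development
sample — would leak the development prevalence into the normalizer). Tjur's
R² is the case/control difference in mean fitted probability. AUC is the
Mann–Whitney statistic with ties at one half, variance by DeLong's
placement-value decomposition. Quantitative traits are evaluated without
quantile normalization (the association scan, by contrast, applies it).

## 4. Heritability via LD score regression

The association scan fits each variant with covariates: gaussian traits via
exact covariate residualization (Frisch–Waugh), identical to the joint fit
at one QR decomposition's cost; binary traits via per-variant logistic
fits, with separation flagged and reported through the covariate-adjusted
score test. LD scores are index-window sums of small-sample-adjusted
$\hat r^2 - (1-\hat r^2)/(n-2)$, self term included; the window is
index-based because the synthetic data has no genetic map. LDSC regresses
$\chi^2_j$ on $N \ell_j / M$ with intercept, weights $1/\max(\ell_j,1)$
updated once with the heteroskedasticity term $1/(2\,\mathrm{fitted}^2)$
(a single iteration; the original tool iterates — with desk-scale m the
second iteration moves estimates well inside one SE). SEs come from a
200-block delete-one jackknife (truncated to m/10 blocks);
$\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549$, the median of $\chi^2_1$.

## 5. The synthetic cohort: what it emulates, what it does not

The generator stands in for biobank individual-level data, which cannot be
redistributed. It emulates the features the pipeline is sensitive to:

* **Ancestry structure**: ancestral allele frequencies uniform on a MAF
  range, per-population drift by the Balding–Nichols Beta model
  (between-population variance $F\,p(1-p)$), clamped by $1/(4n)$ so no
  variant is monomorphic in expectation.
* **LD**: blockwise equicorrelated Gaussian copula on haplotypes.
  Real LD decays with distance; a stationary block model is chosen because
  it has a closed-form/simulable $r^2$ oracle, which the LD-score tests
  exploit. Dosages are sums of two independent haplotypes, so
  Hardy–Weinberg holds by construction (and is tested).
* **Annotation**: multinomial consequence groups, ClinVar classes and an
  allelotype flag, at a coding-enriched genotyping-array-like mix
  (defaults: PTV 0.5%, PAV 15%, ClinVar-pathogenic 0.2%).
* **Phenotypes**: causal variants drawn (optionally enriched among
  medically relevant alleles), standardized-scale effects rescaled so
  $\sum \beta_j^2 = h^2$; the realized genetic score is rescaled to
  variance exactly $h^2$ and noise set to $1 - h^2 - \mathrm{var(covariate\
  score)}$, so the genetic fraction of phenotypic variance is $h^2$ by
  construction (tested to ±0.05). Binary traits threshold the liability at
  its $(1-K)$ Normal quantile; covariate effects act on the liability.
  Default covariate effects (age 0.01/year, sex 0.25) give covariate-only
  models nontrivial but known performance.
* **Sample splitting**: 70/10/20 with floor rounding for train and
  validation and the remainder to test, fixed per seed and shared across
  traits.

It does **not** emulate: admixture or selection, distance-decaying LD, sex
chromosomes, genotyping batch effects, real HLA/CNV dosage structure
(allelotypes are only a boolean flag), case ascertainment, or phenotype
measurement error — so a green test establishes algorithmic correctness and
statistical calibration under the stated generative model, not performance
on real cohorts.

## 6. Pre-registered test bands

Stochastic assertions fix their seeds and their bands before measurement:
Monte-Carlo moments at 3 standard errors; distributional checks at
chi-square/KS p > 0.001; the permuted-phenotype null at ≤ 20% of 20 seeds
below p = 0.05 (mean 5%, 3-sigma binomial band); LDSC recovery within 2
jackknife SEs in ≥ 18/20 replicates. The infinitesimal LDSC simulation
draws per-block copula correlations from U(0, 0.8) because constant LD
would leave the regression slope unidentified — part of that simulation's
stated world, chosen a priori.

## 7. Known limitations

* The engine is in-memory; out-of-core fitting at full biobank scale is out
  of scope.
* Pseudo-R² and $h^2$ are observed-scale; liability-scale conversion is
  deliberately not implemented.
* The gnomAD-frequency and cluster-plot QC filters of array data are
  represented only by an externally supplied blocklist.
* The HWE filter direction follows the universal convention (exclude
  p < 1e-7); the exact test is the plain cumulative two-sided definition,
  no mid-p.
* Elastic-net mixing and cross-validation are not provided (a single
  validation split selects sparsity).
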