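# Synthetic cohort generator: marginal distributions, LD structure,
# heritability calibration, determinism.

test_that("draw_base_frequencies: range, degenerate range, determinism", {
  expect_equal(draw_base_frequencies(3, c(0.3, 0.3), seed = 1), rep(0.3, 3))
  f <- draw_base_frequencies(1e4, c(0.05, 0.5), seed = 2)
  se <- (0.5 - 0.05) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(f) - 0.275), 3 * se)
  expect_true(all(f >= 0.05 & f <= 0.5))
  expect_identical(f, draw_base_frequencies(1e4, c(0.05, 0.5), seed = 2))
  expect_error(draw_base_frequencies(3, c(0, 0.5), 1), "maf_range")
  expect_error(draw_base_frequencies(3, c(0.1, 0.6), 1), "maf_range")
})

test_that("drift_frequencies follows the Balding-Nichols moments", {
  p <- rep(0.3, 1e5)
  expect_identical(drift_frequencies(p, 0, seed = 1), p)
  q <- drift_frequencies(p, 0.1, seed = 1)
  expect_equal(var(q), 0.1 * 0.3 * 0.7, tolerance = 0.05)
  q5 <- drift_frequencies(rep(0.5, 1e5), 0.1, seed = 2)
  se <- sd(q5) / sqrt(1e5)
  expect_lt(abs(mean(q5) - 0.5), 3 * se)
  expect_error(drift_frequencies(p, 1, seed = 1), "fst")
})

test_that("simulate_genotypes: HWE mean, independence, LD oracle", {
  # no LD: near-zero pairwise correlation
  G0 <- simulate_genotypes(rep(0.3, 6), 5000, ld_block_size = 3, ld_rho = 0,
                           seed = 3)
  cors <- cor(G0)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  # HWE mean dosage 2p
  G1 <- simulate_genotypes(rep(0.5, 5), 1e4, 5, 0.2, seed = 4)
  se <- sqrt(0.5 / 1e4)  # var of dosage at p=.5 is 1/2
  expect_true(all(abs(colMeans(G1) - 1) < 3 * se))
  # LD oracle: brute-force haplotype simulation of the same copula
  G2 <- simulate_genotypes(rep(0.5, 2), 1e4, 2, 0.8, seed = 5)
  r2_obs <- cor(G2[, 1], G2[, 2])^2
  set.seed(99)
  nh <- 1e6
  u <- rnorm(nh)
  z1 <- sqrt(0.8) * u + sqrt(0.2) * rnorm(nh)
  z2 <- sqrt(0.8) * u + sqrt(0.2) * rnorm(nh)
  h1 <- z1 < qnorm(0.5)
  h2 <- z2 < qnorm(0.5)
  r2_oracle <- cor(h1, h2)^2  # genotype r2 equals haplotype r2 (iid sum)
  expect_equal(r2_obs, r2_oracle, tolerance = 0.02)
})

test_that("simulate_annotations: proportions, degenerate case, determinism", {
  a1 <- simulate_annotations(50, list(consequence = c(Others = 1)), seed = 1)
  expect_true(all(a1$consequence_group == "Others"))
  expect_true(all(a1$penalty_factor == 1))
  m <- 1e5
  a2 <- simulate_annotations(m, list(consequence = c(PTV = 0.01, Others = 0.99)),
                             seed = 2)
  expect_lt(abs(sum(a2$consequence_group == "PTV") - 1000),
            3 * sqrt(m * 0.01 * 0.99))
  expect_identical(a2, simulate_annotations(
    m, list(consequence = c(PTV = 0.01, Others = 0.99)), seed = 2))
})

test_that("simulate_effects: null heritability, scaling, causal uniformity", {
  ann <- simulate_annotations(20, seed = 7)
  t0 <- simulate_effects(ann, 5, 1, h2_true = 0, seed = 1)
  expect_true(all(t0$beta_true == 0))
  expect_equal(sum(t0$causal_mask), 5)
  # causal set uniform when enrichment = 1: chi-square GOF over 200 replicates
  counts <- numeric(20)
  for (r in 1:200) {
    tr <- simulate_effects(ann, 5, 1, 0.5, seed = 1000 + r)
    counts <- counts + tr$causal_mask
  }
  gof <- sum((counts - 50)^2 / 50)
  expect_gt(pchisq(gof, df = 19, lower.tail = FALSE), 0.001)
  # variance calibration: n_causal = m, independent variants
  m <- 50
  ann2 <- simulate_annotations(m, seed = 8)
  tr <- simulate_effects(ann2, m, 1, 0.4, seed = 9)
  G <- simulate_genotypes(rep(0.5, m), 1e4, 1, 0, seed = 10)
  score <- drop(std_cols(G) %*% tr$beta_true)
  expect_equal(var(score), 0.4, tolerance = 0.04)  # within 10%
})

test_that("simulate_covariates: array fraction, single row, determinism", {
  cv <- simulate_covariates(1e5, seed = 1)
  expect_lt(abs(mean(cv$array) - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))
  expect_identical(names(simulate_covariates(1, 2)),
                   c("age", "sex", "array", paste0("PC", 1:10)))
  expect_identical(cv, simulate_covariates(1e5, seed = 1))
})

test_that("simulate_phenotype: null, prevalence, heritability construction", {
  set.seed(11)
  m <- 50
  n <- 2000
  ann <- simulate_annotations(m, seed = 11)
  G <- simulate_genotypes(runif(m, 0.2, 0.5), n, 5, 0.2, seed = 12)
  cv <- simulate_covariates(n, seed = 13)
  tr0 <- simulate_effects(ann, m, 1, 0, seed = 14)
  y0 <- simulate_phenotype(G, tr0, cv, c(age = 0), "gaussian", 0, seed = 15)
  expect_true(all(abs(cor(y0, G[, 1:10])) < 4 / sqrt(n)))
  # binomial prevalence
  trb <- simulate_effects(ann, m, 1, 0.3, seed = 16)
  Gb <- simulate_genotypes(rep(0.3, m), 1e5, 5, 0.2, seed = 17)
  cvb <- simulate_covariates(1e5, seed = 18)
  yb <- simulate_phenotype(Gb, trb, cvb, c(age = 0.01, sex = 0.25), "binomial",
                           0.3, prevalence_K = 0.1, seed = 19)
  expect_lt(abs(mean(yb) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  # gaussian heritability: R2 of the true genetic score on y ~ h2
  m2 <- 200
  ann2 <- simulate_annotations(m2, seed = 20)
  tr2 <- simulate_effects(ann2, m2, 1, 0.5, seed = 21)
  G2 <- simulate_genotypes(runif(m2, 0.1, 0.5), 1e4, 10, 0.3, seed = 22)
  cv2 <- simulate_covariates(1e4, seed = 23)
  y2 <- simulate_phenotype(G2, tr2, cv2, c(age = 0.01, sex = 0.25), "gaussian",
                           0.5, seed = 24)
  gs <- drop(std_cols(G2) %*% tr2$beta_true)
  expect_equal(summary(lm(y2 ~ gs))$r.squared, 0.5, tolerance = 0.05)
  # heritability calibration invariant: var share of the genetic component
  expect_lt(abs(var(gs * sqrt(0.5 / var(gs))) / var(y2) - 0.5), 0.05)
})

test_that("split_samples: exact sizes, paper-scale rounding, partition", {
  s <- split_samples(10, seed = 1)
  expect_equal(as.vector(table(s)), c(7, 1, 2))
  big <- table(split_samples(337129, c(0.7, 0.1, 0.2), seed = 2))
  expect_true(all(abs(as.vector(big) - c(235990, 33713, 67426)) <= 1))
  s2 <- split_samples(101, c(0.5, 0.25, 0.25), seed = 3)
  expect_equal(length(s2), 101)
  expect_false(anyNA(s2))
  expect_identical(s2, split_samples(101, c(0.5, 0.25, 0.25), seed = 3))
})

test_that("genotypes satisfy HWE at Fst=0, ld_rho=0; drift is calibrated", {
  m <- 1e4
  p <- draw_base_frequencies(m, c(0.05, 0.5), seed = 30)
  G <- simulate_genotypes(p, 500, ld_block_size = 1, ld_rho = 0, seed = 31)
  pvals <- vapply(seq_len(m), function(j) {
    g <- G[, j]
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  expect_gte(mean(pvals > 1e-7), 0.999)
  # drift calibration: empirical variance of drifted frequencies ~ F p (1-p)
  q <- drift_frequencies(rep(0.25, m), 0.15, seed = 32)
  expect_equal(var(q), 0.15 * 0.25 * 0.75, tolerance = 0.1)
})

test_that("simulate_cohort is deterministic and internally consistent", {
  cfg <- sim_config(n_per_population = c(WB = 150, AF = 50),
                    fst_per_population = c(WB = 0, AF = 0.1),
                    m_variants = 60, n_causal = 8, h2_true = 0.4, seed = 77)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch1$G, ch2$G)
  expect_identical(ch1$y, ch2$y)
  expect_equal(as.vector(table(ch1$population)), c(150, 50))
  expect_true(all(ch1$truth$beta_true[!ch1$truth$causal_mask] == 0))
  expect_equal(nrow(ch1$annotation), ncol(ch1$G))
})
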