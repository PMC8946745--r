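# PRS computation and evaluation metrics against brute-force / closed-form
# oracles.

make_model <- function(weights, freq = NULL, alleles = NULL,
                       family = "gaussian") {
  ids <- names(weights)
  structure(list(weights = weights,
                 alleles = alleles %||% setNames(rep(NA_character_, length(ids)), ids),
                 covariate_coef = c(`(Intercept)` = 0),
                 lambda = 0.1, family = family,
                 freq = freq %||% setNames(rep(0.25, length(ids)), ids)),
            class = "prs_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("compute_prs: trivial cases and brute-force oracle", {
  G <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "v1"))
  expect_equal(compute_prs(G, make_model(c(v1 = 0))), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(compute_prs(G, make_model(c(v1 = 0.5))), c(0, 0.5, 1.0),
               ignore_attr = TRUE)
  # 20-variant random model vs naive double loop
  set.seed(21)
  n <- 40
  G20 <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
                dimnames = list(NULL, sprintf("v%02d", 1:20)))
  w <- setNames(rnorm(20), colnames(G20))
  oracle <- numeric(n)
  for (i in 1:n) for (j in 1:20) oracle[i] <- oracle[i] + G20[i, j] * w[j]
  expect_equal(compute_prs(G20, make_model(w)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("compute_prs imputes missing dosage and handles allele flips", {
  model <- make_model(c(v1 = 1, v2 = 1), freq = c(v1 = 0.3, v2 = 0.4),
                      alleles = c(v1 = "A", v2 = "C"))
  G <- matrix(c(NA, 2, 1, 0), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  tgt <- data.frame(variant_id = c("v1", "v2"), a1 = c("A", "G"),
                    a2 = c("G", "C"))
  # v1 oriented; v2's counted allele C is the target's a2 -> reflect 2 - d
  s <- compute_prs(G, model, alleles = tgt)
  expect_equal(unname(s[1]), 2 * 0.3 + (2 - 1))
  expect_equal(unname(s[2]), 2 + (2 - 0))
  # unresolvable alleles are skipped with a count
  tgt2 <- data.frame(variant_id = c("v1", "v2"), a1 = c("T", "C"),
                     a2 = c("G", "G"))
  expect_message(s2 <- compute_prs(G, model, alleles = tgt2), "skipped 1")
  expect_equal(attr(s2, "n_skipped"), 1L)
  # model variant absent from target contributes its imputed term
  G1 <- G[, "v2", drop = FALSE]
  s3 <- compute_prs(G1, model)
  expect_equal(unname(s3), 2 * 0.3 + c(1, 0), ignore_attr = TRUE)
})

test_that("fit_covariate_model: exact fit, constant columns, recovery", {
  set.seed(22)
  n <- 500
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                     array = rep(1, n))
  y <- 0.5 * covs$age
  expect_message(cm <- fit_covariate_model(covs, y, "gaussian"), "constant")
  pred <- predict(cm, covs[, c("age", "sex")])
  expect_equal(cor(pred, y)^2, 1, tolerance = 1e-12)
  # y independent of covariates -> R2 ~ 0 out of sample
  y2 <- rnorm(n)
  cm2 <- fit_covariate_model(covs[, 1:2], y2, "gaussian")
  new <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  expect_lt(cor(predict(cm2, new), rnorm(n))^2, 0.05)
  # binomial coefficient recovery within 3 SE
  n2 <- 20000
  cv <- data.frame(age = rnorm(n2), sex = rbinom(n2, 1, 0.5))
  eta <- -0.5 + 0.3 * cv$age + 0.6 * cv$sex
  yb <- rbinom(n2, 1, plogis(eta))
  cmb <- fit_covariate_model(cv, yb, "binomial")
  fit <- glm(yb ~ age + sex, data = cv, family = binomial())
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(cmb$coefficients["age"] - 0.3), 3 * se["age"])
  expect_lt(abs(cmb$coefficients["sex"] - 0.6), 3 * se["sex"])
})

test_that("fit_full_model: degenerate PRS, perfect fit, null calibration", {
  set.seed(23)
  n <- 200
  y <- rnorm(n)
  cs <- rnorm(n)
  out <- fit_full_model(cs, rep(0, n), y, "gaussian")
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
  prs <- rnorm(n)
  out2 <- fit_full_model(cs, prs, prs, "gaussian")
  expect_lt(out2$p_value, 1e-300)
  # permuted PRS -> uniform p-values (KS)
  pvals <- replicate(1000, {
    fit_full_model(cs, sample(prs), y, "gaussian")$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("nagelkerke_r2 and tjur_r2 match closed forms", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(log(0.5) * 100, 0, 100), 1)  # perfect prediction
  # hand computation
  expect_equal(nagelkerke_r2(-69.31, -50, 100),
               (1 - exp((2 / 100) * (-19.31))) / (1 - exp((2 / 100) * (-69.31))))
  set.seed(24)
  p <- runif(50)
  lab <- rbinom(50, 1, 0.5)
  expect_equal(tjur_r2(p, lab), mean(p[lab == 1]) - mean(p[lab == 0]))
  expect_equal(tjur_r2(rep(0.3, 50), lab), 0)
  expect_equal(tjur_r2(lab, lab), 1)
})

test_that("AUC with DeLong CI matches brute-force pairs and jackknife", {
  set.seed(25)
  n <- 30
  scores <- rnorm(n)
  labels <- rbinom(n, 1, 0.5)
  a <- auc_with_delong_ci(scores, labels)
  # exhaustive pairwise concordance
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  conc <- 0
  for (x in cases) for (y in controls)
    conc <- conc + (x > y) + 0.5 * (x == y)
  expect_equal(a$auc, conc / (length(cases) * length(controls)))
  # jackknife variance oracle within 10%
  jk <- vapply(seq_len(n), function(i) {
    s <- scores[-i]; l <- labels[-i]
    r <- rank(s)
    n1 <- sum(l == 1); n0 <- sum(l == 0)
    (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  v_jk <- (n - 1) / n * sum((jk - mean(jk))^2)
  expect_equal(a$se^2, v_jk, tolerance = 0.1)
  # trivial cases
  expect_equal(auc_with_delong_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(26)
  big <- auc_with_delong_ci(rnorm(1e4), rbinom(1e4, 1, 0.3))
  expect_true(big$ci[1] <= 0.5 && 0.5 <= big$ci[2])
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(27)
  s <- rnorm(200)
  l <- rbinom(200, 1, plogis(s))
  a0 <- auc_with_delong_ci(s, l)$auc
  expect_equal(auc_with_delong_ci(exp(s), l)$auc, a0)
  expect_equal(auc_with_delong_ci(qlogis(plogis(s)), l)$auc, a0)
})

test_that("r2_with_se matches the approximate-SE formula", {
  x <- c(1, 2, 3, 4)
  r <- r2_with_se(x, x)
  expect_equal(r$r2, 1)
  expect_equal(r$se, 0)
  set.seed(28)
  big <- r2_with_se(rnorm(1e5), rnorm(1e5))
  expect_lt(big$r2, 1e-3)
  # direct formula arithmetic at R2 = 0.25, n = 101
  n <- 101; r2 <- 0.25
  se_expected <- sqrt(4 * r2 * (1 - r2)^2 * (n - 2)^2 / ((n^2 - 1) * (n + 3)))
  set.seed(29)
  # construct data with exactly this R2: y = x + noise scaled by bisection
  x <- rnorm(n)
  z <- residuals(lm(rnorm(n) ~ x))
  z <- z / sd(z) * sd(x) * sqrt(3)  # var ratio 3:1 -> R2 = 1/4
  y <- x + z
  got <- r2_with_se(x, y)
  expect_equal(got$r2, 0.25, tolerance = 1e-10)
  expect_equal(got$se, se_expected, tolerance = 1e-10)
})

test_that("incremental_performance and the significance rule", {
  f <- list(trait = "t", population = "test", metric = "NagelkerkeR2",
            value = 0.149)
  c0 <- list(trait = "t", population = "test", metric = "NagelkerkeR2",
             value = 0.006)
  expect_equal(incremental_performance(f, c0), 0.143)
  expect_equal(incremental_performance(f, f), 0)
  c_bad <- c0; c_bad$metric <- "R2"
  expect_error(incremental_performance(f, c_bad), "metric")
  expect_true(is_significant(2.4e-5))
  expect_false(is_significant(2.5e-5))     # strict inequality
  expect_true(is_significant(0.049, n_tests = 1))
  expect_false(is_significant(NA))
})

test_that("evaluate_models produces coherent long-format rows", {
  set.seed(30)
  n <- 1000
  prs <- rnorm(n)
  cs <- rnorm(n)
  y <- prs + 0.5 * cs + rnorm(n)
  ev <- evaluate_models("t1", "test", prs, cs, y, "gaussian")
  expect_setequal(ev$model_type, c("genotype_only", "covariate_only", "full"))
  expect_true(all(ev$ci_low <= ev$value & ev$value <= ev$ci_high))
  expect_true(ev$value[ev$model_type == "full"] >=
                ev$value[ev$model_type == "covariate_only"])
  yb <- rbinom(n, 1, plogis(prs))
  evb <- evaluate_models("t1", "test", prs, cs, yb, "binomial")
  expect_setequal(evb$metric, c("NagelkerkeR2", "TjurR2", "AUC"))
  expect_equal(nrow(evb), 9)
  auc_rows <- evb[evb$metric == "AUC", ]
  expect_true(all(auc_rows$value >= 0 & auc_rows$value <= 1))
  # order-invariance over samples
  perm <- sample(n)
  ev2 <- evaluate_models("t1", "test", prs[perm], cs[perm], y[perm], "gaussian")
  expect_equal(ev$value, ev2$value, tolerance = 1e-12)
})
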