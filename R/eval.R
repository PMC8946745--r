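# Held-out evaluation of PRS models: score computation, covariate-only and
# full models, performance metrics with confidence intervals, incremental
# performance, and the phenome-wide significance rule.

#' Compute polygenic risk scores
#'
#' `score_i = sum_j dosage_ij * weight_j`, with missing dosages imputed as
#' twice the model's training allele frequency and model variants absent from
#' the target contributing their frequency-imputed term. When target allele
#' metadata is supplied, variants whose counted allele is the target's other
#' allele are reflected (`2 - dosage`); variants whose alleles cannot be
#' reconciled are skipped with a logged count.
#'
#' @param G_target n x m dosage matrix, columns named by variant id.
#' @param model a `prs_model` from [refit_final()] or [read_score_file()].
#' @param alleles optional data.frame (variant_id, a1, a2) for the target
#'   data, used for allele-orientation checks.
#' @return numeric score per sample; attribute `n_skipped` counts variants
#'   dropped for unresolvable alleles.
#' @export
compute_prs <- function(G_target, model, alleles = NULL) {
  n <- nrow(G_target)
  score <- numeric(n)
  skipped <- 0L
  tgt_a1 <- tgt_a2 <- NULL
  if (!is.null(alleles)) {
    tgt_a1 <- setNames(alleles$a1, alleles$variant_id)
    tgt_a2 <- setNames(alleles$a2, alleles$variant_id)
  }
  for (v in names(model$weights)) {
    w <- model$weights[[v]]
    imputed <- 2 * model$freq[[v]]
    if (!v %in% colnames(G_target)) {
      score <- score + w * imputed
      next
    }
    d <- G_target[, v]
    if (!is.null(tgt_a1) && !is.na(model$alleles[[v]])) {
      ma <- model$alleles[[v]]
      if (identical(unname(tgt_a1[v]), ma)) {
        # orientation matches
      } else if (identical(unname(tgt_a2[v]), ma)) {
        d <- 2 - d
      } else {
        skipped <- skipped + 1L
        next
      }
    }
    d[is.na(d)] <- imputed
    score <- score + w * d
  }
  if (skipped > 0)
    message(sprintf("compute_prs: skipped %d variant(s) with unresolvable alleles",
                    skipped))
  attr(score, "n_skipped") <- skipped
  score
}

#' Fit the covariate-only model
#'
#' Fits `trait ~ age + sex + array + PCs` (whatever columns are supplied) on
#' the score development set and returns an object whose [predict()] method
#' gives the covariate-only linear predictor for new samples. Columns that
#' are constant (e.g. the array indicator in a population genotyped on one
#' array) are dropped, as are aliased columns in a rank-deficient design.
#'
#' @param covariates data.frame of covariates (development samples).
#' @param y response on the same samples.
#' @param family `"gaussian"` or `"binomial"`.
#' @return object of class `covariate_model`.
#' @export
fit_covariate_model <- function(covariates, y, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(x) length(unique(x)) == 1, TRUE)
  if (any(const)) {
    message(sprintf("dropping constant covariate(s): %s",
                    paste(names(covariates)[const], collapse = ", ")))
    covariates <- covariates[!const]
  }
  dat <- cbind(.y = y, covariates)
  fit <- glm(.y ~ ., data = dat,
             family = if (family == "gaussian") gaussian() else binomial())
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning(sprintf("dropping aliased covariate column(s): %s",
                    paste(names(cf)[is.na(cf)], collapse = ", ")))
    cf[is.na(cf)] <- 0
  }
  structure(list(coefficients = cf, family = family,
                 terms = names(covariates)), class = "covariate_model")
}

#' @export
predict.covariate_model <- function(object, newdata, ...) {
  X <- model.matrix(~., data = as.data.frame(newdata)[,
         intersect(object$terms, names(newdata)), drop = FALSE])
  cf <- object$coefficients[colnames(X)]
  cf[is.na(cf)] <- 0
  drop(X %*% cf)
}

#' Fit the full model `trait ~ 1 + covariate score + PRS`
#'
#' The intercept absorbs differences in trait mean (or case prevalence)
#' between the development and target populations. The two-sided Wald p-value
#' for the PRS term measures the significance of the PRS. A PRS column with
#' zero variance is flagged degenerate and reported non-significant.
#'
#' @param covariate_score covariate-only linear predictor on the target set.
#' @param prs PRS on the target set.
#' @param y observed trait on the target set.
#' @param family `"gaussian"` or `"binomial"`.
#' @return list: fit (glm), coefficients, p_value (PRS term), degenerate flag.
#' @export
fit_full_model <- function(covariate_score, prs, y,
                           family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (sd(prs) == 0) {
    return(list(fit = NULL, coefficients = NULL, p_value = NA_real_,
                degenerate = TRUE))
  }
  dat <- data.frame(.y = y, cov_score = covariate_score, PRS = prs)
  fit <- glm(.y ~ cov_score + PRS, data = dat,
             family = if (family == "gaussian") gaussian() else binomial())
  sm <- summary(fit)$coefficients
  pv <- if ("PRS" %in% rownames(sm)) {
    z <- sm["PRS", 1] / sm["PRS", 2]
    if (family == "gaussian") 2 * pt(-abs(z), df = fit$df.residual)
    else 2 * pnorm(-abs(z))
  } else NA_real_
  list(fit = fit, coefficients = coef(fit), p_value = pv,
       degenerate = is.na(pv))
}

#' Nagelkerke (Cragg-Uhler) pseudo-R2
#'
#' `[1 - exp((2/n)(ll_null - ll_model))] / [1 - exp((2/n) ll_null)]` with the
#' intercept-only model as the null.
#'
#' @param loglik_null log-likelihood of the intercept-only fit.
#' @param loglik_model log-likelihood of the model.
#' @param n sample size.
#' @return value in `[0, 1]` (up to floating error).
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  (1 - exp((2 / n) * (loglik_null - loglik_model))) /
    (1 - exp((2 / n) * loglik_null))
}

#' Tjur's coefficient of discrimination
#'
#' Mean fitted probability among cases minus mean fitted probability among
#' controls.
#'
#' @param fitted_probabilities fitted case probabilities.
#' @param labels 0/1 case labels.
#' @return numeric value.
#' @export
tjur_r2 <- function(fitted_probabilities, labels) {
  mean(fitted_probabilities[labels == 1]) -
    mean(fitted_probabilities[labels == 0])
}

# Mann-Whitney AUC with ties counted 1/2; rank-based, O(n log n)
auc_mannwhitney <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with DeLong 95% confidence interval
#'
#' AUC as the Mann-Whitney statistic (ties counted one half); variance from
#' DeLong's structural components (placement values); Wald interval clipped
#' to `[0, 1]`.
#'
#' @param scores predicted scores.
#' @param labels 0/1 case labels.
#' @return list: auc, se, ci (length 2).
#' @export
auc_with_delong_ci <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  n1 <- length(cases)
  n0 <- length(controls)
  if (n1 == 0 || n0 == 0) stop_config("need both cases and controls")
  auc <- auc_mannwhitney(scores, labels)
  # placement values via midranks (DeLong et al.'s fast formulation)
  all_r <- rank(c(cases, controls), ties.method = "average")
  rc <- rank(cases, ties.method = "average")
  rn <- rank(controls, ties.method = "average")
  v10 <- (all_r[seq_len(n1)] - rc) / n0              # P(X > Y) per case
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - rn) / n1     # per control
  s <- if (n1 > 1) var(v10) / n1 else 0
  s <- s + if (n0 > 1) var(v01) / n0 else 0
  se <- sqrt(s)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(auc = auc, se = se, ci = ci)
}

#' R-squared with approximate standard error
#'
#' Squared Pearson correlation between predicted and observed values, with
#' the large-sample (Wishart) approximation
#' `SE = sqrt(4 R2 (1 - R2)^2 (n-2)^2 / ((n^2 - 1)(n + 3)))` and a Wald 95%
#' interval clipped to `[0, 1]`.
#'
#' @param predicted predicted values.
#' @param observed observed values.
#' @return list: r2, se, ci (length 2).
#' @export
r2_with_se <- function(predicted, observed) {
  n <- length(observed)
  r2 <- if (sd(predicted) == 0 || sd(observed) == 0) 0
        else cor(predicted, observed)^2
  se <- sqrt(4 * r2 * (1 - r2)^2 * (n - 2)^2 / ((n^2 - 1) * (n + 3)))
  ci <- pmin(pmax(r2 + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(r2 = r2, se = se, ci = ci)
}

#' Incremental predictive performance
#'
#' `value(full) - value(covariate_only)` for a pair of evaluation rows
#' matched on trait, population and metric.
#'
#' @param full,covariate_only single-row data.frames (or lists) with fields
#'   trait, population, metric, value.
#' @return numeric difference.
#' @export
incremental_performance <- function(full, covariate_only) {
  for (f in c("trait", "population", "metric"))
    if (!identical(full[[f]], covariate_only[[f]]))
      stop_config("mismatched '%s' between full and covariate-only results", f)
  full$value - covariate_only$value
}

#' Phenome-wide significance rule
#'
#' Bonferroni: significant iff `p < 0.05 / n_tests` (strict inequality);
#' the default 2,000 tests gives the 2.5e-5 threshold.
#'
#' @param p_value p-value(s).
#' @param n_tests number of tests corrected for.
#' @return logical; NA p-values are non-significant.
#' @export
is_significant <- function(p_value, n_tests = 2000) {
  !is.na(p_value) & p_value < 0.05 / n_tests
}

#' Evaluate genotype-only, covariate-only and full models on a target set
#'
#' Produces the long-format evaluation rows for one (trait, population) pair:
#' R2 (gaussian) or Nagelkerke/Tjur/AUC (binomial) per model type, 95%
#' confidence intervals where defined, and the full-model PRS-term p-value.
#' The intercept-only null for pseudo-R2 is fit on the evaluation sample.
#'
#' @param trait,population identifying labels.
#' @param prs PRS on the target samples.
#' @param covariate_score covariate-only linear predictor on the target samples.
#' @param y observed trait.
#' @param family `"gaussian"` or `"binomial"`.
#' @return data.frame with columns trait, population, model_type, metric,
#'   value, ci_low, ci_high, p_value.
#' @export
evaluate_models <- function(trait, population, prs, covariate_score, y,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  full <- fit_full_model(covariate_score, prs, y, family)
  p_full <- full$p_value
  row <- function(model_type, metric, value, ci = c(NA, NA), p = NA)
    data.frame(trait = trait, population = population, model_type = model_type,
               metric = metric, value = value, ci_low = ci[1], ci_high = ci[2],
               p_value = p, stringsAsFactors = FALSE)
  out <- list()
  if (family == "gaussian") {
    rg <- r2_with_se(prs, y)
    rc <- r2_with_se(covariate_score, y)
    rf <- if (full$degenerate) rc
          else r2_with_se(predict(full$fit, type = "response"), y)
    out <- list(row("genotype_only", "R2", rg$r2, rg$ci),
                row("covariate_only", "R2", rc$r2, rc$ci),
                row("full", "R2", rf$r2, rf$ci, p_full))
  } else {
    n <- length(y)
    ll0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
    nag <- function(fit) nagelkerke_r2(ll0, as.numeric(logLik(fit)), n)
    g_fit <- glm(y ~ prs, family = binomial())
    c_fit <- glm(y ~ covariate_score, family = binomial())
    f_fit <- if (full$degenerate) c_fit else full$fit
    for (mt in c("genotype_only", "covariate_only", "full")) {
      fit <- switch(mt, genotype_only = g_fit, covariate_only = c_fit,
                    full = f_fit)
      p_hat <- predict(fit, type = "response")
      scr <- switch(mt, genotype_only = prs, covariate_only = covariate_score,
                    full = predict(fit))
      a <- auc_with_delong_ci(scr, y)
      pp <- if (mt == "full") p_full else NA
      out <- c(out, list(row(mt, "NagelkerkeR2", nag(fit), p = pp),
                         row(mt, "TjurR2", tjur_r2(p_hat, y)),
                         row(mt, "AUC", a$auc, a$ci)))
    }
  }
  do.call(rbind, out)
}
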