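# Batch-screening iterative lasso (BASIL-style) with per-variant penalty
# factors and unpenalized covariates.
#
# The engine solves, over a decreasing lambda grid,
#   min_beta (1/2n) * deviance(y, eta) + lambda * sum_j w_j |beta_j|
# (gaussian: squared error; binomial: logistic deviance via IRLS around the
# log-likelihood), where only variant columns are penalized. Rather than ever
# forming the full design inside the solver, variants are screened into an
# active set in batches by gradient magnitude scaled by 1/w_j, and every
# reported solution is certified by a KKT check against ALL variants.

#' Fitting configuration for the BASIL engine
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param n_lambda number of lambda values on the geometric grid.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param batch_size newly screened variants added per iteration.
#' @param cd_tolerance max absolute coefficient change per coordinate-descent
#'   cycle, on the standardized scale.
#' @param max_cd_iter maximum coordinate-descent cycles per solve.
#' @param early_stop_patience consecutive non-improving lambdas on the
#'   validation set before the path stops.
#' @param kkt_tol additive slack in the KKT violation check.
#' @param seed integer seed (the fit itself is deterministic; kept for
#'   provenance).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(family = c("gaussian", "binomial"), n_lambda = 100,
                       lambda_min_ratio = 0.01, batch_size = 1000,
                       cd_tolerance = 1e-7, max_cd_iter = 100000,
                       early_stop_patience = 10, kkt_tol = 1e-7, seed = 1L) {
  family <- match.arg(family)
  if (n_lambda < 2) stop_config("n_lambda must be >= 2")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  structure(list(family = family, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, batch_size = batch_size,
                 cd_tolerance = cd_tolerance, max_cd_iter = max_cd_iter,
                 early_stop_patience = early_stop_patience, kkt_tol = kkt_tol,
                 seed = as.integer(seed)), class = "fit_config")
}

#' Lambda grid from screening gradients
#'
#' `lambda_max` is the largest penalty at which all penalized coefficients are
#' zero: `max_j |g_j| / w_j` over variants with `w_j > 0`, where `g_j` is the
#' gradient `x_j' r / n` of the covariate-only fit's residual with the
#' standardized variant j. A geometric sequence of `n_lambda` values descends
#' to `lambda_max * lambda_min_ratio`.
#'
#' @param gradients per-variant gradients `x_j' r / n`.
#' @param penalty_factors per-variant penalty factors.
#' @param n_lambda grid length.
#' @param lambda_min_ratio ratio of smallest to largest lambda.
#' @return strictly decreasing numeric vector.
#' @export
lambda_grid <- function(gradients, penalty_factors, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
  pen <- penalty_factors > 0
  if (!any(pen)) stop_config("need at least one penalized variant")
  lmax <- max(abs(gradients[pen]) / penalty_factors[pen])
  if (!is.finite(lmax) || lmax <= 0)
    stop_config("degenerate path: all screening gradients are zero")
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Penalized deviance objective (standardized scale), used for step halving
# and the objective-monotonicity property.
penalized_objective <- function(X, y, beta, lambda, pf, family) {
  eta <- drop(X %*% beta)
  loss <- if (family == "gaussian") sum((y - eta)^2) / (2 * length(y))
  else sum(log1p(exp(eta)) - y * eta) / length(y)
  loss + lambda * sum(pf * abs(beta))
}

# IRLS wrapper around the weighted coordinate-descent core for the logistic
# family; step-halving on the penalized objective.
irls_cd <- function(X, y, lambda, pf, beta, cd_tol, max_cd_iter,
                    irls_tol = 1e-10, max_irls = 100) {
  obj <- penalized_objective(X, y, beta, lambda, pf, "binomial")
  for (it in seq_len(max_irls)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    v <- pmax(p * (1 - p), 1e-5)  # weight floor guards near-separation
    z <- eta + (y - p) / v
    fit <- .cd_wls(X, z, v, lambda, pf, beta, cd_tol, max_cd_iter)
    if (!fit$converged)
      stop_config("coordinate descent did not converge within max_cd_iter")
    bn <- fit$beta
    objn <- penalized_objective(X, y, bn, lambda, pf, "binomial")
    h <- 0
    while (objn > obj + 1e-12 && h < 30) {     # step-halving on increase
      bn <- (bn + beta) / 2
      objn <- penalized_objective(X, y, bn, lambda, pf, "binomial")
      h <- h + 1
    }
    delta <- max(abs(bn - beta))
    beta <- bn
    obj <- objn
    if (delta < max(irls_tol, cd_tol)) break
  }
  beta
}

#' Coordinate-descent lasso solve on an active set
#'
#' Minimizes `(1/2n) deviance + lambda * sum_j w_j |beta_j|` over the supplied
#' (already standardized) active variant columns with unpenalized intercept
#' and covariates.
#'
#' @param X_active n x k matrix of standardized variant columns.
#' @param y response (0/1 for binomial).
#' @param lambda penalty strength.
#' @param penalty_factors length-k penalty factors for `X_active` columns.
#' @param covariates optional n x c matrix of unpenalized covariates
#'   (centered; an intercept is always added internally).
#' @param family `"gaussian"` or `"binomial"`.
#' @param warm_start optional coefficient vector (intercept, covariates,
#'   active variants) to start from.
#' @param cd_tolerance,max_cd_iter convergence control.
#' @return named coefficient vector: `(Intercept)`, covariate columns, then
#'   active variant columns.
#' @export
cd_lasso <- function(X_active, y, lambda, penalty_factors, covariates = NULL,
                     family = c("gaussian", "binomial"), warm_start = NULL,
                     cd_tolerance = 1e-7, max_cd_iter = 100000) {
  family <- match.arg(family)
  n <- length(y)
  covariates <- if (is.null(covariates)) matrix(0, n, 0) else as.matrix(covariates)
  X_active <- as.matrix(X_active)
  X <- cbind(`(Intercept)` = 1, covariates, X_active)
  pf <- c(rep(0, 1 + ncol(covariates)), penalty_factors)
  beta <- if (is.null(warm_start)) numeric(ncol(X)) else warm_start
  if (length(beta) != ncol(X)) stop_config("warm_start has wrong length")
  if (family == "gaussian") {
    fit <- .cd_wls(X, y, rep(1, n), lambda, pf, beta, cd_tolerance, max_cd_iter)
    if (!fit$converged)
      stop_config("coordinate descent did not converge within max_cd_iter")
    beta <- fit$beta
  } else {
    beta <- irls_cd(X, y, lambda, pf, beta, cd_tolerance, max_cd_iter)
  }
  setNames(drop(beta), colnames(X))
}

#' KKT violations over the full variant set
#'
#' A variant j with `beta_j = 0` violates the KKT conditions at `lambda` iff
#' `|x_j' r| / n > lambda * w_j` (plus tolerance), where r is the residual
#' (gaussian) or `y - p` working residual (binomial).
#'
#' @param beta per-variant coefficients (length m, zeros for inactive).
#' @param full_X n x m standardized variant matrix.
#' @param residual residual or working residual on the same samples.
#' @param lambda penalty strength.
#' @param penalty_factors per-variant penalty factors.
#' @param tol additive slack.
#' @return integer indices of violating variants, sorted by decreasing
#'   violation magnitude.
#' @export
kkt_violations <- function(beta, full_X, residual, lambda, penalty_factors,
                           tol = 1e-7) {
  g <- drop(crossprod(full_X, residual)) / nrow(full_X)
  excess <- abs(g) - lambda * penalty_factors
  viol <- which(beta == 0 & excess > tol)
  viol[order(-excess[viol], viol)]
}

# -- internal engine ----------------------------------------------------------

# standardize columns with training-row statistics (population sd); NAs are
# mean-imputed from the training allele frequency first.
standardize_geno <- function(G, train) {
  mu <- colMeans(G[train, , drop = FALSE], na.rm = TRUE)
  if (anyNA(G)) {
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  Gc <- sweep(G, 2, mu)
  sdev <- sqrt(colMeans(Gc[train, , drop = FALSE]^2))
  sd_safe <- ifelse(sdev > 0, sdev, 1)
  list(Gs = sweep(Gc, 2, sd_safe, "/"), mu = mu, sdev = sdev)
}

basil_engine <- function(Gs_tr, cov_tr, y_tr, w, lambdas, config,
                         Gs_val = NULL, cov_val = NULL, y_val = NULL) {
  n <- nrow(Gs_tr)
  m <- ncol(Gs_tr)
  ncov <- ncol(cov_tr)
  family <- config$family
  pnames <- c("(Intercept)", colnames(cov_tr), colnames(Gs_tr))
  # degenerate (zero-variance) columns can never enter
  eligible <- apply(Gs_tr, 2, function(x) any(x != 0))
  active <- integer(0)
  beta_var <- numeric(m)
  beta_cov <- cd_lasso(matrix(0, n, 0), y_tr, 0, numeric(0), cov_tr,
                       family, cd_tolerance = config$cd_tolerance,
                       max_cd_iter = config$max_cd_iter)
  eta <- drop(cbind(1, cov_tr) %*% beta_cov)
  resid_of <- function(eta) if (family == "gaussian") y_tr - eta
                            else y_tr - plogis(eta)
  r <- resid_of(eta)

  K <- length(lambdas)
  betas <- vector("list", K)
  covs <- matrix(NA_real_, 1 + ncov, K, dimnames = list(pnames[1:(1 + ncov)], NULL))
  metric <- rep(NA_real_, K)
  active_counts <- integer(K)
  best <- -Inf
  stall <- 0L
  recorded <- 0L
  for (k in seq_len(K)) {
    lam <- lambdas[k]
    # (1) screen: rank zero-coefficient variants by |gradient| / w_j
    g <- drop(crossprod(Gs_tr, r)) / n
    cand <- which(eligible & beta_var == 0 & !(seq_len(m) %in% active))
    if (length(cand)) {
      sc <- abs(g[cand]) / pmax(w[cand], .Machine$double.eps)
      add <- cand[order(-sc, cand)][seq_len(min(config$batch_size, length(cand)))]
      active <- sort(c(active, add))
    }
    active <- sort(union(active, which(eligible & w == 0)))  # never screened out
    # (2) solve over the active set with warm starts, (3) certify KKT on all m
    for (pass in seq_len(50)) {
      warm <- c(beta_cov, beta_var[active])
      coefs <- cd_lasso(Gs_tr[, active, drop = FALSE], y_tr, lam, w[active],
                        cov_tr, family, warm_start = warm,
                        cd_tolerance = config$cd_tolerance,
                        max_cd_iter = config$max_cd_iter)
      beta_cov <- coefs[seq_len(1 + ncov)]
      beta_var[active] <- coefs[-seq_len(1 + ncov)]
      eta <- drop(cbind(1, cov_tr) %*% beta_cov) +
        drop(Gs_tr[, active, drop = FALSE] %*% beta_var[active])
      r <- resid_of(eta)
      viol <- kkt_violations(beta_var, Gs_tr, r, lam, w, tol = config$kkt_tol)
      viol <- viol[eligible[viol]]
      if (!length(viol)) break
      if (pass == 50) stop_config("KKT certification failed at lambda index %d", k)
      active <- sort(c(active, viol))
    }
    betas[[k]] <- beta_var
    covs[, k] <- beta_cov
    active_counts[k] <- sum(beta_var != 0)
    recorded <- k
    if (!is.null(Gs_val)) {
      eta_val <- drop(cbind(1, cov_val) %*% beta_cov) +
        drop(Gs_val[, active, drop = FALSE] %*% beta_var[active])
      metric[k] <- if (family == "gaussian") {
        if (sd(eta_val) == 0 || sd(y_val) == 0) 0 else cor(eta_val, y_val)^2
      } else auc_mannwhitney(eta_val, y_val)
      if (metric[k] > best + 1e-12) { best <- metric[k]; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }
  keep <- seq_len(recorded)
  beta_mat <- do.call(cbind, betas[keep])
  coef_all <- rbind(covs[, keep, drop = FALSE], beta_mat)
  rownames(coef_all) <- pnames
  list(lambdas = lambdas[keep],
       coefficients = methods::as(methods::as(Matrix::Matrix(coef_all, sparse = TRUE),
                                              "generalMatrix"), "CsparseMatrix"),
       active_counts = active_counts[keep],
       validation_metric = metric[keep],
       n_covariates = ncov)
}

#' Fit the sparse PRS path with batch screening
#'
#' Runs the BASIL procedure on the training rows: per lambda, (1) screen the
#' top `batch_size` zero-coefficient variants by penalty-scaled gradient into
#' the active set, (2) solve the active-set lasso with warm starts, (3)
#' certify the solution with a KKT check against all variants, adding any
#' violators and re-solving, then (4) record the validation metric (R2 for
#' gaussian, AUC for binomial). Stops early after `early_stop_patience`
#' non-improving lambdas.
#'
#' @param G n x m dosage matrix (training and validation rows), columns named
#'   by variant id; missing dosages are mean-imputed from training frequencies.
#' @param covariates data.frame or matrix of unpenalized covariates.
#' @param y response vector for all rows of `G`.
#' @param penalty_factors per-variant penalty factors (w_j).
#' @param config a [fit_config()].
#' @param validation integer row indices of the validation set (disjoint from
#'   training; all remaining rows train the model).
#' @return object of class `lasso_path`: lambdas, sparse coefficient matrix
#'   (rows: intercept, covariates, variants), active_counts,
#'   validation_metric, standardization stats, family.
#' @export
basil_fit <- function(G, covariates, y, penalty_factors, config = fit_config(),
                      validation) {
  if (missing(validation) || length(validation) == 0)
    stop_config("validation set is empty")
  n <- nrow(G)
  train <- setdiff(seq_len(n), validation)
  if (length(intersect(train, validation)))
    stop_config("train and validation sets must be disjoint")
  std <- standardize_geno(G, train)
  cov_m <- as.matrix(covariates)
  cov_mu <- colMeans(cov_m[train, , drop = FALSE])
  cov_c <- sweep(cov_m, 2, cov_mu)
  # covariate-only fit on training rows -> screening gradients -> grid
  fam <- config$family
  cov0 <- cd_lasso(matrix(0, length(train), 0), y[train], 0, numeric(0),
                   cov_c[train, , drop = FALSE], fam,
                   cd_tolerance = config$cd_tolerance,
                   max_cd_iter = config$max_cd_iter)
  eta0 <- drop(cbind(1, cov_c[train, , drop = FALSE]) %*% cov0)
  r0 <- if (fam == "gaussian") y[train] - eta0 else y[train] - plogis(eta0)
  g0 <- drop(crossprod(std$Gs[train, , drop = FALSE], r0)) / length(train)
  lambdas <- lambda_grid(g0, penalty_factors, config$n_lambda,
                         config$lambda_min_ratio)
  fit <- basil_engine(std$Gs[train, , drop = FALSE],
                      cov_c[train, , drop = FALSE], y[train],
                      penalty_factors, lambdas, config,
                      Gs_val = std$Gs[validation, , drop = FALSE],
                      cov_val = cov_c[validation, , drop = FALSE],
                      y_val = y[validation])
  structure(c(fit, list(family = fam, mu = std$mu, sdev = std$sdev,
                        cov_mu = cov_mu, penalty_factors = penalty_factors,
                        config = config)),
            class = "lasso_path")
}

#' Select the sparsity level on the validation set
#'
#' Argmax of the per-lambda validation metric; ties break toward the larger
#' lambda (the sparser model).
#'
#' @param path a `lasso_path`.
#' @return integer index into `path$lambdas`.
#' @export
select_lambda <- function(path) {
  m <- path$validation_metric
  if (all(is.na(m))) stop_config("path has no validation metric")
  which.max(m)  # first maximum = largest lambda among ties
}

#' Refit the final PRS model on the combined development set
#'
#' Runs a fresh BASIL fit on the combined training + validation samples along
#' a geometric grid ending exactly at the chosen lambda VALUE (warm-started
#' from lambda_max for stability), then de-standardizes coefficients to
#' per-dosage effect-allele weights.
#'
#' @param G dosage matrix over the combined development samples.
#' @param covariates covariates for the same samples.
#' @param y response for the same samples.
#' @param lambda_value the penalty strength endorsed by the validation set.
#' @param penalty_factors per-variant penalty factors.
#' @param config a [fit_config()].
#' @param alleles optional data.frame (variant_id, a1, a2) recording the
#'   effect allele for each variant.
#' @return object of class `prs_model`: `weights` (named per-dosage effect
#'   sizes for selected variants), `alleles`, `covariate_coef` (original
#'   scale, incl. intercept), `lambda`, `family`, `freq` (training allele
#'   frequency of the counted allele, for missing-dosage imputation).
#' @export
refit_final <- function(G, covariates, y, lambda_value, penalty_factors,
                        config = fit_config(), alleles = NULL) {
  n <- nrow(G)
  std <- standardize_geno(G, seq_len(n))
  cov_m <- as.matrix(covariates)
  cov_mu <- colMeans(cov_m)
  cov_c <- sweep(cov_m, 2, cov_mu)
  fam <- config$family
  cov0 <- cd_lasso(matrix(0, n, 0), y, 0, numeric(0), cov_c, fam,
                   cd_tolerance = config$cd_tolerance,
                   max_cd_iter = config$max_cd_iter)
  eta0 <- drop(cbind(1, cov_c) %*% cov0)
  r0 <- if (fam == "gaussian") y - eta0 else y - plogis(eta0)
  g0 <- drop(crossprod(std$Gs, r0)) / n
  pen <- penalty_factors > 0
  lmax <- max(abs(g0[pen]) / penalty_factors[pen])
  lambdas <- if (lambda_value >= lmax) lambda_value else {
    step <- log(1 / config$lambda_min_ratio) / (config$n_lambda - 1)
    len <- max(2, ceiling(log(lmax / lambda_value) / step) + 1)
    c(exp(seq(log(lmax), log(lambda_value), length.out = len))[-len], lambda_value)
  }
  fit <- basil_engine(std$Gs, cov_c, y, penalty_factors, lambdas, config)
  k <- length(fit$lambdas)
  coefs <- fit$coefficients[, k]
  ncov <- fit$n_covariates
  beta_std <- coefs[-seq_len(1 + ncov)]
  sel <- which(beta_std != 0)
  weights <- beta_std[sel] / std$sdev[sel]
  names(weights) <- colnames(G)[sel]
  cov_coef <- coefs[seq_len(1 + ncov)]
  # fold centering back into the intercept so coefficients apply to raw inputs
  cov_coef[1] <- cov_coef[1] - sum(cov_coef[-1] * cov_mu) -
    sum(weights * std$mu[sel])
  a1 <- if (!is.null(alleles)) {
    setNames(alleles$a1, alleles$variant_id)[names(weights)]
  } else setNames(rep(NA_character_, length(weights)), names(weights))
  structure(list(weights = weights, alleles = a1, covariate_coef = cov_coef,
                 lambda = lambda_value, family = fam,
                 freq = setNames(std$mu[sel] / 2, names(weights))),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("Sparse PRS model (%s): %d variants, lambda = %.4g\n",
              x$family, length(x$weights), x$lambda))
  invisible(x)
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("BASIL lasso path (%s): %d lambdas, %d-%d active variants\n",
              x$family, length(x$lambdas), min(x$active_counts),
              max(x$active_counts)))
  invisible(x)
}
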