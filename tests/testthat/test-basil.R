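# BASIL engine: grid construction, coordinate descent closed forms and
# numerical oracle, KKT checks, screening soundness, penalty prioritization,
# lambda selection and the final refit.

test_that("lambda_grid: closed form, penalty scaling, geometric spacing", {
  expect_equal(lambda_grid(0.4, 1, n_lambda = 2, lambda_min_ratio = 0.5)[1], 0.4)
  expect_equal(lambda_grid(0.4, 0.5, n_lambda = 2, lambda_min_ratio = 0.5)[1], 0.8)
  g <- lambda_grid(c(0.4, 0.1), c(1, 1), n_lambda = 3, lambda_min_ratio = 0.01)
  expect_equal(g, c(0.4, 0.04, 0.004))
  expect_error(lambda_grid(c(0, 0), c(1, 1), 3, 0.01), "degenerate")
})

test_that("cd_lasso univariate closed forms", {
  set.seed(1)
  n <- 100
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))   # orthogonal to x and the intercept
  y <- 0.5 * x + e
  y <- y - mean(y)
  # beta = soft_threshold(x'y/n, lambda * w)
  b1 <- cd_lasso(matrix(x), y, 0.2, 1, family = "gaussian", cd_tolerance = 1e-12)
  expect_equal(unname(b1[2]), 0.3, tolerance = 1e-9)
  b2 <- cd_lasso(matrix(x), y, 0.2, 0.5, family = "gaussian", cd_tolerance = 1e-12)
  expect_equal(unname(b2[2]), 0.4, tolerance = 1e-9)
})

test_that("cd_lasso matches an independent proximal-gradient oracle", {
  # ISTA with small fixed step, run long: an independent minimizer of the
  # same objective (gaussian)
  set.seed(2)
  n <- 50; m <- 8
  X <- std_cols(matrix(rnorm(n * m), n, m))
  y <- drop(X[, 1] * 0.7 - X[, 2] * 0.4 + rnorm(n))
  w <- c(0.5, 1, 1, 0.75, 1, 0.5, 1, 1)
  lam <- 0.15
  obj <- function(b0, b) sum((y - b0 - X %*% b)^2) / (2 * n) + lam * sum(w * abs(b))
  ista <- function() {
    b <- rep(0, m); b0 <- 0
    step <- 1 / max(eigen(crossprod(X) / n)$values)
    for (i in 1:20000) {
      r <- y - b0 - drop(X %*% b)
      b0 <- b0 + mean(r)
      g <- -drop(crossprod(X, r)) / n
      u <- b - step * g
      b <- sign(u) * pmax(abs(u) - step * lam * w, 0)
    }
    list(b0 = b0, b = b)
  }
  o <- ista()
  mine <- cd_lasso(X, y, lam, w, family = "gaussian", cd_tolerance = 1e-12)
  expect_lt(abs(obj(mine[1], mine[-1]) - obj(o$b0, o$b)), 1e-5)
  expect_equal(unname(mine[-1]), o$b, tolerance = 1e-4)
})

test_that("kkt_violations agrees with dense recomputation", {
  set.seed(3)
  n <- 120; m <- 40
  X <- std_cols(matrix(rnorm(n * m), n, m))
  y <- drop(X[, 1] + rnorm(n))
  w <- rep(c(0.5, 1), m / 2)
  g <- drop(crossprod(X, y - mean(y))) / n
  lam_max <- max(abs(g) / w)
  expect_length(kkt_violations(rep(0, m), X, y - mean(y), lam_max * 1.0001, w), 0)
  # at a smaller lambda, the package must report exactly the dense violators
  lam <- 0.4 * lam_max
  got <- kkt_violations(rep(0, m), X, y - mean(y), lam, w)
  dense <- which(abs(g) - lam * w > 1e-7)
  expect_setequal(got, dense)
  # sorted by violation magnitude
  expect_equal(got, dense[order(-(abs(g) - lam * w)[dense], dense)])
  # constructed single violator
  b <- rep(0, 3)
  X3 <- std_cols(matrix(rnorm(n * 3), n, 3))
  r3 <- X3[, 2] * 1.5 * lam  # |x2'r|/n ~ 1.5 lam
  expect_true(2 %in% kkt_violations(b, X3, r3, lam, rep(1, 3)))
})

test_that("basil_fit equals the dense-lasso oracle (screening soundness)", {
  for (fam in c("gaussian", "binomial")) {
    pr <- make_problem(n = 400, m = 150, family = fam, seed = 11)
    # lambda_min_ratio 0.05 keeps the binomial path out of deep saturation,
    # where the dense oracle's own convergence limits the attainable agreement
    fc <- fit_config(fam, n_lambda = 25, batch_size = 10, cd_tolerance = 1e-10,
                     lambda_min_ratio = 0.05, early_stop_patience = 1000)
    val <- 301:400
    path <- basil_fit(pr$G, pr$covs, pr$y, pr$w, fc, validation = val)
    oracle <- glmnet_oracle(pr$G, pr$covs, pr$y, pr$w, path$lambdas, fam,
                            train = 1:300)
    expect_lt(max(abs(as.matrix(path$coefficients) - oracle)), 1e-6)
  }
})

test_that("null signal yields a near-empty selected model", {
  pr <- make_problem(n = 400, m = 100, seed = 12)
  set.seed(13)
  y_perm <- sample(pr$y)
  fc <- fit_config("gaussian", n_lambda = 30, batch_size = 20)
  path <- basil_fit(pr$G, pr$covs, y_perm, rep(1, 100), fc, validation = 301:400)
  k <- select_lambda(path)
  expect_lte(path$active_counts[k], 10)
  expect_lt(path$validation_metric[k], 0.08)
})

test_that("lower-penalty duplicate enters the path first", {
  set.seed(14)
  pr <- make_problem(n = 300, m = 40, seed = 14)
  G <- cbind(pr$G, dupA = pr$G[, 1], dupB = pr$G[, 1])
  colnames(G) <- c(colnames(pr$G), "dupA", "dupB")
  w <- c(rep(1, 40), 0.5, 1.0)
  # make the duplicated signal strong
  y <- pr$y + 0.5 * std_cols(G[, "dupA", drop = FALSE])[, 1]
  fc <- fit_config("gaussian", n_lambda = 40, batch_size = 5,
                   early_stop_patience = 1000)
  path <- basil_fit(G, pr$covs, y, w, fc, validation = 251:300)
  B <- as.matrix(path$coefficients)
  first_nz <- function(v) { i <- which(B[v, ] != 0); if (length(i)) min(i) else Inf }
  expect_lt(first_nz("dupA"), first_nz("dupB"))
})

test_that("select_lambda maximizes with sparse tie-breaking", {
  mk <- function(metric) structure(list(validation_metric = metric),
                                   class = "lasso_path")
  expect_equal(select_lambda(mk(c(0.1, 0.3, 0.2))), 2)
  expect_equal(select_lambda(mk(c(0.3, 0.3))), 1)
  expect_equal(select_lambda(mk(c(0.1, 0.2, 0.3))), 3)
})

test_that("refit_final de-standardizes to per-dosage weights", {
  pr <- make_problem(n = 500, m = 60, seed = 15)
  fc <- fit_config("gaussian", n_lambda = 25, batch_size = 10,
                   cd_tolerance = 1e-10, early_stop_patience = 1000)
  val <- 401:500
  path <- basil_fit(pr$G, pr$covs, pr$y, pr$w, fc, validation = val)
  k <- select_lambda(path)
  model <- refit_final(pr$G, pr$covs, pr$y, path$lambdas[k], pr$w, fc)
  expect_gt(length(model$weights), 0)
  # linear predictor identity: intercept + cov + sum_j w_j dosage_j
  covm <- as.matrix(pr$covs)
  eta_raw <- model$covariate_coef[1] +
    drop(covm %*% model$covariate_coef[-1]) +
    drop(pr$G[, names(model$weights), drop = FALSE] %*% model$weights)
  # reconstruct the standardized-scale prediction at the refit solution
  mu <- colMeans(pr$G)
  sdev <- apply(pr$G, 2, function(x) sqrt(mean((x - mean(x))^2)))
  beta_std <- model$weights * sdev[names(model$weights)]
  eta_std <- (model$covariate_coef[1] +
                sum(model$covariate_coef[-1] * colMeans(covm)) +
                sum(beta_std * mu[names(model$weights)] /
                      sdev[names(model$weights)])) +
    drop(sweep(covm, 2, colMeans(covm)) %*% model$covariate_coef[-1]) +
    drop(sweep(sweep(pr$G[, names(model$weights), drop = FALSE], 2,
                     mu[names(model$weights)]), 2,
               sdev[names(model$weights)], "/") %*% beta_std)
  expect_equal(eta_raw, eta_std, tolerance = 1e-10)
})

test_that("refit at the selected lambda reproduces the path solution when the
           development set equals the training set", {
  pr <- make_problem(n = 300, m = 50, seed = 16)
  fc <- fit_config("gaussian", n_lambda = 20, batch_size = 10,
                   cd_tolerance = 1e-11, early_stop_patience = 1000)
  val <- 251:300
  path <- basil_fit(pr$G, pr$covs, pr$y, pr$w, fc, validation = val)
  k <- select_lambda(path)
  train <- 1:250
  model <- refit_final(pr$G[train, ], pr$covs[train, ], pr$y[train],
                       path$lambdas[k], pr$w, fc)
  # compare on the standardized scale
  sdev <- apply(pr$G[train, ], 2, function(x) sqrt(mean((x - mean(x))^2)))
  beta_path <- as.matrix(path$coefficients)[-(1:3), k]
  beta_refit <- setNames(rep(0, 50), colnames(pr$G))
  beta_refit[names(model$weights)] <- model$weights * sdev[names(model$weights)]
  expect_equal(unname(beta_refit), unname(beta_path), tolerance = 1e-6)
})

test_that("basil_fit validates its inputs", {
  pr <- make_problem(n = 100, m = 20, seed = 17)
  expect_error(basil_fit(pr$G, pr$covs, pr$y, pr$w, fit_config("gaussian"),
                         validation = integer(0)), "validation")
})
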