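# Shared fixture builders. Everything is generated in code under fixed seeds.

# standardize columns to mean 0, population sd 1 (matching the fit engine)
std_cols <- function(X) {
  apply(X, 2, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
}

# small random genotype/trait problem for engine tests
make_problem <- function(n = 300, m = 80, n_causal = 5, family = "gaussian",
                         seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]), n, m)
  colnames(G) <- sprintf("v%04d", seq_len(m))
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  beta <- c(rnorm(n_causal), rep(0, m - n_causal))
  eta <- drop(std_cols(G) %*% beta) * 0.4 + 0.3 * covs$age
  y <- if (family == "gaussian") eta + rnorm(n)
       else rbinom(n, 1, plogis(eta - 0.5))
  w <- sample(c(0.5, 0.75, 1), m, replace = TRUE)
  list(G = G, covs = covs, y = y, w = w, beta = beta)
}

# dense lasso oracle: glmnet on the same standardized design, with the
# penalty-factor rescaling undone so the effective penalty is lambda * w_j
glmnet_oracle <- function(G, covs, y, w, lambdas, family, train) {
  Gs <- std_cols(G[train, , drop = FALSE])
  covm <- sweep(as.matrix(covs[train, , drop = FALSE]), 2,
                colMeans(as.matrix(covs[train, , drop = FALSE])))
  X <- cbind(covm, Gs)
  pf <- c(rep(0, ncol(covm)), w)
  fit <- glmnet::glmnet(X, y[train], family = family, penalty.factor = pf,
                        lambda = lambdas * sum(pf) / ncol(X),
                        standardize = FALSE, thresh = 1e-18, maxit = 1e8)
  as.matrix(coef(fit))
}
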