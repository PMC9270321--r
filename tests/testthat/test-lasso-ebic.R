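# Independent proximal-gradient (ISTA) solver for the gaussian lasso on
# standardised predictors: shares no code with the coordinate-descent path.
ista_gaussian <- function(X, y, lambda, iters = 20000) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  b <- rep(0, p); b0 <- mean(y)
  L <- max(eigen(crossprod(Xs) / n, only.values = TRUE)$values) + 1
  for (k in seq_len(iters)) {
    r <- y - b0 - Xs %*% b
    g <- -crossprod(Xs, r) / n
    bn <- b - g / L
    bn <- sign(bn) * pmax(abs(bn) - lambda / L, 0)
    b0 <- mean(y - Xs %*% bn)
    if (max(abs(bn - b)) < 1e-10) { b <- bn; break }
    b <- bn
  }
  list(obj = sum((y - b0 - Xs %*% b)^2) / (2 * n) + lambda * sum(abs(b)))
}

path_objective <- function(path, X, y, l) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  r <- y - path$b0_std[l] - Xs %*% path$beta_std[, l]
  sum(r^2) / (2 * length(y)) + path$lambdas[l] * sum(abs(path$beta_std[, l]))
}

test_that("the null model holds at lambda_max and OLS at lambda -> 0", {
  set.seed(41)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- drop(X %*% c(1, -0.5, 0, 0, 0.3) + rnorm(200))
  path <- glm_lasso_path(X, y, "gaussian")
  expect_equal(path$df[1], 0)                       # KKT at the null model

  lam <- c(0.5, 0.1, 0.01, 1e-4, 1e-8)
  p2 <- glm_lasso_path(X, y, "gaussian", lambdas = lam)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(p2$beta[, 5] - ols[-1])), 1e-6)
  expect_lt(abs(p2$intercept[5] - ols[1]), 1e-6)
})

test_that("path objectives match an independent convex solver", {
  set.seed(42)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- drop(X %*% c(1.5, 0, -1, 0, 0.5) + rnorm(50))
  path <- glm_lasso_path(X, y, "gaussian", n_lambdas = 20)
  for (l in seq(1, 20, by = 4)) {
    o_cd <- path_objective(path, X, y, l)
    o_ista <- ista_gaussian(X, y, path$lambdas[l])$obj
    expect_lt(abs(o_cd - o_ista), 1e-6)
  }
})

test_that("KKT conditions hold at the selected penalty for every family", {
  set.seed(43)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6)
  ys <- list(
    gaussian = drop(X %*% c(1, 0, 0, -0.7, 0, 0) + rnorm(n)),
    binomial = rbinom(n, 1, plogis(drop(X %*% c(1, 0, 0, -1, 0, 0)))),
    poisson = rpois(n, exp(drop(X %*% c(0.4, 0, 0, -0.3, 0, 0)))))
  for (fam in names(ys)) {
    y <- ys[[fam]]
    path <- glm_lasso_path(X, y, fam)
    sel <- ebic_select(path, p_candidates = 6, gamma = 0.25)
    l <- sel$index
    ctr <- colMeans(X)
    scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    eta <- drop(Xs %*% path$beta_std[, l]) + path$b0_std[l]
    mu <- switch(fam, gaussian = eta, binomial = plogis(eta),
                 poisson = exp(eta))
    g <- drop(crossprod(Xs, mu - y)) / n
    b <- path$beta_std[, l]
    lam <- path$lambdas[l]
    if (any(b == 0)) expect_lte(max(abs(g[b == 0])), lam + 1e-5)
    if (any(b != 0))
      expect_lt(max(abs(g[b != 0] + lam * sign(b[b != 0]))), 1e-5)
  }
})

test_that("EBIC selection reduces to BIC when the extra term vanishes", {
  set.seed(44)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- drop(X %*% c(1, 0.8, 0, 0) + rnorm(300))
  path <- glm_lasso_path(X, y, "gaussian")
  s_bic <- which.min(-2 * path$loglik + path$df * log(path$n))
  expect_equal(ebic_select(path, p_candidates = 4, gamma = 0)$index, s_bic)
  # a single candidate predictor: the 2 gamma df log(p) term is log(1) = 0
  X1 <- X[, 1, drop = FALSE]
  y1 <- drop(X1 * 1.2 + rnorm(300))
  p1 <- glm_lasso_path(X1, y1, "gaussian")
  expect_equal(ebic_select(p1, p_candidates = 1, gamma = 0.25)$index,
               ebic_select(p1, p_candidates = 1, gamma = 0)$index)
  expect_error(ebic_select(loglik = numeric(0), df = numeric(0), n = 10,
                           p_candidates = 1), "empty")
})

test_that("EBIC keeps the null model when the response is independent", {
  empty <- 0
  R <- 40
  for (r in seq_len(R)) {
    set.seed(800 + r)
    X <- matrix(rnorm(500 * 6), 500, 6)
    y <- rnorm(500)
    path <- glm_lasso_path(X, y, "gaussian")
    sel <- ebic_select(path, p_candidates = 6, gamma = 0.25)
    empty <- empty + (sel$df == 0)
  }
  expect_gte(empty / R, 0.9)
})
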