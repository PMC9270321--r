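test_that("nodewise EBIC selection matches brute-force enumeration", {
  for (r in 1:20) {
    set.seed(600 + r)
    p <- sample(2:4, 1)
    n <- 300
    X <- matrix(rnorm(n * p), n, p)
    k <- sample(0:p, 1)
    b <- rep(0, p)
    if (k > 0) b[sample(p, k)] <- sample(c(-1, 1), k, TRUE) * runif(k, 0.5, 1.5)
    y <- drop(X %*% b + rnorm(n))
    lmax <- morbinet:::lambda_max(scale(X, scale = apply(X, 2, function(c)
      sqrt(mean((c - mean(c))^2)))), y, "gaussian")
    lam <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 5))
    path <- glm_lasso_path(X, y, "gaussian", lambdas = lam)
    sel <- ebic_select(path, p_candidates = p, gamma = 0.25)
    expect_equal(sel$index,
                 brute_force_ebic_index(X, y, path, "gaussian", 0.25, p))
  }
})

test_that("independent binary nodes give an empty Ising graph", {
  empty <- 0
  R <- 20
  for (r in seq_len(R)) {
    set.seed(700 + r)
    x <- matrix(rbinom(1000 * 6, 1, 0.3), 1000, 6)
    empty <- empty + (sum(fit_ising(x)$weights != 0) == 0)
  }
  expect_gte(empty / R, 0.9)
})

test_that("a chain graph is recovered with positive couplings", {
  th <- chain_theta(6, 1.2)
  tau <- centred_tau(th)
  ok <- 0
  R <- 10
  for (r in seq_len(R)) {
    x <- sample_ising_exact(th, tau, 3000, seed = 750 + r)
    W <- fit_ising(x)$weights
    true_e <- abs(row(W) - col(W)) == 1
    tp <- sum(W[true_e & upper.tri(W)] > 0)
    fp <- sum(W[!true_e & upper.tri(W)] != 0)
    ok <- ok + (tp == 5 && fp <= 1)
  }
  expect_gte(ok / R, 0.8)
})

test_that("AND-rule edges are a subset of OR-rule edges", {
  th <- chain_theta(5, 0.8)
  x <- sample_ising_exact(th, centred_tau(th), 800, seed = 46)
  e_and <- fit_ising(x, ebic_config(rule = "AND"))$weights != 0
  e_or <- fit_ising(x, ebic_config(rule = "OR"))$weights != 0
  expect_true(all(e_or[e_and]))
})

test_that("Ising estimates are invariant to node ordering", {
  th <- chain_theta(5, 1.0)
  x <- sample_ising_exact(th, centred_tau(th), 1200, seed = 47)
  colnames(x) <- paste0("n", 1:5)
  perm <- c(3, 1, 5, 2, 4)
  net1 <- fit_ising(x)
  net2 <- fit_ising(x[, perm])
  expect_equal(net2$weights[colnames(x), colnames(x)], net1$weights,
               tolerance = 1e-8)
})

test_that("fit_ising validates its inputs", {
  x <- matrix(rbinom(300, 1, 0.4), 100, 3)
  x[, 2] <- 0
  colnames(x) <- c("a", "b", "c")
  expect_error(fit_ising(x), "zero variance.*b")
  expect_error(fit_ising(matrix(0:1, 50, 2)), "at least 3")
  xm <- matrix(rbinom(300, 1, 0.4), 100, 3)
  xm[1, 1] <- NA
  expect_error(fit_ising(xm), "complete")
})

test_that("all-binary mixed models reduce to the Ising fit", {
  th <- chain_theta(4, 1.0)
  x <- sample_ising_exact(th, centred_tau(th), 900, seed = 48)
  colnames(x) <- paste0("v", 1:4)
  ei <- fit_ising(x)$weights != 0
  em <- fit_mgm(x, rep("binary", 4))$weights != 0
  expect_identical(em, ei)
})

test_that("a planted continuous-binary edge is recovered with its sign", {
  hits <- 0
  R <- 10
  for (r in seq_len(R)) {
    set.seed(760 + r)
    n <- 2000
    B <- matrix(rbinom(n * 10, 1, 0.3), n, 10)
    colnames(B) <- paste0("b", 1:10)
    y <- 0.8 * B[, 1] + rnorm(n)
    net <- fit_mgm(cbind(B, y = y), c(rep("binary", 10), "continuous"))
    hits <- hits + (net$weights["b1", "y"] != 0 && net$signs["b1", "y"] == 1)
  }
  expect_gte(hits / R, 0.9)
})

test_that("an independent continuous node stays isolated", {
  iso <- 0
  R <- 20
  for (r in seq_len(R)) {
    set.seed(780 + r)
    n <- 1000
    B <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
    colnames(B) <- paste0("b", 1:5)
    y <- rnorm(n)
    net <- fit_mgm(cbind(B, y = y), c(rep("binary", 5), "continuous"))
    iso <- iso + (sum(net$weights[, "y"] != 0) == 0)
  }
  expect_gte(iso / R, 0.9)
})

test_that("mixed-model input validation catches type errors", {
  M <- cbind(matrix(rbinom(300, 1, 0.4), 100, 3), z = rnorm(100))
  expect_error(fit_mgm(M, c("binary", "binary", "binary", "ordinal")),
               "unsupported")
  expect_error(fit_mgm(M, c("binary", "binary", "binary")), "one entry")
  M2 <- M
  M2[, 4] <- c(-1, rep(1, 99))
  expect_error(fit_mgm(M2, c(rep("binary", 3), "count")), "non-negative")
})
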