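test_that("predictability tracks signal, baseline and exact fits", {
  th <- chain_theta(5, 1.2)
  x <- sample_ising_exact(th, centred_tau(th), 2000, seed = 61)
  colnames(x) <- paste0("d", 1:5)
  # append a node independent of everything
  set.seed(62)
  x2 <- cbind(x, iso = rbinom(2000, 1, 0.4))
  net <- fit_ising(x2)
  rep_ <- node_predictability(x2, net)
  iso_row <- rep_[rep_$node == "iso", ]
  expect_lt(abs(iso_row$value - iso_row$baseline), 0.03)
  # in-sample refits never fall meaningfully below baseline
  expect_true(all(rep_$value >= rep_$baseline - 0.02))

  # a continuous node that is an exact linear function of its neighbours
  set.seed(63)
  B <- matrix(rbinom(1500 * 4, 1, 0.4), 1500, 4)
  colnames(B) <- paste0("b", 1:4)
  y <- 2 * B[, 1] - B[, 2]
  M <- cbind(B, y = y)
  net2 <- fit_mgm(M, c(rep("binary", 4), "continuous"))
  # binary neighbours of an exactly determined node separate perfectly,
  # so their refits warn about non-convergence; the R^2 = 1 claim is the
  # point of the fixture
  rep2 <- suppressWarnings(node_predictability(M, net2))
  expect_equal(rep2$value[rep2$node == "y"], 1.0, tolerance = 1e-8)
})

test_that("classification accuracy approaches the Bayes rate", {
  # planted logistic node with known coefficients; the Bayes rate is
  # E[max(mu, 1 - mu)], estimated by Monte Carlo from the generative model
  set.seed(64)
  n <- 5000
  B <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  colnames(B) <- paste0("b", 1:3)
  eta <- -0.5 + 1.5 * B[, 1] - 2 * B[, 2] + 1 * B[, 3]
  y <- rbinom(n, 1, plogis(eta))
  big <- matrix(rbinom(2e5 * 3, 1, 0.5), 2e5, 3)
  mu_big <- plogis(-0.5 + 1.5 * big[, 1] - 2 * big[, 2] + 1 * big[, 3])
  bayes <- mean(pmax(mu_big, 1 - mu_big))
  M <- cbind(B, y = y)
  net <- fit_ising(M)
  rep_ <- node_predictability(M, net)
  expect_lt(abs(rep_$value[rep_$node == "y"] - bayes), 0.03)
})

test_that("bootstrap summaries are seeded and degenerate correctly", {
  th <- chain_theta(4, 1.2)
  x <- sample_ising_exact(th, centred_tau(th), 600, seed = 65)
  colnames(x) <- paste0("d", 1:4)
  fit_fn <- function(m) fit_ising(m)
  b1 <- bootstrap_edges(x, fit_fn, B = 50, seed = 5)
  b2 <- bootstrap_edges(x, fit_fn, B = 50, seed = 5)
  expect_identical(b1$edges, b2$edges)
  expect_true(all(b1$edges$q025 <= b1$edges$q50 + 1e-12))
  expect_true(all(b1$edges$q50 <= b1$edges$q975 + 1e-12))
  expect_true(all(b1$edges$inclusion >= 0 & b1$edges$inclusion <= 1))
  expect_error(bootstrap_edges(x, fit_fn, B = 10, seed = 1), "at least 50")

  # a table of identical rows makes every resample identical: width 0.
  # (constant nodes cannot be fitted, so collapse pairs of distinct rows)
  x_dup <- x[rep(1:50, each = 12), ]
  b3 <- bootstrap_edges(x_dup, fit_fn, B = 50, seed = 6)
  expect_true(all(b3$edges$q975 - b3$edges$q025 >= 0))
})

test_that("true chain edges are retained more often than false ones", {
  th <- chain_theta(6, 1.2)
  x <- sample_ising_exact(th, centred_tau(th), 1500, seed = 66)
  colnames(x) <- paste0("d", 1:6)
  bs <- bootstrap_edges(x, function(m) fit_ising(m), B = 60, seed = 7)
  idx <- which(upper.tri(th), arr.ind = TRUE)
  is_true <- th[upper.tri(th)] != 0
  expect_gt(mean(bs$edges$inclusion[is_true]),
            mean(bs$edges$inclusion[!is_true]))
})

test_that("case-dropping stability is high under strong signal", {
  th <- chain_theta(5, 1.5)
  x <- sample_ising_exact(th, centred_tau(th), 4000, seed = 67)
  colnames(x) <- paste0("d", 1:5)
  cs <- case_drop_stability(x, function(m) fit_ising(m), B = 20, seed = 8)
  expect_gte(cs$cs_coefficient, 0.5)
  # mean correlation does not increase as more cases are dropped
  mc <- cs$curve$mean_cor
  expect_true(all(diff(mc) <= 0.02))
})

test_that("pure-noise data has nothing stable to retain", {
  set.seed(68)
  x <- matrix(rbinom(800 * 5, 1, 0.4), 800, 5)
  colnames(x) <- paste0("d", 1:5)
  cs <- case_drop_stability(x, function(m) fit_ising(m), B = 10, seed = 9)
  expect_equal(cs$cs_coefficient, 0)
})

test_that("flow layers equal BFS depth from the target", {
  # path graph: target - A - B
  W <- matrix(0, 3, 3, dimnames = rep(list(c("t", "A", "B")), 2))
  W["t", "A"] <- W["A", "t"] <- 0.5
  W["A", "B"] <- W["B", "A"] <- 0.3
  net <- list(labels = c("t", "A", "B"), weights = W,
              node_types = rep("binary", 3))
  fl <- flow_layers(net, "t")
  expect_equal(unname(fl$layer), c(0L, 1L, 2L))

  # edgeless network: every other node in the sentinel layer
  W0 <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  net0 <- list(labels = letters[1:4], weights = W0,
               node_types = rep("binary", 4))
  fl0 <- flow_layers(net0, "a")
  expect_equal(unname(fl0$layer), c(0L, 1L, 1L, 1L))
  expect_equal(fl0$sentinel_layer, 1L)

  expect_error(flow_layers(net0, "zz"), "unknown target")

  # random connected graphs against an independent shortest-path oracle
  for (s in 1:15) {
    set.seed(900 + s)
    p <- 8
    W <- matrix(0, p, p)
    for (i in 2:p) {                      # random tree keeps it connected
      j <- sample(i - 1, 1)
      W[i, j] <- W[j, i] <- runif(1, 0.2, 1)
    }
    extra <- which(upper.tri(W) & W == 0)
    on <- sample(extra, 3)
    W[on] <- runif(3, 0.2, 1)
    W <- pmax(W, t(W))
    labs <- paste0("v", 1:p)
    dimnames(W) <- list(labs, labs)
    net <- list(labels = labs, weights = W, node_types = rep("binary", p))
    fl <- flow_layers(net, "v1")
    g <- igraph::graph_from_adjacency_matrix(W != 0, mode = "undirected")
    ref <- as.integer(igraph::distances(g, v = "v1"))
    expect_equal(unname(fl$layer), ref)
  }
})
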