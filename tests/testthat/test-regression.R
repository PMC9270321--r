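make_xy_cohort <- function(n, x, y, seed = 1) {
  set.seed(seed)
  df <- data.frame(id = seq_len(n), psu = seq_len(n), stratum = 1L,
                   weight = 1, d1 = rbinom(n, 1, 0.3),
                   d2 = rbinom(n, 1, 0.3), y = y,
                   x = ifelse(x == 1, "b", "a"))
  cohort_table(df, tiny_schema(covariate = TRUE), validate = FALSE)
}

test_that("saturated Poisson PR equals the 2x2 prevalence ratio", {
  set.seed(21)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, ifelse(x == 1, 0.3, 0.15))
  tab <- make_xy_cohort(n, x, y)
  res <- fit_poisson_pr(tab, "y", "x")
  expect_equal(res$terms$effect[2], mean(y[x == 1]) / mean(y[x == 0]),
               tolerance = 1e-10)
  expect_true(res$terms$reference[1])
  expect_equal(res$terms$effect[1], 1)

  # singleton clusters + unit weights: CR0 equals HC0 on the same fit
  hc0 <- sqrt(diag(sandwich::vcovHC(res$fit, type = "HC0")))
  expect_equal(unname(res$terms$robust_se[2]), unname(hc0[2]),
               tolerance = 1e-10)
})

test_that("Poisson PR refuses degenerate outcomes and flags zero events", {
  tab <- make_xy_cohort(100, rbinom(100, 1, 0.5), rep(0L, 100))
  expect_error(fit_poisson_pr(tab, "y", "x"), "no events")

  set.seed(22)
  x <- c(rep(0, 150), rep(1, 50))
  y <- c(rbinom(150, 1, 0.3), rep(0L, 50))   # no events in level b
  tab2 <- make_xy_cohort(200, x, y)
  expect_warning(res <- fit_poisson_pr(tab2, "y", "x"), "zero outcome")
  expect_equal(res$terms$ci_low[2], 0)
  expect_equal(res$terms$ci_high[2], Inf)
})

test_that("linear model reduces to group-mean differences and exact fits", {
  set.seed(23)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  yl <- rnorm(n, 5 + 2 * x)
  tab <- make_xy_cohort(n, x, rbinom(n, 1, 0.2))
  df <- as.data.frame(tab)
  df$los <- yl
  sc <- cohort_schema(rbind(attr(tab, "schema")$variables,
                            data.frame(name = "los", type = "continuous",
                                       role = "outcome", design = NA,
                                       levels = I(list(NULL)))))
  tab2 <- cohort_table(df, sc, validate = FALSE)
  res <- fit_linear(tab2, "los", "x")
  expect_equal(res$terms$coef[2], mean(yl[x == 1]) - mean(yl[x == 0]),
               tolerance = 1e-10)

  # outcome an exact linear function of the covariate: exact recovery
  df$los <- 3 + 1.5 * x
  tab3 <- cohort_table(df, sc, validate = FALSE)
  res3 <- suppressWarnings(fit_linear(tab3, "los", "x"))  # exact fit
  expect_equal(res3$terms$coef[2], 1.5, tolerance = 1e-10)
  expect_lt(sum(residuals(res3$fit)^2), 1e-18)

  # aliased covariate: error naming the term
  df$x2 <- df$x
  sc4 <- cohort_schema(rbind(sc$variables,
                             data.frame(name = "x2", type = "categorical",
                                        role = "covariate", design = NA,
                                        levels = I(list(c("a", "b"))))))
  tab4 <- cohort_table(df, sc4, validate = FALSE)
  expect_error(fit_linear(tab4, "los", c("x", "x2")), "aliased.*x2")
})

test_that("Poisson PR recovers a known log-prevalence-ratio", {
  # marginal log-PR stays 0.6 under independent PSU effects (log link is
  # collapsible); CR0 intervals should cover it at near-nominal rate
  R <- 60
  cover <- 0
  est <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(3000 + r)
    n <- 2000; G <- 100
    psu <- rep(seq_len(G), each = n / G)
    u <- rnorm(G, 0, 0.2)
    x <- rbinom(n, 1, 0.5)
    pr <- exp(log(0.08) - 0.02 + 0.6 * x + u[psu])
    y <- rbinom(n, 1, pmin(pr, 1))
    df <- data.frame(id = seq_len(n), psu = psu, stratum = 1L, weight = 1,
                     d1 = 0L, d2 = 1L, y = y,
                     x = ifelse(x == 1, "b", "a"))
    tab <- cohort_table(df, tiny_schema(covariate = TRUE),
                        validate = FALSE)
    res <- fit_poisson_pr(tab, "y", "x")
    est[r] <- res$terms$coef[2]
    cover <- cover + (log(res$terms$ci_low[2]) <= 0.6 &&
                        0.6 <= log(res$terms$ci_high[2]))
  }
  expect_lt(abs(mean(est) - 0.6), 3 * sd(est) / sqrt(R))
  expect_gte(cover / R, 0.85)
})
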