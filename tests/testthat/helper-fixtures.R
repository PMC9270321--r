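# Shared fixtures: small schemas, design generators and graph builders used
# across the suite. Everything is generated in code under fixed seeds.

# Minimal schema: id + design triplet + two diseases + one binary outcome,
# optionally one categorical covariate `x` (levels a < b) and extra columns.
tiny_schema <- function(covariate = FALSE, extra = NULL) {
  v <- data.frame(
    name = c("id", "psu", "stratum", "weight", "d1", "d2", "y"),
    type = c("count", "count", "count", "continuous", "binary", "binary",
             "binary"),
    role = c("id", "design", "design", "design", "disease", "disease",
             "outcome"),
    design = c(NA, "psu", "stratum", "weight", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  v$levels <- vector("list", nrow(v))
  if (covariate) {
    v <- rbind(v, data.frame(name = "x", type = "categorical",
                             role = "covariate", design = NA,
                             levels = I(list(c("a", "b")))))
  }
  if (!is.null(extra)) v <- rbind(v, extra)
  cohort_schema(v)
}

# Cohort with iid Bernoulli data under a trivial design (each row its own
# PSU, unit weights, one stratum).
tiny_cohort <- function(n, y_prob = 0.2, x = NULL, seed = 1) {
  set.seed(seed)
  df <- data.frame(id = seq_len(n), psu = seq_len(n), stratum = 1L,
                   weight = 1, d1 = rbinom(n, 1, 0.3),
                   d2 = rbinom(n, 1, 0.3), y = rbinom(n, 1, y_prob))
  if (!is.null(x)) {
    df$x <- x
    cohort_table(df, tiny_schema(covariate = TRUE))
  } else {
    cohort_table(df, tiny_schema())
  }
}

# Chain coupling matrix with theta on consecutive pairs.
chain_theta <- function(p, th = 1.2) {
  m <- matrix(0, p, p)
  for (i in seq_len(p - 1)) { m[i, i + 1] <- th; m[i + 1, i] <- th }
  m
}

# Thresholds centring each node's conditional at 1/2 given half its
# neighbours active: gives balanced marginals for chain graphs.
centred_tau <- function(theta) -rowSums(theta) / 2

# Two-block planted-partition weight matrix (within-density wd, between bd).
planted_partition <- function(block = 8, wd = 0.8, bd = 0.05, seed = 1) {
  set.seed(seed)
  p <- 2 * block
  truth <- rep(1:2, each = block)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    pr <- if (truth[i] == truth[j]) wd else bd
    if (runif(1) < pr) { W[i, j] <- 1; W[j, i] <- 1 }
  }
  list(W = W, truth = truth)
}

# Brute-force state distribution for the {0,1} Ising model: independent of
# the package's internal enumeration (loops over states explicitly).
brute_ising_probs <- function(theta, tau) {
  p <- length(tau)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  un <- apply(states, 1, function(s) {
    e <- sum(tau * s)
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      e <- e + theta[i, j] * s[i] * s[j]
    exp(e)
  })
  list(states = states, probs = un / sum(un))
}

# Exhaustive independent re-scoring of every candidate model on a path:
# recounts df from the coefficients, recomputes the log-likelihood directly
# from the GLM density, rebuilds the EBIC formula and re-applies the
# sparser-tie rule (first minimum = largest penalty).
brute_force_ebic_index <- function(X, y, path, family, gamma, pc) {
  n <- length(y)
  scores <- vapply(seq_along(path$lambdas), function(l) {
    eta <- drop(as.matrix(X) %*% path$beta[, l]) + path$intercept[l]
    ll <- switch(family,
      gaussian = {
        rss <- sum((y - eta)^2)
        -n / 2 * (log(2 * pi * rss / n) + 1)
      },
      binomial = sum(dbinom(y, 1, plogis(eta), log = TRUE)),
      poisson = sum(dpois(y, exp(eta), log = TRUE)))
    df <- sum(path$beta[, l] != 0)
    -2 * ll + df * log(n) + 2 * gamma * df * log(pc)
  }, 0)
  which.min(scores)
}

# Frequency of each enumerated state in a sample matrix.
state_freqs <- function(x, states) {
  key <- apply(states, 1, paste, collapse = "")
  obs <- table(factor(apply(x, 1, paste, collapse = ""), levels = key))
  as.numeric(obs) / nrow(x)
}
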