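#' L1-penalised GLM coefficient path
#'
#' For each penalty in a strictly decreasing `lambdas` sequence, minimises
#' (1/n) * negative log-likelihood + lambda * sum_j |beta_j| with an
#' unpenalised intercept, by cyclic coordinate descent on an IRLS quadratic
#' approximation with warm starts along the path (convergence: maximum
#' absolute coefficient update below 1e-7). Predictors are standardised
#' internally (mean 0, population sd 1) and coefficients are returned on the
#' original scale. At lambda >= lambda_max = max_j |(1/n) X_j' (y - ybar)|
#' (with X standardised) every penalised coefficient is exactly zero.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y response vector.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param lambdas strictly decreasing penalty sequence; by default a
#'   log-spaced path of `n_lambdas` values from lambda_max down to
#'   `lambda_min_ratio * lambda_max`.
#' @param n_lambdas,lambda_min_ratio path shape when `lambdas` is `NULL`.
#' @param tol coordinate-update convergence tolerance.
#' @return A list of class `lasso_path`: `beta` (p x L, original scale),
#'   `intercept` (length L), `lambdas`, `loglik` (length L), `df` (nonzero
#'   penalised coefficients per lambda), `family`, `n`.
#' @export
glm_lasso_path <- function(X, y, family = c("gaussian", "binomial",
                                            "poisson"),
                           lambdas = NULL, n_lambdas = 100L,
                           lambda_min_ratio = 0.01, tol = 1e-7) {
  family <- match.arg(family)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) stop("binomial family requires a 0/1 response")
    if (length(unique(y)) < 2L)
      stop("binomial response is constant; the model is undefined")
  }
  if (family == "poisson" && any(y < 0))
    stop("poisson family requires a non-negative response")

  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  if (any(scl == 0))
    stop("zero-variance predictor column: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  if (is.null(lambdas)) {
    lmax <- lambda_max(Xs, y, family)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambdas))
  } else {
    if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  }

  fam_code <- match(family, c("gaussian", "binomial", "poisson")) - 1L
  res <- .cd_glm_path(Xs, y, fam_code, as.numeric(lambdas), tol, 100L)

  beta_std <- res$beta
  beta <- sweep(beta_std, 1, scl, "/")
  intercept <- res$b0 - colSums(beta_std * (ctr / scl))
  ll <- vapply(seq_along(lambdas), function(l) {
    eta <- drop(Xs %*% beta_std[, l]) + res$b0[l]
    glm_loglik(y, eta, family)
  }, 0)
  structure(list(beta = beta, intercept = intercept,
                 lambdas = as.numeric(lambdas), loglik = ll,
                 df = colSums(beta_std != 0), family = family, n = n,
                 beta_std = beta_std, b0_std = res$b0,
                 center = ctr, scale = scl),
            class = "lasso_path")
}

# Smallest penalty at which all coefficients are zero (KKT at the null fit).
lambda_max <- function(Xs, y, family) {
  mu0 <- mean(y)
  max(abs(crossprod(Xs, y - mu0)) / length(y))
}

# GLM log-likelihood at a linear predictor (gaussian uses the profile
# loglik with sigma^2 = RSS/n, the convention used by the EBIC).
glm_loglik <- function(y, eta, family) {
  n <- length(y)
  switch(family,
    gaussian = {
      rss <- sum((y - eta)^2)
      -n / 2 * (log(2 * pi * rss / n) + 1)
    },
    binomial = {
      mu <- plogis(pmin(pmax(eta, -30), 30))
      sum(y * log(mu) + (1 - y) * log(1 - mu))
    },
    poisson = {
      eta <- pmin(eta, 30)
      sum(y * eta - exp(eta) - lgamma(y + 1))
    })
}

#' Extended BIC selection along a penalty path
#'
#' Selects the path index minimising
#' EBIC(lambda) = -2 loglik(lambda) + df(lambda) log n
#'   + 2 gamma df(lambda) log(p_candidates),
#' where df counts the nonzero penalised coefficients. With gamma = 0 this
#' is the plain BIC; ties are broken toward the larger penalty (the sparser
#' model).
#'
#' @param path a [glm_lasso_path()] result, or `NULL` if `df` and `loglik`
#'   are given directly.
#' @param loglik,df per-lambda log-likelihoods and nonzero counts
#'   (defaulting to the path's).
#' @param n sample size.
#' @param p_candidates number of candidate predictors offered to the model.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return A list with `index` (selected position, lambdas descending),
#'   `ebic` (the full criterion vector), `df` and `loglik` at the selection.
#' @export
ebic_select <- function(path = NULL, loglik = NULL, df = NULL, n = NULL,
                        p_candidates = NULL, gamma = 0.25) {
  if (!is.null(path)) {
    if (is.null(loglik)) loglik <- path$loglik
    if (is.null(df)) df <- path$df
    if (is.null(n)) n <- path$n
    if (is.null(p_candidates)) p_candidates <- nrow(path$beta)
  }
  if (is.null(loglik) || length(loglik) == 0L) stop("empty path")
  if (!all(is.finite(loglik))) stop("log-likelihoods must be finite")
  stopifnot(length(df) == length(loglik), gamma >= 0, p_candidates >= 1)
  ebic <- -2 * loglik + df * log(n) + 2 * gamma * df * log(p_candidates)
  # which.min takes the first minimum; lambdas are descending, so the first
  # minimising index is the largest (sparsest) penalty
  idx <- which.min(ebic)
  list(index = idx, ebic = ebic, df = df[idx], loglik = loglik[idx])
}
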