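#' Association models with cluster-robust variance
#'
#' `fit_poisson_pr()` estimates prevalence ratios for a binary outcome by
#' weighted Poisson regression with a log link (IRLS to a relative deviance
#' change below 1e-10 or 100 iterations), the standard device for
#' prevalence ratios in cross-sectional data. `fit_linear()` fits weighted
#' least squares for continuous or count outcomes and reports raw
#' coefficients. Both use the CR0 cluster sandwich on PSUs (weights inside
#' the meat) for standard errors, and Wald 95% intervals with z = 1.959964 —
#' on the log scale (back-transformed to the PR scale) for Poisson, on the
#' identity scale for linear models.
#'
#' Covariates are entered as factors with the schema's reference level
#' first; reference levels are reported with effect 1 (PR) or 0 (beta) and
#' an empty interval. A covariate level with zero outcome events triggers a
#' warning and an unbounded CI for that term.
#'
#' @param table a [cohort_table()].
#' @param outcome outcome variable name (binary for Poisson).
#' @param covariates covariate names (categorical variables use their
#'   schema-declared levels; numeric variables enter linearly).
#' @param weights per-row analysis weights (default: the design weights).
#' @param cluster per-row cluster ids (default: the design PSUs).
#' @return A list of class `regression_result` with a per-term data frame
#'   (`term`, `level`, `coef`, `robust_se`, `effect`, `ci_low`, `ci_high`,
#'   `reference`), `model_family` and `n_used`.
#' @export
fit_poisson_pr <- function(table, outcome, covariates, weights = NULL,
                           cluster = NULL) {
  fit_design_glm(table, outcome, covariates, weights, cluster,
                 family = "poisson")
}

#' @rdname fit_poisson_pr
#' @export
fit_linear <- function(table, outcome, covariates, weights = NULL,
                       cluster = NULL) {
  fit_design_glm(table, outcome, covariates, weights, cluster,
                 family = "linear")
}

fit_design_glm <- function(table, outcome, covariates, weights, cluster,
                           family) {
  sc <- attr(table, "schema")
  df <- as.data.frame(table)
  des <- survey_design(table)
  if (is.null(weights)) weights <- des$weight
  if (is.null(cluster)) cluster <- des$psu
  stopifnot(length(weights) == nrow(df), length(cluster) == nrow(df))

  y <- as.numeric(df[[outcome]])
  dat <- data.frame(.y = y)
  for (cv in covariates) {
    rec <- schema_record(sc, cv)
    col <- df[[cv]]
    dat[[cv]] <- if (rec$type == "categorical") {
      lv <- rec$levels
      if (is.null(lv) || !length(lv)) factor(col) else factor(col, levels = lv)
    } else if (cv %in% names(df) && rec$type %in% c("binary", "count",
                                                    "continuous")) {
      as.numeric(col)
    } else factor(col)
  }
  keep <- complete.cases(dat) & !is.na(weights) & weights > 0
  dat <- dat[keep, , drop = FALSE]
  w <- weights[keep]; cl <- cluster[keep]
  n_used <- nrow(dat)
  if (n_used == 0L) stop("no usable rows after removing missing values")

  if (family == "poisson") {
    if (!all(dat$.y %in% c(0, 1)))
      stop("Poisson prevalence-ratio model requires a binary outcome")
    if (sum(dat$.y) == 0) stop("outcome has no events; model is undefined")
    if (all(dat$.y == 1)) stop("outcome is constantly 1; model is undefined")
    fit <- stats::glm(.y ~ ., data = dat, weights = w,
                      family = quasipoisson(link = "log"),
                      control = list(epsilon = 1e-10, maxit = 100))
    if (!fit$converged)
      stop("Poisson IRLS did not converge in 100 iterations (deviance ",
           signif(fit$deviance, 6), ")")
  } else {
    fit <- stats::lm(.y ~ ., data = dat, weights = w)
    if (any(is.na(coef(fit))))
      stop("rank-deficient design; aliased terms: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }

  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  b <- coef(fit)
  se <- sqrt(diag(V))
  zc <- 1.959964

  rows <- list()
  zero_event_terms <- character()
  for (cv in covariates) {
    col <- dat[[cv]]
    if (is.factor(col)) {
      lv <- levels(col)
      for (k in seq_along(lv)) {
        if (k == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            term = cv, level = lv[1], coef = 0, robust_se = NA_real_,
            effect = if (family == "poisson") 1 else 0,
            ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
        } else {
          cn <- paste0(cv, lv[k])
          bi <- b[[cn]]; si <- se[[cn]]
          unbounded <- family == "poisson" &&
            sum(dat$.y[col == lv[k]]) == 0
          if (unbounded) zero_event_terms <- c(zero_event_terms,
                                               paste0(cv, "=", lv[k]))
          eff <- if (family == "poisson") exp(bi) else bi
          lo <- if (family == "poisson") exp(bi - zc * si) else bi - zc * si
          hi <- if (family == "poisson") exp(bi + zc * si) else bi + zc * si
          if (unbounded) { lo <- 0; hi <- Inf }
          rows[[length(rows) + 1L]] <- data.frame(
            term = cv, level = lv[k], coef = bi, robust_se = si,
            effect = eff, ci_low = lo, ci_high = hi, reference = FALSE)
        }
      }
    } else {
      bi <- b[[cv]]; si <- se[[cv]]
      eff <- if (family == "poisson") exp(bi) else bi
      rows[[length(rows) + 1L]] <- data.frame(
        term = cv, level = NA_character_, coef = bi, robust_se = si,
        effect = eff,
        ci_low = if (family == "poisson") exp(bi - zc * si) else bi - zc * si,
        ci_high = if (family == "poisson") exp(bi + zc * si) else bi + zc * si,
        reference = FALSE)
    }
  }
  if (length(zero_event_terms))
    warning("covariate level(s) with zero outcome events (CI unbounded): ",
            paste(zero_event_terms, collapse = ", "))
  terms_df <- do.call(rbind, rows)
  rownames(terms_df) <- NULL
  structure(list(terms = terms_df,
                 model_family = if (family == "poisson") "poisson" else
                   "linear",
                 n_used = n_used, vcov = V, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> family = ", x$model_family,
      ", n = ", x$n_used, "\n", sep = "")
  t <- x$terms
  eff <- if (x$model_family == "poisson") "PR" else "beta"
  for (i in seq_len(nrow(t))) {
    lab <- if (is.na(t$level[i])) t$term[i] else
      paste0(t$term[i], " [", t$level[i], "]")
    if (t$reference[i])
      cat(sprintf("  %-32s %s = %s (reference)\n", lab, eff,
                  format(t$effect[i])))
    else
      cat(sprintf("  %-32s %s = %.3f (%.3f, %.3f)\n", lab, eff,
                  t$effect[i], t$ci_low[i], t$ci_high[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.regression_result <- function(x, ...) x$terms
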