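#' Inverse probability weights for complete-case analysis
#'
#' Models the probability that a subject is a complete case (no missing cell
#' on the analysis variables) by logistic regression on fully observed
#' predictors, and returns the multiplier 1 / p-hat(complete) for complete
#' rows. Multipliers are combined with the survey weight multiplicatively
#' downstream; incomplete rows, which a complete-case analysis drops, receive
#' `NA`.
#'
#' @param table a [cohort_table()].
#' @param predictors names of fully observed predictor variables.
#' @param analysis_vars variables defining completeness (default: all
#'   disease, covariate and outcome variables except the predictors
#'   themselves). A row is complete if none of these is missing.
#' @return Numeric vector, one multiplier per row (`NA` on incomplete rows),
#'   with the fitted complete-case model attached as attribute `model`.
#' @export
compute_ipw <- function(table, predictors, analysis_vars = NULL) {
  sc <- attr(table, "schema")
  df <- as.data.frame(table)
  if (is.null(analysis_vars))
    analysis_vars <- setdiff(
      schema_vars(sc, role = c("disease", "covariate", "outcome")),
      predictors)
  unknown <- setdiff(c(predictors, analysis_vars), sc$variables$name)
  if (length(unknown))
    stop("variables not in schema: ", paste(unknown, collapse = ", "))
  pr <- df[, predictors, drop = FALSE]
  if (anyNA(pr))
    stop("predictors must be fully observed; missing values found in: ",
         paste(predictors[colSums(is.na(pr)) > 0], collapse = ", "))
  complete <- complete.cases(df[, analysis_vars, drop = FALSE])
  if (all(complete)) {
    out <- rep(1, nrow(df))          # nothing to reweight
    attr(out, "model") <- NULL
    return(out)
  }
  if (!any(complete))
    stop("complete-case indicator is constantly 0: IPW weights are undefined")
  pr <- as.data.frame(lapply(seq_along(predictors), function(j) {
    rec <- schema_record(sc, predictors[j])
    col <- pr[[j]]
    if (rec$type == "categorical") {
      lv <- rec$levels
      if (is.null(lv) || !length(lv)) factor(col) else factor(col, levels = lv)
    } else as.numeric(col)
  }))
  names(pr) <- predictors
  dat <- cbind(.complete = as.integer(complete), pr)
  fit <- stats::glm(.complete ~ ., data = dat, family = binomial())
  eta <- fit$linear.predictors
  if (max(abs(eta)) > 15)
    stop("perfect (or near-perfect) separation in the complete-case model: ",
         "fitted probabilities reach ", signif(max(plogis(abs(eta))), 4),
         "; IPW multipliers would be unstable")
  phat <- fitted(fit)
  out <- ifelse(complete, 1 / phat, NA_real_)
  attr(out, "model") <- fit
  out
}
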