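#' Design-based prevalence with stratified between-PSU variance
#'
#' Horvitz-Thompson ratio estimate of a binary variable's prevalence under a
#' stratified cluster design, with variance by Taylor linearisation and
#' between-PSU contrasts within strata (the standard `with-replacement'
#' first-stage approximation). The 95% CI is Wald on the logit scale and
#' back-transformed, which keeps it inside (0, 1); degenerate prevalences
#' (0 or 1) return a width-zero interval.
#'
#' @param table a [cohort_table()].
#' @param var name of a binary variable.
#' @param weights optional replacement analysis weights (e.g. survey weight
#'   times IPW multiplier); default: the design weights.
#' @param single_psu what to do with strata containing a single PSU:
#'   `"fail"` (default; the between-PSU variance is undefined there) or
#'   `"collapse"` (pool all single-PSU strata into one pseudo-stratum).
#' @return A list of class `prevalence_estimate`: `estimate`, `ci_low`,
#'   `ci_high`, `se`, `n_unweighted`.
#' @export
weighted_prevalence <- function(table, var, weights = NULL,
                                single_psu = c("fail", "collapse")) {
  single_psu <- match.arg(single_psu)
  sc <- attr(table, "schema")
  rec <- schema_record(sc, var)
  if (rec$type != "binary") stop("'", var, "' is not a binary variable")
  df <- as.data.frame(table)
  des <- survey_design(table)
  w <- if (is.null(weights)) des$weight else as.numeric(weights)
  y <- as.numeric(df[[var]])
  keep <- !is.na(y) & !is.na(w)
  y <- y[keep]; w <- w[keep]
  psu <- des$psu[keep]; stratum <- des$stratum[keep]
  n <- length(y)
  if (n == 0L) stop("no analysable rows for '", var, "'")

  W <- sum(w)
  est <- sum(w * y) / W

  if (est <= 0 || est >= 1) {
    out <- list(estimate = est, ci_low = est, ci_high = est, se = 0,
                n_unweighted = n)
    class(out) <- "prevalence_estimate"
    return(out)
  }

  # linearised residuals of the ratio estimator
  z <- w * (y - est) / W
  psu_tot <- tapply(z, list(stratum, psu), sum)
  strata <- rownames(psu_tot)
  n_psu <- rowSums(!is.na(psu_tot))
  if (any(n_psu < 2)) {
    lone <- strata[n_psu < 2]
    if (single_psu == "fail")
      stop("stratum with a single PSU (variance undefined): ",
           paste(lone, collapse = ", "),
           "; set single_psu = \"collapse\" to pool them")
    stratum2 <- as.character(stratum)
    stratum2[stratum2 %in% lone] <- ".collapsed"
    stratum <- stratum2
    psu_tot <- tapply(z, list(stratum, psu), sum)
    n_psu <- rowSums(!is.na(psu_tot))
    if (any(n_psu < 2))
      stop("collapse left a stratum with a single PSU; variance undefined")
  }
  v <- 0
  for (h in rownames(psu_tot)) {
    zh <- psu_tot[h, ]; zh <- zh[!is.na(zh)]
    nh <- length(zh)
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  se <- sqrt(v)
  lg <- qlogis(est)
  se_lg <- se / (est * (1 - est))
  zc <- 1.959964
  out <- list(
    estimate = est,
    ci_low = plogis(lg - zc * se_lg),
    ci_high = plogis(lg + zc * se_lg),
    se = se,
    n_unweighted = n
  )
  class(out) <- "prevalence_estimate"
  out
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("<prevalence_estimate> %.3f (95%% CI %.3f, %.3f), n = %d\n",
              x$estimate, x$ci_low, x$ci_high, x$n_unweighted))
  invisible(x)
}
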