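#' Household asset index by principal component analysis
#'
#' The socioeconomic score is the first principal component of the
#' standardised block of household asset variables, cut into weighted
#' quintiles. The PC sign is arbitrary, so the score is made sign-canonical:
#' it is oriented so that its skewness is positive (asset counts are
#' right-skewed, so the long tail points toward wealth); when the score is
#' essentially symmetric the orientation falls back to a positive loading
#' sum. The quintile cut respects the survey weights; boundaries are
#' left-closed/right-open except the last.
#'
#' @param table a [cohort_table()].
#' @param asset_vars names of the 12 asset variables (complete, numeric).
#' @return A list with `score` (per-row), `quintile` (integer 1-5 per row),
#'   `boundaries` (the 4 interior cut points), and `loadings`.
#' @export
asset_index <- function(table, asset_vars) {
  if (length(asset_vars) < 12L)
    stop("asset_index requires 12 asset variables, got ", length(asset_vars))
  df <- as.data.frame(table)
  unknown <- setdiff(asset_vars, names(df))
  if (length(unknown))
    stop("asset variables not in table: ", paste(unknown, collapse = ", "))
  X <- as.matrix(df[, asset_vars, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("asset variables must be complete")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance asset variable(s): ",
            paste(asset_vars[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  sk <- skewness(score)
  flip <- if (abs(sk) > 1e-8) sk < 0 else sum(loadings) < 0
  if (flip) { score <- -score; loadings <- -loadings }
  w <- survey_design(table)$weight
  boundaries <- weighted_quantile(score, w, probs = c(0.2, 0.4, 0.6, 0.8))
  quintile <- findInterval(score, boundaries, left.open = FALSE) + 1L
  list(score = score, quintile = quintile, boundaries = boundaries,
       loadings = loadings)
}

skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

# Weighted lower quantile: smallest x with cumulative weight share >= p.
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], 0)
}
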