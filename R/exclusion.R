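#' Complete-case exclusion accounting
#'
#' Counts and removes the rows missing any of the analysis variables,
#' mirroring the standard cohort flow chart: baseline n, excluded n, the
#' percentage excluded (one decimal), and the final analytic n.
#'
#' @param table a [cohort_table()].
#' @param analysis_vars variables whose missingness triggers exclusion.
#' @return A list of class `exclusion_report` with elements `report`
#'   (`n_baseline`, `n_missing`, `pct_missing`, `n_final`) and `table`
#'   (the filtered cohort).
#' @examples
#' \dontrun{
#' res <- exclusion_report(cohort, analysis_vars = c("hypertension", "sex"))
#' res$report$n_final
#' }
#' @export
exclusion_report <- function(table, analysis_vars) {
  if (length(analysis_vars) == 0L)
    stop("analysis_vars must name at least one variable")
  sc <- attr(table, "schema")
  unknown <- setdiff(analysis_vars, sc$variables$name)
  if (length(unknown))
    stop("analysis_vars not in schema: ", paste(unknown, collapse = ", "))
  df <- as.data.frame(table)
  incomplete <- !complete.cases(df[, analysis_vars, drop = FALSE])
  n_baseline <- nrow(df)
  n_missing <- sum(incomplete)
  report <- list(
    n_baseline = n_baseline,
    n_missing = n_missing,
    pct_missing = round(100 * n_missing / n_baseline, 1),
    n_final = n_baseline - n_missing
  )
  if (report$n_final == 0L)
    warning("all rows excluded: every subject is missing an analysis variable")
  kept <- cohort_table(df[!incomplete, , drop = FALSE], sc, validate = FALSE)
  structure(list(report = report, table = kept, analysis_vars = analysis_vars),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  r <- x$report
  cat("<exclusion_report> baseline ", r$n_baseline, "; missing ",
      r$n_missing, " (", r$pct_missing, "%); final ", r$n_final, "\n",
      sep = "")
  invisible(x)
}

#' @export
as.list.exclusion_report <- function(x, ...) x$report
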