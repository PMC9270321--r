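#' Cohort table: the single currency of the pipeline
#'
#' A `cohort_table` is a data frame validated against a [cohort_schema()]:
#' one row per subject, typed columns, missing values representable per cell,
#' and the survey-design triplet (PSU id, stratum id, sampling weight)
#' attached through the schema. All pipeline stages consume and produce this
#' class.
#'
#' @param data data frame conforming to the schema.
#' @param schema a [cohort_schema()].
#' @param validate validate cell domains (default `TRUE`).
#' @return A `cohort_table` (data frame subclass with the schema attached).
#' @export
cohort_table <- function(data, schema, validate = TRUE) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  missing_cols <- setdiff(schema$variables$name, names(data))
  if (length(missing_cols)) {
    dsub <- schema$variables$design[match(missing_cols, schema$variables$name)]
    if (any(!is.na(dsub)))
      stop("fatal schema error: design column(s) missing from data: ",
           paste(missing_cols[!is.na(dsub)], collapse = ", "))
    stop("columns missing from data: ", paste(missing_cols, collapse = ", "))
  }
  data <- data[, schema$variables$name, drop = FALSE]
  if (validate) validate_cohort_cells(data, schema)
  structure(data, schema = schema,
            class = c("cohort_table", "data.frame"))
}

validate_cohort_cells <- function(data, schema) {
  v <- schema$variables
  for (i in seq_len(nrow(v))) {
    nm <- v$name[i]
    col <- data[[nm]]
    obs <- !is.na(col)
    bad <- switch(v$type[i],
      binary = obs & !(col %in% c(0, 1)),
      count = obs & (!is.finite(suppressWarnings(as.numeric(col))) |
                       as.numeric(col) < 0 |
                       as.numeric(col) != round(as.numeric(col))),
      continuous = obs & !is.finite(suppressWarnings(as.numeric(col))),
      categorical = {
        lv <- v$levels[[i]]
        if (is.null(lv) || !length(lv)) rep(FALSE, length(col))
        else obs & !(col %in% lv)
      })
    if (any(bad)) {
      row1 <- which(bad)[1]
      stop("invalid value in column '", nm, "' (type ", v$type[i],
           ") at row ", row1, ": '", col[row1], "'")
    }
    if (v$role[i] == "design" && !is.na(v$design[i]) &&
        v$design[i] == "weight") {
      w <- as.numeric(col)
      if (any(!is.na(w) & w <= 0))
        stop("non-positive survey weight at row ",
             which(!is.na(w) & w <= 0)[1])
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- attr(x, "schema")
  cat("<cohort_table> ", nrow(x), " subjects x ", ncol(x), " variables (",
      sum(sc$variables$role == "disease"), " diseases)\n", sep = "")
  d <- design_columns(x)
  cat("  design: psu = ", d$psu, ", stratum = ", d$stratum,
      ", weight = ", d$weight, "\n", sep = "")
  core <- schema_vars(sc, role = c("disease", "covariate"))
  n_inc <- sum(!complete.cases(as.data.frame(x)[, core, drop = FALSE]))
  cat("  rows missing a disease/covariate cell: ", n_inc, "\n", sep = "")
  invisible(x)
}

#' Survey-design view of a cohort table
#'
#' @param table a [cohort_table()].
#' @return `design_columns()` gives the names of the PSU/stratum/weight
#'   columns; `survey_design()` gives a data frame with columns `psu`,
#'   `stratum`, `weight` (one row per subject).
#' @export
design_columns <- function(table) {
  sc <- attr(table, "schema")
  list(psu = schema_vars(sc, design = "psu"),
       stratum = schema_vars(sc, design = "stratum"),
       weight = schema_vars(sc, design = "weight"))
}

#' @rdname design_columns
#' @export
survey_design <- function(table) {
  d <- design_columns(table)
  data.frame(psu = table[[d$psu]],
             stratum = table[[d$stratum]],
             weight = as.numeric(table[[d$weight]]))
}

#' Read and write cohort CSV files
#'
#' The on-disk form is UTF-8 CSV with a header row; missing cells are empty.
#' Reading validates every cell against the schema and fails with the row and
#' column of the first out-of-domain value.
#'
#' @param path CSV file path.
#' @param schema a [cohort_schema()] (or a path to a YAML schema file).
#' @param table a [cohort_table()] (for writing).
#' @return `read_cohort()` returns a validated `cohort_table`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(schema)) schema <- read_schema(schema)
  data <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(schema$variables$name, names(data))
  if (length(missing_cols))
    stop("fatal schema error: header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cohort_table(data, schema)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
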