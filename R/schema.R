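#' Variable schema for a cohort table
#'
#' A schema is the typed contract for one cohort rectangle: one record per
#' variable giving its name, measurement type, analysis role and (for
#' categorical variables) the ordered level set with the reference level
#' first. Every [cohort_table()] is validated against a schema, and the
#' survey-design triplet (PSU, stratum, weight) is located through it.
#'
#' @param variables data frame with columns `name`, `type`
#'   (`"binary"`, `"categorical"`, `"count"`, `"continuous"`), `role`
#'   (`"disease"`, `"covariate"`, `"outcome"`, `"design"`, `"id"`), and for
#'   design variables a `design` subtype (`"psu"`, `"stratum"`, `"weight"`,
#'   otherwise `NA`). An optional list column `levels` carries category
#'   labels, reference level first.
#' @return An object of class `cohort_schema`.
#' @examples
#' sc <- cohort_schema(data.frame(
#'   name = c("id", "psu", "stratum", "weight", "hypertension", "diabetes",
#'            "hospitalisation"),
#'   type = c("count", "count", "count", "continuous", "binary", "binary",
#'            "binary"),
#'   role = c("id", "design", "design", "design", "disease", "disease",
#'            "outcome"),
#'   design = c(NA, "psu", "stratum", "weight", NA, NA, NA)
#' ))
#' schema_vars(sc, role = "disease")
#' @export
cohort_schema <- function(variables) {
  stopifnot(is.data.frame(variables))
  required <- c("name", "type", "role")
  missing_cols <- setdiff(required, names(variables))
  if (length(missing_cols))
    stop("schema is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"design" %in% names(variables)) variables$design <- NA_character_
  if (!"levels" %in% names(variables))
    variables$levels <- vector("list", nrow(variables))
  if (anyDuplicated(variables$name))
    stop("duplicate variable names in schema")
  bad_type <- setdiff(variables$type,
                      c("binary", "categorical", "count", "continuous"))
  if (length(bad_type)) stop("unknown variable type: ", bad_type[1])
  bad_role <- setdiff(variables$role,
                      c("disease", "covariate", "outcome", "design", "id"))
  if (length(bad_role)) stop("unknown variable role: ", bad_role[1])
  for (sub in c("psu", "stratum", "weight")) {
    k <- sum(variables$role == "design" &
             !is.na(variables$design) & variables$design == sub)
    if (k != 1L)
      stop("schema must declare exactly one design variable of subtype '",
           sub, "' (found ", k, ")")
  }
  n_dis <- sum(variables$role == "disease")
  if (n_dis < 2L)
    stop("schema must declare at least 2 disease variables (found ",
         n_dis, ")")
  if (any(variables$role == "disease" & variables$type != "binary"))
    stop("disease variables must be binary")
  structure(list(variables = variables), class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  v <- x$variables
  cat("<cohort_schema> ", nrow(v), " variables: ",
      sum(v$role == "disease"), " disease, ",
      sum(v$role == "covariate"), " covariate, ",
      sum(v$role == "outcome"), " outcome\n", sep = "")
  invisible(x)
}

#' Variable names by role or design subtype
#'
#' @param schema a [cohort_schema()].
#' @param role optional role filter.
#' @param design optional design subtype filter (`"psu"`, `"stratum"`,
#'   `"weight"`).
#' @return Character vector of variable names.
#' @export
schema_vars <- function(schema, role = NULL, design = NULL) {
  v <- schema$variables
  keep <- rep(TRUE, nrow(v))
  if (!is.null(role)) keep <- keep & v$role %in% role
  if (!is.null(design))
    keep <- keep & !is.na(v$design) & v$design %in% design
  v$name[keep]
}

schema_record <- function(schema, name) {
  v <- schema$variables
  i <- match(name, v$name)
  if (is.na(i)) stop("variable not in schema: ", name)
  lapply(v, `[[`, i)
}

#' Read or write a schema as YAML
#'
#' The on-disk form is a plain-text YAML list with one entry per variable
#' (`name`, `type`, `role`, optional `design` and `levels`).
#'
#' @param path file path.
#' @param schema a [cohort_schema()] (for writing).
#' @return `read_schema()` returns a `cohort_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- yaml::read_yaml(path)
  vars <- data.frame(
    name = vapply(raw, function(r) r$name, ""),
    type = vapply(raw, function(r) r$type, ""),
    role = vapply(raw, function(r) r$role, ""),
    design = vapply(raw, function(r)
      if (is.null(r$design)) NA_character_ else r$design, ""),
    stringsAsFactors = FALSE
  )
  vars$levels <- lapply(raw, function(r)
    if (is.null(r$levels)) NULL else as.character(r$levels))
  cohort_schema(vars)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  v <- schema$variables
  recs <- lapply(seq_len(nrow(v)), function(i) {
    r <- list(name = v$name[i], type = v$type[i], role = v$role[i])
    if (!is.na(v$design[i])) r$design <- v$design[i]
    lv <- v$levels[[i]]
    if (!is.null(lv) && length(lv)) r$levels <- as.list(lv)
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}
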