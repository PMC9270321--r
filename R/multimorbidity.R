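#' Multimorbidity category from the disease count
#'
#' Counts the yes-responses across the disease columns and classifies each
#' subject as `"<=1"`, `"2"` or `">=3"` chronic conditions. A row with any
#' missing disease cell gets a missing category: counts are never imputed.
#'
#' @param table a [cohort_table()].
#' @return Ordered factor with levels `"<=1" < "2" < ">=3"`, one per row,
#'   with the raw disease count attached as attribute `count`.
#' @export
multimorbidity_category <- function(table) {
  sc <- attr(table, "schema")
  dis <- schema_vars(sc, role = "disease")
  M <- as.matrix(as.data.frame(table)[, dis, drop = FALSE])
  storage.mode(M) <- "double"
  count <- rowSums(M)                       # NA if any disease cell missing
  cat <- cut(count, breaks = c(-Inf, 1, 2, Inf),
             labels = c("<=1", "2", ">=3"), ordered_result = TRUE)
  attr(cat, "count") <- count
  cat
}
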