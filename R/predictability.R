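#' Node predictability
#'
#' How well each node is predicted by its selected network neighbours: per
#' node, the unpenalised nodewise GLM restricted to the node's neighbours is
#' refitted and scored in-sample. Classification nodes (binary) report the
#' proportion correctly classified at a 0.5 threshold, with the larger
#' marginal class share as the intercept-only baseline; quantitative nodes
#' (count, continuous) report the proportion of variance explained on the
#' response scale (baseline 0). Nodes without neighbours report their
#' baseline and are flagged isolated.
#'
#' @param table the node block the network was fitted on.
#' @param network an `ising_network` or `mgm_network` fitted on `table`.
#' @return Data frame of class `predictability_report`: `node`, `measure`
#'   (`"correct_classification"` or `"variance_explained"`), `value`,
#'   `baseline`, `n_neighbours`, `isolated`.
#' @export
node_predictability <- function(table, network) {
  M <- node_block(table)
  if (!identical(colnames(M), network$labels))
    stop("table columns do not match the network's node labels")
  types <- network$node_types
  # mgm fits are performed on standardised continuous nodes
  for (j in which(types == "continuous")) {
    s <- sd(M[, j]); M[, j] <- (M[, j] - mean(M[, j])) / s
  }
  p <- ncol(M)
  out <- data.frame(node = network$labels,
                    measure = ifelse(types == "binary",
                                     "correct_classification",
                                     "variance_explained"),
                    value = NA_real_, baseline = NA_real_,
                    n_neighbours = 0L, isolated = FALSE)
  for (j in seq_len(p)) {
    nb <- which(network$weights[j, ] != 0)
    y <- M[, j]
    if (types[j] == "binary") {
      base <- max(mean(y), 1 - mean(y))
    } else base <- 0
    if (!length(nb)) {
      out$value[j] <- base
      out$baseline[j] <- base
      out$isolated[j] <- TRUE
      next
    }
    dat <- data.frame(.y = y, M[, nb, drop = FALSE])
    fam <- switch(types[j], binary = binomial(),
                  count = quasipoisson(link = "log"), continuous = gaussian())
    fit <- stats::glm(.y ~ ., data = dat, family = fam)
    mu <- fitted(fit)
    val <- if (types[j] == "binary") {
      mean((mu > 0.5) == (y == 1))
    } else {
      r2 <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
      min(max(r2, 0), 1)
    }
    out$value[j] <- val
    out$baseline[j] <- base
    out$n_neighbours[j] <- length(nb)
  }
  class(out) <- c("predictability_report", "data.frame")
  out
}
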