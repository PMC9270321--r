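#' EBIC configuration for network estimation
#'
#' @param gamma EBIC hyperparameter (default 0.25, the conventional value
#'   for graphical-model selection).
#' @param n_lambdas penalty path length per node.
#' @param lambda_min_ratio smallest/largest penalty on the path.
#' @param rule edge symmetrisation: `"AND"` keeps an edge only when both
#'   nodewise coefficients are nonzero, `"OR"` when either is.
#' @return A list of class `ebic_config`.
#' @export
ebic_config <- function(gamma = 0.25, n_lambdas = 100L,
                        lambda_min_ratio = 0.01, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  stopifnot(gamma >= 0, n_lambdas >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio, rule = rule),
            class = "ebic_config")
}

#' Estimate an Ising network over binary nodes
#'
#' Nodewise pseudo-likelihood estimation: each node is regressed on all
#' other nodes by an L1-penalised logistic path ([glm_lasso_path()]), the
#' penalty is chosen per node by the extended BIC ([ebic_select()]) with
#' p_candidates = p - 1, and the directed coefficient pairs are symmetrised
#' by the configured rule (AND by default). The retained edge weight is the
#' mean of the two nodewise coefficients (an absent one counts as 0 under
#' OR); thresholds are the selected intercepts. Edges are conditional
#' associations: each one controls for all other nodes in the network.
#'
#' @param table binary node block: a matrix/data frame of 0/1 columns, or a
#'   [cohort_table()] (its disease + binary outcome columns are not
#'   extracted automatically; pass the block you want).
#' @param config an [ebic_config()].
#' @return A list of class `ising_network`: `labels`, `weights` (symmetric,
#'   zero diagonal), `thresholds`, `n_fit`, `config`, and the per-node
#'   selected coefficient matrix `nodewise`.
#' @export
fit_ising <- function(table, config = ebic_config()) {
  M <- node_block(table)
  p <- ncol(M)
  if (p < 3L) stop("fit_ising needs at least 3 nodes")
  check_binary_block(M)
  nodewise <- matrix(0, p, p, dimnames = list(colnames(M), colnames(M)))
  thresholds <- setNames(numeric(p), colnames(M))
  for (j in seq_len(p)) {
    sel <- nodewise_select(M[, -j, drop = FALSE], M[, j], "binomial", config)
    nodewise[j, -j] <- sel$beta
    thresholds[j] <- sel$intercept
  }
  weights <- symmetrise_edges(nodewise, config$rule, signed_mean = TRUE)
  structure(list(labels = colnames(M), weights = weights,
                 thresholds = thresholds, n_fit = nrow(M), config = config,
                 nodewise = nodewise, node_types = rep("binary", p)),
            class = c("ising_network", "morbinet_network"))
}

#' Estimate a mixed graphical model over binary, count and continuous nodes
#'
#' Same nodewise machinery as [fit_ising()], with the GLM family chosen per
#' node by its declared type (binary -> logistic, count -> Poisson with log
#' link, continuous -> gaussian). Continuous nodes are standardised to unit
#' variance before fitting. Edge strength is the mean absolute value of the
#' two directed coefficients under AND-rule symmetrisation, with a sign
#' attribute: the common sign when the two directed coefficients agree,
#' 0 (undetermined) when they disagree.
#'
#' @param table mixed node block (matrix or data frame).
#' @param node_types character vector (`"binary"`, `"count"`,
#'   `"continuous"`), one per column.
#' @param config an [ebic_config()].
#' @return A list of class `mgm_network`: `labels`, `weights` (non-negative
#'   magnitudes), `signs` (+1/-1/0 per edge), `intercepts`, `node_types`,
#'   `n_fit`, `config`, `nodewise`.
#' @export
fit_mgm <- function(table, node_types, config = ebic_config()) {
  M <- node_block(table)
  p <- ncol(M)
  if (p < 3L) stop("fit_mgm needs at least 3 nodes")
  if (length(node_types) != p)
    stop("node_types must have one entry per column")
  bad <- setdiff(node_types, c("binary", "count", "continuous"))
  if (length(bad)) stop("unsupported node type: ", bad[1])
  if (anyNA(M)) stop("node block must be complete (no missing cells)")
  for (j in which(node_types == "binary"))
    if (!all(M[, j] %in% c(0, 1)))
      stop("binary node '", colnames(M)[j], "' has values outside {0,1}")
  for (j in which(node_types == "count"))
    if (any(M[, j] < 0) || any(M[, j] != round(M[, j])))
      stop("count node '", colnames(M)[j],
           "' must hold non-negative integers")
  # standardise continuous nodes to unit variance pre-fit
  for (j in which(node_types == "continuous")) {
    s <- sd(M[, j])
    if (s == 0) stop("zero-variance node: ", colnames(M)[j])
    M[, j] <- (M[, j] - mean(M[, j])) / s
  }
  fam <- c(binary = "binomial", count = "poisson",
           continuous = "gaussian")[node_types]
  nodewise <- matrix(0, p, p, dimnames = list(colnames(M), colnames(M)))
  intercepts <- setNames(numeric(p), colnames(M))
  for (j in seq_len(p)) {
    sel <- nodewise_select(M[, -j, drop = FALSE], M[, j], fam[j], config)
    nodewise[j, -j] <- sel$beta
    intercepts[j] <- sel$intercept
  }
  weights <- symmetrise_edges(nodewise, config$rule, signed_mean = FALSE)
  signs <- edge_signs(nodewise, weights)
  structure(list(labels = colnames(M), weights = weights, signs = signs,
                 intercepts = intercepts, node_types = node_types,
                 n_fit = nrow(M), config = config, nodewise = nodewise),
            class = c("mgm_network", "morbinet_network"))
}

node_block <- function(table) {
  M <- as.matrix(as.data.frame(table))
  storage.mode(M) <- "double"
  if (is.null(colnames(M)))
    colnames(M) <- paste0("V", seq_len(ncol(M)))
  M
}

check_binary_block <- function(M) {
  if (anyNA(M)) stop("node block must be complete (no missing cells)")
  vr <- apply(M, 2, function(x) length(unique(x)))
  if (any(vr < 2L))
    stop("node with zero variance: ",
         paste(colnames(M)[vr < 2L], collapse = ", "))
  if (!all(M %in% c(0, 1)))
    stop("Ising nodes must be 0/1")
  invisible(TRUE)
}

# One node's L1 path + EBIC selection. p_candidates = ncol(X) (the
# predictors offered to this node).
nodewise_select <- function(X, y, family, config) {
  path <- glm_lasso_path(X, y, family = family,
                         n_lambdas = config$n_lambdas,
                         lambda_min_ratio = config$lambda_min_ratio)
  sel <- ebic_select(path, p_candidates = ncol(X), gamma = config$gamma)
  list(beta = setNames(path$beta[, sel$index], colnames(X)),
       intercept = path$intercept[sel$index], selection = sel)
}

symmetrise_edges <- function(nodewise, rule, signed_mean) {
  p <- nrow(nodewise)
  W <- matrix(0, p, p, dimnames = dimnames(nodewise))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- nodewise[i, j]; b <- nodewise[j, i]
    keep <- if (rule == "AND") (a != 0 && b != 0) else (a != 0 || b != 0)
    if (keep) {
      w <- if (signed_mean) (a + b) / 2 else (abs(a) + abs(b)) / 2
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

edge_signs <- function(nodewise, weights) {
  p <- nrow(nodewise)
  S <- matrix(0L, p, p, dimnames = dimnames(nodewise))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (weights[i, j] != 0) {
      sa <- sign(nodewise[i, j]); sb <- sign(nodewise[j, i])
      s <- if (sa == sb) sa else if (sa == 0) sb else if (sb == 0) sa else 0L
      S[i, j] <- S[j, i] <- as.integer(s)
    }
  }
  S
}

#' @export
print.morbinet_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<", class(x)[1], "> ", length(x$labels), " nodes, ", ne,
      " edges (", x$config$rule, " rule, gamma = ", x$config$gamma,
      "), n = ", x$n_fit, "\n", sep = "")
  invisible(x)
}

#' Edge list of an estimated network
#'
#' @param network an `ising_network` or `mgm_network`.
#' @param keep_zero include absent edges (default `FALSE`).
#' @return Data frame with `node_i`, `node_j`, `weight`, `sign`.
#' @export
edge_list <- function(network, keep_zero = FALSE) {
  W <- network$weights
  p <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_i = network$labels[idx[, 1]],
                    node_j = network$labels[idx[, 2]],
                    weight = W[idx],
                    sign = if (!is.null(network$signs)) network$signs[idx]
                           else as.integer(sign(W[idx])))
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
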