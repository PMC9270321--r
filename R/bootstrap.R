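#' Bootstrap accuracy of network edge weights
#'
#' Nonparametric accuracy check: rows are resampled n-out-of-n with
#' replacement, the network is refitted on each replicate, and each edge's
#' resampled weights are summarised by 2.5/50/97.5% quantiles and the
#' proportion of replicates in which the edge is retained. Replicates whose
#' refit fails are dropped and counted; more than 10% failures is an error.
#'
#' @param table node block passed to `fit_fn`.
#' @param fit_fn function taking a node block and returning a network
#'   (e.g. `function(m) fit_ising(m, config)`).
#' @param B number of bootstrap replicates (>= 50).
#' @param seed integer seed; the summary is deterministic under it.
#' @return A list of class `bootstrap_summary`: `B`, `edges` (data frame
#'   with `node_i`, `node_j`, `full_weight`, `q025`, `q50`, `q975`,
#'   `inclusion`), `n_failed`.
#' @export
bootstrap_edges <- function(table, fit_fn, B = 1000L, seed = 1L) {
  if (B < 50L) stop("B must be at least 50")
  M <- node_block(table)
  full <- fit_fn(M)
  ev_full <- edge_vector(full)
  set.seed(as.integer(seed))
  n <- nrow(M)
  reps <- matrix(NA_real_, length(ev_full), B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    net <- tryCatch(fit_fn(M[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(net)) { failed <- failed + 1L; next }
    reps[, b] <- edge_vector(net)
  }
  if (failed > 0.1 * B)
    stop("bootstrap failed on ", failed, " of ", B, " replicates")
  ok <- colSums(is.na(reps)) == 0
  q <- apply(reps[, ok, drop = FALSE], 1, quantile,
             probs = c(0.025, 0.5, 0.975))
  idx <- which(upper.tri(full$weights), arr.ind = TRUE)
  edges <- data.frame(node_i = full$labels[idx[, 1]],
                      node_j = full$labels[idx[, 2]],
                      full_weight = ev_full,
                      q025 = q[1, ], q50 = q[2, ], q975 = q[3, ],
                      inclusion = rowMeans(reps[, ok, drop = FALSE] != 0))
  structure(list(B = B, edges = edges, n_failed = failed,
                 replicates_used = sum(ok)),
            class = "bootstrap_summary")
}

#' Case-dropping stability of network edge weights
#'
#' For each drop fraction, rows are subsampled without replacement, the
#' network refitted, and the subsample edge vector correlated with the
#' full-sample one. The correlation-stability (CS) coefficient is the
#' largest drop fraction at which that correlation stays >= `cor_threshold`
#' in at least `prop_threshold` of replicates (0 when no fraction
#' qualifies). Degenerate correlations (either edge vector constant) count
#' as failures to stay above threshold.
#'
#' @param table node block passed to `fit_fn`.
#' @param fit_fn as in [bootstrap_edges()].
#' @param drop_fractions fractions of rows to drop.
#' @param B replicates per fraction.
#' @param seed integer seed.
#' @param cor_threshold,prop_threshold CS definition (defaults 0.7 and
#'   0.95, the conventional stability cut-offs).
#' @return A list of class `case_drop_stability`: `curve` (data frame with
#'   `drop`, `mean_cor`, `prop_above`), `cs_coefficient`.
#' @export
case_drop_stability <- function(table, fit_fn,
                                drop_fractions = seq(0.1, 0.7, by = 0.1),
                                B = 50L, seed = 1L,
                                cor_threshold = 0.7,
                                prop_threshold = 0.95) {
  M <- node_block(table)
  full <- fit_fn(M)
  ev_full <- edge_vector(full)
  set.seed(as.integer(seed))
  n <- nrow(M)
  curve <- data.frame(drop = drop_fractions, mean_cor = NA_real_,
                      prop_above = NA_real_)
  for (k in seq_along(drop_fractions)) {
    m <- round((1 - drop_fractions[k]) * n)
    cors <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      net <- tryCatch(fit_fn(M[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(net)) next
      ev <- edge_vector(net)
      if (sd(ev) == 0 || sd(ev_full) == 0) next   # undefined: counts failed
      cors[b] <- cor(ev, ev_full)
    }
    curve$mean_cor[k] <- if (all(is.na(cors))) NA_real_ else
      mean(cors, na.rm = TRUE)
    curve$prop_above[k] <- mean(!is.na(cors) & cors >= cor_threshold)
  }
  ok <- curve$prop_above >= prop_threshold
  cs <- if (any(ok)) max(curve$drop[ok]) else 0
  structure(list(curve = curve, cs_coefficient = cs,
                 cor_threshold = cor_threshold,
                 prop_threshold = prop_threshold, B = B),
            class = "case_drop_stability")
}

# Upper-triangle edge weights as a vector, in fixed (row, col) order.
edge_vector <- function(network) {
  network$weights[upper.tri(network$weights)]
}
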