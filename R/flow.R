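#' Flow layout: layer nodes by distance to a target
#'
#' Places the target node alone in layer 0 on the left and organises the
#' remaining nodes in layers by their unweighted shortest-path (BFS)
#' distance to the target over the network's nonzero edges, so the first
#' layer holds the nodes directly connected to the outcome and deeper
#' layers hold nodes whose association is mediated. Unreachable nodes (an
#' isolated morbidity, say) are assigned a sentinel layer one past the
#' deepest reachable one. Within each layer, vertical order comes from a
#' single barycenter pass over the previous layer's positions, which keeps
#' edges short in a drawn layout.
#'
#' @param network an `ising_network` or `mgm_network`.
#' @param target target node label (the outcome variable).
#' @return A list of class `flow_layout`: `target`, `layer` (named integer
#'   per node), `sentinel_layer`, `order` (list of label vectors per layer,
#'   in vertical order).
#' @export
flow_layers <- function(network, target) {
  labels <- network$labels
  if (!target %in% labels)
    stop("unknown target '", target, "'; nodes are: ",
         paste(labels, collapse = ", "))
  W <- network$weights != 0
  p <- length(labels)
  dist <- rep(NA_integer_, p)
  t0 <- match(target, labels)
  dist[t0] <- 0L
  frontier <- t0
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      nb <- which(W[u, ] & is.na(dist))
      dist[nb] <- dist[u] + 1L
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  max_d <- max(dist, na.rm = TRUE)
  sentinel <- max_d + 1L
  layer <- ifelse(is.na(dist), sentinel, dist)
  names(layer) <- labels

  # vertical order: layer by layer, barycenter over the previous layer
  order_by_layer <- list()
  prev_pos <- setNames(1, target)
  order_by_layer[["0"]] <- target
  for (l in seq_len(sentinel)) {
    nodes <- labels[layer == l]
    if (!length(nodes)) next
    bary <- vapply(nodes, function(v) {
      prev <- intersect(labels[W[match(v, labels), ]], names(prev_pos))
      if (!length(prev)) Inf else mean(prev_pos[prev])
    }, 0)
    nodes <- nodes[order(bary, nodes)]
    order_by_layer[[as.character(l)]] <- nodes
    prev_pos <- setNames(seq_along(nodes), nodes)
  }
  structure(list(target = target, layer = layer,
                 sentinel_layer = sentinel, order = order_by_layer),
            class = "flow_layout")
}

#' @export
print.flow_layout <- function(x, ...) {
  cat("<flow_layout> target = ", x$target, "\n", sep = "")
  for (l in names(x$order))
    cat("  layer ", l, if (as.integer(l) == x$sentinel_layer)
        " (unreachable)" else "", ": ",
        paste(x$order[[l]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
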