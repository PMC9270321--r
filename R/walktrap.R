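#' Walktrap community detection
#'
#' Agglomerative community detection from short random walks (Pons & Latapy).
#' Node distances are computed from the t-step transition probabilities,
#' r_ij^2 = sum_k (P^t_ik - P^t_jk)^2 / d_k; starting from singleton
#' communities, the pair of *adjacent* communities whose merge minimises the
#' increase in mean squared distance (Ward-style,
#' delta = |C1||C2| / (|C1| + |C2|) * r^2_{C1 C2} / n) is merged repeatedly,
#' producing a full dendrogram. Components of a disconnected graph are
#' processed independently and never merged together. The returned partition
#' cuts the dendrogram at the level of maximum Newman modularity.
#'
#' Edge weights must be non-negative: for networks with signed weights pass
#' the absolute values (the standard practice for psychometric networks).
#'
#' @param weights symmetric non-negative weight matrix, zero diagonal.
#' @param t random-walk length (default 4, the conventional choice).
#' @return A list of class `community_partition`: `labels`, `assignment`
#'   (community id per node, contiguous from 0), `dendrogram` (merge list),
#'   `modularity_profile` (modularity at each merge level, level 0 = all
#'   singletons), `chosen_level`, `modularity`.
#' @export
walktrap <- function(weights, t = 4L) {
  W <- as.matrix(weights)
  p <- nrow(W)
  if (p != ncol(W)) stop("weights must be square")
  if (any(W < 0)) stop("weights must be non-negative; pass absolute values")
  if (max(abs(W - t(W))) > 1e-10) stop("weights must be symmetric")
  if (any(diag(W) != 0)) stop("self-loops are not allowed")
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))

  d <- rowSums(W)
  P <- matrix(0, p, p)
  pos <- d > 0
  P[pos, ] <- W[pos, , drop = FALSE] / d[pos]
  Pt <- P
  if (t >= 2) for (s in seq_len(t - 1)) Pt <- Pt %*% P

  # community state: member lists and mean t-step probability profiles
  members <- as.list(seq_len(p))
  prof <- Pt                      # row c = P^t averaged over members of c
  active <- rep(TRUE, p)
  comp <- graph_components(W)
  inv_d <- ifelse(d > 0, 1 / d, 0)   # zero-degree columns contribute nothing

  adjacent <- function(a, b) {
    any(W[members[[a]], members[[b]], drop = FALSE] > 0)
  }
  delta_sigma <- function(a, b) {
    r2 <- sum((prof[a, ] - prof[b, ])^2 * inv_d)
    na <- length(members[[a]]); nb <- length(members[[b]])
    (na * nb) / (na + nb) * r2 / p
  }

  assignment_now <- function() {
    asg <- integer(p)
    ids <- which(active)
    for (k in seq_along(ids)) asg[members[[ids[k]]]] <- k - 1L
    asg
  }

  merges <- list()
  profile <- modularity(W, assignment_now())   # level 0: singletons
  repeat {
    ids <- which(active)
    if (length(ids) < 2L) break
    best <- NULL; best_ds <- Inf
    for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
      if (bi <= ai) next
      a <- ids[ai]; b <- ids[bi]
      if (comp[members[[a]][1]] != comp[members[[b]][1]]) next
      if (!adjacent(a, b)) next
      ds <- delta_sigma(a, b)
      if (ds < best_ds - 1e-15) { best_ds <- ds; best <- c(a, b) }
    }
    if (is.null(best)) break      # only cross-component pairs remain
    a <- best[1]; b <- best[2]
    na <- length(members[[a]]); nb <- length(members[[b]])
    prof[a, ] <- (na * prof[a, ] + nb * prof[b, ]) / (na + nb)
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
    merges[[length(merges) + 1L]] <- list(a = a, b = b, height = best_ds)
    profile <- c(profile, modularity(W, assignment_now()))
  }

  chosen <- which.max(profile)    # level index (1 = singletons)
  # rebuild the partition at the chosen level by replaying the merges
  members2 <- as.list(seq_len(p))
  active2 <- rep(TRUE, p)
  if (chosen > 1) for (k in seq_len(chosen - 1)) {
    m <- merges[[k]]
    members2[[m$a]] <- c(members2[[m$a]], members2[[m$b]])
    active2[m$b] <- FALSE
  }
  asg <- integer(p)
  ids <- which(active2)
  for (k in seq_along(ids)) asg[members2[[ids[k]]]] <- k - 1L

  structure(list(labels = labels,
                 assignment = setNames(asg, labels),
                 dendrogram = merges,
                 modularity_profile = profile,
                 chosen_level = chosen - 1L,
                 modularity = profile[chosen]),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", length(x$labels), " nodes, ",
      length(unique(x$assignment)), " communities, Q = ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Newman weighted modularity
#'
#' Q = (1 / 2m) sum_ij (w_ij - k_i k_j / (2m)) delta(c_i, c_j), with
#' 2m = sum(W). An all-zero weight matrix returns 0 by convention.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param assignment community id per node.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity <- function(weights, assignment) {
  W <- as.matrix(weights)
  two_m <- sum(W)
  if (two_m == 0) return(0)
  k <- rowSums(W)
  same <- outer(assignment, assignment, "==")
  sum((W - outer(k, k) / two_m) * same) / two_m
}

# Connected components over nonzero weights (BFS).
graph_components <- function(W) {
  p <- nrow(W)
  comp <- integer(p)
  cur <- 0L
  for (v in seq_len(p)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(W[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
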