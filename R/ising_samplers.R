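#' Sample binary vectors from an Ising model
#'
#' Both samplers draw subject-by-disease {0,1} matrices from the pairwise
#' model P(x) proportional to exp(sum_i tau_i x_i + sum_{i<j} theta_ij x_i x_j).
#'
#' `sample_ising_exact()` enumerates all 2^p states, normalises exactly and
#' samples i.i.d. rows from the resulting distribution; it refuses p > 15,
#' where the state table stops being enumerable, and directs the caller to
#' the Gibbs sampler. `sample_ising_gibbs()` runs a single chain of
#' single-site Gibbs sweeps with full conditional
#' P(x_i = 1 | rest) = logistic(tau_i + sum_j theta_ij x_j), discarding
#' `burn_in` sweeps and keeping every `thin`-th sweep afterwards; it scales
#' to arbitrary p at the cost of residual autocorrelation between rows.
#'
#' @param theta symmetric p x p coupling matrix with zero diagonal.
#' @param tau length-p threshold vector.
#' @param n number of rows to draw.
#' @param seed integer seed; the output is fully determined by it.
#' @param burn_in discarded initial sweeps (Gibbs only).
#' @param thin keep every `thin`-th sweep (Gibbs only).
#' @return Integer n x p matrix with entries in {0, 1}; disease names from
#'   `colnames(theta)` if present.
#' @examples
#' th <- matrix(0, 3, 3); th[1, 2] <- th[2, 1] <- 1
#' x <- sample_ising_exact(th, tau = rep(-1, 3), n = 500, seed = 1)
#' colMeans(x)
#' @export
sample_ising_exact <- function(theta, tau, n, seed) {
  check_ising_params(theta, tau)
  p <- length(tau)
  if (p > 15L)
    stop("p = ", p, " needs 2^p state enumeration, which is infeasible; ",
         "use sample_ising_gibbs() instead")
  states <- ising_states(p)
  pr <- ising_state_probs(theta, tau, states)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(states), size = n, replace = TRUE, prob = pr)
  out <- states[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, colnames(theta))
  out
}

#' @rdname sample_ising_exact
#' @export
sample_ising_gibbs <- function(theta, tau, n, burn_in = 200L, thin = 1L,
                               seed) {
  check_ising_params(theta, tau)
  if (burn_in < 1L) stop("burn_in must be >= 1")
  if (thin < 1L) stop("thin must be >= 1")
  set.seed(as.integer(seed))
  out <- .ising_gibbs_chain(theta, tau, as.integer(n), as.integer(burn_in),
                            as.integer(thin))
  dimnames(out) <- list(NULL, colnames(theta))
  out
}

check_ising_params <- function(theta, tau) {
  if (!is.matrix(theta) || nrow(theta) != ncol(theta))
    stop("theta must be a square matrix")
  if (!all(is.finite(theta)) || !all(is.finite(tau)))
    stop("theta and tau must be finite")
  if (length(tau) != nrow(theta))
    stop("length(tau) must equal nrow(theta)")
  if (max(abs(theta - t(theta))) > 1e-12)
    stop("theta must be symmetric")
  if (any(diag(theta) != 0))
    stop("theta must have a zero diagonal")
  invisible(TRUE)
}

# All 2^p states as a (2^p) x p 0/1 matrix, in binary counting order.
ising_states <- function(p) {
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  states
}

# Exactly normalised state probabilities under (theta, tau).
ising_state_probs <- function(theta, tau, states = ising_states(length(tau))) {
  S <- states
  storage.mode(S) <- "double"
  en <- drop(S %*% tau) + rowSums((S %*% theta) * S) / 2
  en <- en - max(en)
  ex <- exp(en)
  ex / sum(ex)
}
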