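#' Teleported random walk on a directed network
#'
#' Builds the row-stochastic transition matrix of a PageRank-style walk:
#' with probability `tau` the walker follows an out-edge chosen with
#' probability proportional to its weight, and with probability `1 - tau`
#' it teleports to a uniformly random node. Dangling nodes (zero
#' out-degree) teleport with probability one. Teleportation makes the
#' chain ergodic on any directed network, so the stationary distribution
#' `pi` (the PageRank vector) is unique and strictly positive.
#'
#' The walker moves along the edge orientation. In a follower network an
#' edge points from follower to followee, so the walk traces declared
#' attention; content flows the opposite way.
#'
#' @param net a [directed_network()].
#' @param tau teleportation retention in (0, 1]; default 0.85. For
#'   symmetric (undirected) connected networks `tau = 1` is appropriate
#'   since the chain is already ergodic in continuous time.
#' @param tol L1 convergence tolerance for the stationary distribution.
#' @param max_iter power-iteration cap.
#' @return A `markov_process` object: list with `A`, `tau`, `M`
#'   (row-stochastic transition matrix), `pi` (stationary distribution),
#'   `dangling` (logical vector), and `labels`.
#' @export
markov_process <- function(net, tau = 0.85, tol = 1e-12, max_iter = 1e5) {
  if (net$N < 2) stopf("network must have at least 2 nodes")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1) {
    stopf("tau must lie in (0, 1]")
  }
  A <- net$A
  N <- net$N
  out <- rowSums(A)
  dangling <- out == 0
  M <- matrix(0, N, N, dimnames = dimnames(A))
  if (any(!dangling)) {
    M[!dangling, ] <- tau * A[!dangling, , drop = FALSE] / out[!dangling] +
      (1 - tau) / N
  }
  M[dangling, ] <- 1 / N
  pi <- stationary_distribution(M, tol = tol, max_iter = max_iter)
  structure(list(A = A, tau = tau, M = M, pi = pi, dangling = dangling,
                 labels = net$labels),
            class = "markov_process")
}

#' @export
print.markov_process <- function(x, ...) {
  cat(sprintf(
    "markov_process: %d states, tau = %g, %d dangling, max pi = %.4g\n",
    length(x$pi), x$tau, sum(x$dangling), max(x$pi)))
  invisible(x)
}

# Power iteration for the left stationary vector of a row-stochastic M.
stationary_distribution <- function(M, tol = 1e-12, max_iter = 1e5) {
  N <- nrow(M)
  pi <- rep(1 / N, N)
  for (i in seq_len(max_iter)) {
    new <- as.vector(pi %*% M)
    new <- new / sum(new)
    if (sum(abs(new - pi)) < tol) {
      pi <- new
      break
    }
    pi <- new
  }
  names(pi) <- rownames(M)
  pi
}

#' Continuous-time propagator
#'
#' `P(t) = expm(t (M - I))`: the transition kernel of the continuous-time
#' walk whose jump chain is `M`, after Markov time `t`. `P(0)` is the
#' identity; as `t` grows every row converges to the stationary
#' distribution.
#'
#' @param proc a [markov_process()].
#' @param t Markov time, non-negative.
#' @return dense row-stochastic matrix `P(t)`.
#' @export
propagator <- function(proc, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0) stopf("t must be >= 0")
  N <- length(proc$pi)
  if (t == 0) {
    P <- diag(N)
    dimnames(P) <- dimnames(proc$M)
    return(P)
  }
  L <- proc$M
  diag(L) <- diag(L) - 1
  P <- as.matrix(Matrix::expm(Matrix::Matrix(t * L)))
  dimnames(P) <- dimnames(proc$M)
  P
}

#' Symmetric stability quality matrix
#'
#' `B(t) = (Pi P(t) + P(t)' Pi) / 2 - pi pi'` where `Pi = diag(pi)`.
#' Every row and column of `B(t)` sums to zero, and for any partition
#' indicator `H` the stability equals `trace(H' B(t) H)`; the
#' symmetrization leaves that trace unchanged, which lets an undirected
#' quality optimizer work on directed flows.
#'
#' @param proc a [markov_process()].
#' @param t Markov time.
#' @return symmetric matrix `B(t)`.
#' @export
quality_matrix <- function(proc, t) {
  P <- propagator(proc, t)
  PiP <- proc$pi * P            # diag(pi) %*% P
  B <- (PiP + t(PiP)) / 2 - tcrossprod(proc$pi)
  dimnames(B) <- dimnames(proc$M)
  B
}

#' Markov Stability of a partition
#'
#' `r(t, H) = trace(H' (Pi P(t) - pi pi') H)`: the probability that a
#' walker started at stationarity remains in (or has returned to) its
#' starting community after Markov time `t`, in excess of the stationary
#' baseline. High stability means the partition's communities contain and
#' reinforce flow over horizon `t`.
#'
#' @param proc a [markov_process()].
#' @param partition named vector mapping each node label to a community.
#' @param t Markov time.
#' @return numeric stability value.
#' @export
stability <- function(proc, partition, t) {
  part <- partition_vector(partition, proc$labels)
  P <- propagator(proc, t)
  PiP <- proc$pi * P
  C <- PiP - tcrossprod(proc$pi)
  sum(vapply(split(seq_along(part), part),
             function(ix) sum(C[ix, ix]), numeric(1)))
}

# Align a partition (named or positional) to a label order; errors when a
# label is missing.
partition_vector <- function(partition, labels) {
  if (!is.null(names(partition))) {
    miss <- setdiff(labels, names(partition))
    if (length(miss) > 0) stopf("partition misses node(s): %s",
                                paste(utils::head(miss, 5), collapse = ", "))
    partition <- partition[labels]
  } else if (length(partition) != length(labels)) {
    stopf("unnamed partition must have one entry per node")
  }
  as.integer(as.factor(partition))
}
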