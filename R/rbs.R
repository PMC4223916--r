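#' Spectral radius of a non-negative adjacency matrix
#'
#' Direct power iteration on `A` (no symmetrization), run on the shifted
#' matrix `A + I` so that periodic structure (e.g. pure cycles) does not
#' stall convergence: for non-negative `A` the spectral radius of `A + I`
#' is `1 + rho(A)` and the shifted iteration is aperiodic. Restarts with a
#' perturbed vector guard against starting vectors orthogonal to the
#' leading direction; a nilpotent (DAG) adjacency returns 0.
#'
#' @param A square non-negative matrix.
#' @param tol convergence tolerance on the eigenvalue estimate.
#' @param max_iter iteration cap per restart.
#' @return the spectral radius (a non-negative number).
#' @export
leading_eigenvalue <- function(A, tol = 1e-10, max_iter = 1e5) {
  A <- as.matrix(A)
  if (any(A < 0)) stopf("A must be non-negative")
  n <- nrow(A)
  if (n == 0 || all(A == 0)) return(0)
  # nilpotency check: A is non-negative, so A^n 1 = 0 iff A is nilpotent
  # (a DAG adjacency); the shifted power iteration would converge only
  # polynomially there, so short-circuit to an exact 0.
  z <- rep(1, n)
  for (k in seq_len(n)) {
    z <- as.vector(A %*% z)
    if (max(z) == 0) return(0)
  }
  for (restart in 1:3) {
    x <- rep(1, n) + (restart - 1) * seq_len(n) / n  # deterministic restarts
    x <- x / sqrt(sum(x^2))
    lambda <- 0
    for (it in seq_len(max_iter)) {
      y <- as.vector(A %*% x) + x          # (A + I) x
      ny <- sqrt(sum(y^2))
      if (ny == 0) return(0)               # nilpotent direction collapsed
      lam_new <- ny - 1                    # rho(A + I) = rho(A) + 1
      x <- y / ny
      if (abs(lam_new - lambda) < tol) return(max(lam_new, 0))
      lambda <- lam_new
    }
  }
  max(lambda, 0)
}

#' Role-based similarity feature matrix
#'
#' Each node's feature vector collects the number of incoming and
#' outgoing walks of every length `1 .. K_max` that touch it, scaled
#' geometrically so that "all lengths" converges: column `k` of the
#' incoming block is `alpha^k * (t(A)^k 1)` and of the outgoing block
#' `alpha^k * (A^k 1)`, with `alpha = beta / lambda1` and `lambda1` the
#' spectral radius of `A`. Columns 1 and `K_max + 1` are the (scaled) in-
#' and out-degrees; the last column of each block approaches an
#' eigencentrality-type stationary flow metric. Dividing column `k` by
#' `alpha^k` recovers integer walk counts on unweighted networks. For a
#' nilpotent (DAG) adjacency `alpha` defaults to 1, since only finitely
#' many walk lengths are non-zero.
#'
#' @param net a [directed_network()].
#' @param beta geometric decay in (0, 1); default 0.87, which under the
#'   auto-stop rule keeps walk lengths up to roughly 130 before the
#'   column norms fall below the cutoff.
#' @param k_max integer cap on walk length, or `"auto"` to stop at the
#'   first length whose columns have decayed below `1e-8` of the largest
#'   earlier column (capped at `4 * N`).
#' @return A `flow_feature_matrix`: list with `X` (N x 2 K_max, incoming
#'   block first), `alpha`, `beta`, `lambda1`, `k_max`, `labels`.
#' @export
build_feature_matrix <- function(net, beta = 0.87, k_max = "auto") {
  if (net$N < 2) stopf("network must have at least 2 nodes")
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) stopf("beta must lie in (0, 1)")
  A <- net$A
  N <- net$N
  lambda1 <- leading_eigenvalue(A)
  alpha <- if (lambda1 > 0) beta / lambda1 else 1
  auto <- identical(k_max, "auto")
  cap <- if (auto) 4L * N else as.integer(k_max)
  if (cap < 1) stopf("k_max must be >= 1")
  v <- rep(1, N)  # incoming-walk accumulator
  w <- rep(1, N)  # outgoing-walk accumulator
  vs <- vector("list", cap)
  ws <- vector("list", cap)
  peak <- 0
  used <- 0L
  for (k in seq_len(cap)) {
    v <- alpha * as.vector(crossprod(A, v))  # alpha * t(A) %*% v
    w <- alpha * as.vector(A %*% w)
    mk <- max(max(abs(v)), max(abs(w)))
    if (auto && used > 0 && mk < 1e-8 * peak) break
    vs[[k]] <- v
    ws[[k]] <- w
    used <- k
    peak <- max(peak, mk)
  }
  X <- cbind(do.call(cbind, vs[seq_len(used)]),
             do.call(cbind, ws[seq_len(used)]))
  rownames(X) <- net$labels
  colnames(X) <- c(paste0("in_", seq_len(used)), paste0("out_", seq_len(used)))
  structure(list(X = X, alpha = alpha, beta = beta, lambda1 = lambda1,
                 k_max = used, labels = net$labels),
            class = "flow_feature_matrix")
}

#' @export
print.flow_feature_matrix <- function(x, ...) {
  cat(sprintf(
    "flow_feature_matrix: %d nodes, K_max = %d (2*%d columns), alpha = %.6g\n",
    nrow(x$X), x$k_max, x$k_max, x$alpha))
  invisible(x)
}

#' Unscaled walk counts from a feature matrix
#'
#' Divides each column by `alpha^k` to recover raw walk counts (integers
#' on unweighted networks).
#'
#' @param Xf a `flow_feature_matrix`.
#' @return matrix of the same shape as `Xf$X`.
#' @export
unscaled_counts <- function(Xf) {
  K <- Xf$k_max
  scale <- Xf$alpha^c(seq_len(K), seq_len(K))
  sweep(Xf$X, 2, scale, "/")
}

#' Cosine similarity matrix of flow features
#'
#' `y_ij = <x_i, x_j> / (||x_i|| ||x_j||)` over the rows of the feature
#' matrix. Since features are non-negative, similarities lie in
#' `[0, 1]`. Nodes whose feature rows are entirely zero (isolated nodes)
#' get similarity 0 to everything and 1 to themselves.
#'
#' @param Xf a `flow_feature_matrix` (or a plain non-negative matrix whose
#'   rows are feature vectors).
#' @return symmetric N x N similarity matrix with unit diagonal.
#' @export
cosine_similarity <- function(Xf) {
  X <- if (inherits(Xf, "flow_feature_matrix")) Xf$X else as.matrix(Xf)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  Xn <- X / nrm
  Y <- tcrossprod(Xn)
  Y[zero, ] <- 0
  Y[, zero] <- 0
  Y <- pmin(pmax(Y, 0), 1)
  diag(Y) <- 1
  Y <- (Y + t(Y)) / 2
  rownames(Y) <- colnames(Y) <- rownames(X)
  Y
}
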