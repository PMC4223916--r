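#' Greedy multilevel optimization of a generalized quality matrix
#'
#' Maximizes `trace(H' B H)` over partitions with indicator matrix `H`,
#' where `B` is any symmetric matrix whose rows sum to (approximately)
#' zero — the null model is already folded into `B`, so the same optimizer
#' serves Markov Stability at every time and on both directed and
#' undirected networks. The algorithm is the Louvain heuristic: repeated
#' single-node moves in a seed-shuffled order (strictly positive gains
#' only), followed by aggregation of communities into supernodes, until no
#' move improves the objective. A final pass merges community pairs whose
#' merge changes the objective by less than `tol`, so exact ties (e.g. an
#' all-zero matrix) resolve toward the coarser partition.
#'
#' @param B symmetric quality matrix (asymmetry beyond 1e-10 is an error).
#' @param seed integer seed controlling the node sweep order; the result
#'   is deterministic given `seed`.
#' @param tol gain threshold: moves must improve the objective by more
#'   than `tol`; merges within `tol` of zero are applied. Default 1e-12.
#' @return canonical partition (named if `B` has dimnames) with attribute
#'   `"objective"` holding `trace(H' B H)`.
#' @export
louvain_optimize <- function(B, seed = 1L, tol = 1e-12) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stopf("B must be square")
  if (max(abs(B - t(B))) > 1e-10) stopf("B must be symmetric (tolerance 1e-10)")
  labels <- rownames(B)
  N <- nrow(B)
  membership <- seq_len(N)  # original node -> current supernode
  Bc <- B
  with_seed(seed, {
    repeat {
      lev <- louvain_level(Bc, tol)
      if (!lev$moved) break
      membership <- lev$comm[membership]
      Bc <- aggregate_quality(Bc, lev$comm)
      if (nrow(Bc) == 1) break
    }
    # tie-breaking merge pass toward coarser partitions
    repeat {
      n <- nrow(Bc)
      if (n == 1) break
      merged <- FALSE
      for (c1 in seq_len(n - 1)) {
        delta <- 2 * Bc[c1, (c1 + 1):n]
        hit <- which(delta > -tol)
        if (length(hit) > 0) {
          c2 <- c1 + hit[1]
          comm <- seq_len(n)
          comm[c2] <- c1
          comm <- match(comm, unique(comm))
          membership <- comm[membership]
          Bc <- aggregate_quality(Bc, comm)
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  })
  part <- membership
  names(part) <- labels
  out <- canonicalize_partition(part)
  attr(out, "objective") <- sum(diag(Bc))
  out
}

# One Louvain level: local moves until no strictly improving move exists.
# Returns consecutive community ids and whether anything moved.
louvain_level <- function(B, tol) {
  n <- nrow(B)
  comm <- seq_len(n)
  moved_any <- FALSE
  diagB <- diag(B)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      s <- rowsum(B[i, ], comm)           # community-wise link sums to i
      ids <- as.integer(rownames(s))
      a <- comm[i]
      s_a <- s[match(a, ids), 1]
      gains <- 2 * (s[, 1] - (s_a - diagB[i]))
      gains[match(a, ids)] <- 0
      best <- which.max(gains)             # ties -> smallest community id
      if (gains[best] > tol) {
        comm[i] <- ids[best]
        moved <- TRUE
      }
    }
    moved_any <- moved_any || moved
    if (!moved) break
  }
  list(comm = match(comm, sort(unique(comm))), moved = moved_any)
}

# Aggregate B over communities: B' = H' B H.
aggregate_quality <- function(B, comm) {
  Br <- rowsum(B, comm)
  t(rowsum(t(Br), comm))
}
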