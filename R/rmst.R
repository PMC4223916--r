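#' Convert cosine similarities to chord distances
#'
#' `d_ij = sqrt(2 (1 - y_ij))`: the exact Euclidean distance between the
#' unit-normalized feature vectors whose inner product is `y_ij`. Identical
#' profiles get distance 0, orthogonal ones `sqrt(2)`.
#'
#' @param Y symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]` (values outside `[-1, 1]` beyond 1e-9 are an error).
#' @return symmetric distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(Y) {
  Y <- as.matrix(Y)
  if (max(abs(Y)) > 1 + 1e-9) stopf("similarities must lie in [-1, 1]")
  D <- sqrt(2 * pmax(1 - Y, 0))
  diag(D) <- 0
  (D + t(D)) / 2
}

# Kruskal MST on a full distance matrix; ties broken by lexicographic
# (i, j) edge order so the result is stable under node permutation with
# canonical relabeling. Returns a matrix of edges (i, j, d) with i < j.
mst_edges <- function(D) {
  n <- nrow(D)
  ut <- which(upper.tri(D))
  i <- (ut - 1) %% n + 1
  j <- (ut - 1) %/% n + 1
  d <- D[ut]
  ord <- order(d, i, j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  sel <- integer(0)
  for (e in ord) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      sel <- c(sel, e)
      if (length(sel) == n - 1) break
    }
  }
  cbind(i = i[sel], j = j[sel], d = d[sel])
}

#' Maximum link weights over a spanning tree
#'
#' For every node pair, the largest edge weight on the unique tree path
#' between them (the minimax/bottleneck value when the tree is a minimum
#' spanning tree). Computed by one tree traversal per root in `O(N^2)`.
#'
#' @param edges matrix or data frame with columns `i`, `j`, `d` listing
#'   the `N - 1` edges of a spanning tree over nodes `1..N`.
#' @param n number of nodes; defaults to the largest endpoint index.
#' @return symmetric N x N matrix of maximum link values, zero diagonal.
#' @export
mlink_all_pairs <- function(edges, n = NULL) {
  edges <- as.matrix(edges)
  if (is.null(n)) n <- max(edges[, 1:2])
  if (nrow(edges) != n - 1) stopf("input is not a spanning tree (%d edges for %d nodes)",
                                  nrow(edges), n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]; d <- edges[e, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  M <- matrix(0, n, n)
  seen_all <- TRUE
  for (root in seq_len(n)) {
    # BFS from root, carrying the running maximum edge weight
    visited <- logical(n)
    visited[root] <- TRUE
    frontier <- root
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- adj[[u]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
          v <- nb[r, 1]
          if (!visited[v]) {
            visited[v] <- TRUE
            M[root, v] <- max(M[root, u], nb[r, 2])
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    if (!all(visited)) seen_all <- FALSE
  }
  if (!seen_all) stopf("input is not a spanning tree (disconnected)")
  M
}

#' Relaxed minimum spanning tree graph from a distance matrix
#'
#' Keeps every MST edge, plus any pair `(i, j)` whose direct distance is
#' beaten by the tree's bottleneck path once a local-scale relaxation is
#' allowed: the edge is included iff
#' `mlink_ij + gamma * (d_i + d_j) > d_ij`, where `mlink_ij` is the
#' largest edge on the MST path between `i` and `j` and `d_i` is the
#' distance from `i` to its nearest neighbour. The construction keeps
#' strong similarities and discards weaker, redundant ones that the tree
#' already explains: the result is connected for every `gamma >= 0`, and
#' its edge set grows monotonically with `gamma` (from the bare MST at
#' `gamma = 0` when distances are distinct, toward the complete graph for
#' large `gamma`).
#'
#' @param D symmetric distance matrix with zero diagonal (typically from
#'   [similarity_to_distance()]).
#' @param gamma relaxation parameter `>= 0`; default 0.5.
#' @param knn number of nearest neighbours averaged for the local scale
#'   `d_i`; default 1 (the single nearest neighbour).
#' @param Y optional similarity matrix; output edge weights are then the
#'   similarities `y_ij = 1 - d_ij^2 / 2` by default.
#' @return A `role_similarity_graph`: list with `S` (symmetric weighted
#'   adjacency of the kept edges), `edges` (data frame i, j, distance,
#'   similarity, in_mst), `D`, `mst`, `d_local`, `gamma`, `labels`.
#' @export
rmst <- function(D, gamma = 0.5, knn = 1, Y = NULL) {
  D <- as.matrix(D)
  if (gamma < 0) stopf("gamma must be >= 0")
  if (max(abs(D - t(D))) > 1e-10) stopf("D must be symmetric")
  if (any(diag(D) != 0)) stopf("D must have zero diagonal")
  n <- nrow(D)
  labels <- rownames(D) %||% paste0("V", seq_len(n))
  if (is.null(Y)) Y <- 1 - D^2 / 2
  degenerate_all <- max(D) <= 1e-12
  tree <- mst_edges(D)
  ml <- mlink_all_pairs(tree, n)
  offd <- D
  diag(offd) <- Inf
  d_local <- apply(offd, 1, function(r) mean(sort(r)[seq_len(knn)]))
  keep <- ml + gamma * outer(d_local, d_local, "+") > D
  # fully degenerate input (all profiles identical): there is no geometry
  # to sparsify, and a tree would break the symmetry arbitrarily — keep
  # the complete graph instead
  if (degenerate_all) keep[] <- TRUE
  keep[cbind(tree[, 1], tree[, 2])] <- TRUE
  keep[cbind(tree[, 2], tree[, 1])] <- TRUE
  keep <- keep & t(keep)
  diag(keep) <- FALSE
  S <- matrix(0, n, n, dimnames = list(labels, labels))
  S[keep] <- Y[keep]
  in_mst <- matrix(FALSE, n, n)
  in_mst[cbind(tree[, 1], tree[, 2])] <- TRUE
  ut <- which(keep & upper.tri(keep))
  ei <- (ut - 1) %% n + 1
  ej <- (ut - 1) %/% n + 1
  edges <- data.frame(i = ei, j = ej, distance = D[ut], similarity = Y[ut],
                      in_mst = in_mst[ut] | t(in_mst)[ut])
  structure(list(S = S, edges = edges, D = D, mst = tree,
                 d_local = d_local, gamma = gamma, labels = labels),
            class = "role_similarity_graph")
}

#' @export
print.role_similarity_graph <- function(x, ...) {
  cat(sprintf(
    "role_similarity_graph: %d nodes, %d edges (%d in MST), gamma = %g\n",
    length(x$labels), nrow(x$edges), sum(x$edges$in_mst), x$gamma))
  invisible(x)
}

#' View a role similarity graph as an undirected network
#' @param rsg a `role_similarity_graph`.
#' @return a [directed_network()] with symmetric (similarity-weighted)
#'   adjacency, suitable for [stability_sweep()].
#' @export
rsg_as_network <- function(rsg) directed_network(rsg$S, rsg$labels)
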