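# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: series expansion instead of expm, recursive
# enumeration instead of matrix powers, exhaustive search instead of
# heuristics.

# Matrix exponential by scaling-and-squaring with a long Taylor series.
expm_series <- function(M, squarings = 20, terms = 60) {
  n <- nrow(M)
  Ms <- M / 2^squarings
  P <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% Ms / k
    P <- P + term
  }
  for (s in seq_len(squarings)) P <- P %*% P
  P
}

# Stability as an explicit double sum over node pairs.
stability_bruteforce <- function(proc, partition, t) {
  P <- propagator(proc, t)
  part <- partition[proc$labels]
  total <- 0
  n <- length(proc$pi)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (part[i] == part[j]) {
        total <- total + proc$pi[i] * P[i, j] - proc$pi[i] * proc$pi[j]
      }
    }
  }
  unname(total)
}

# All set partitions of seq_len(n) as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_max) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible(NULL))
    }
    for (g in seq_len(next_max + 1)) {
      rec(c(assign, g), max(next_max, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# Number of directed walks of length k ending at (mode = "in") or starting
# from (mode = "out") each node, by recursive neighbour enumeration.
walk_counts_enum <- function(A, k, mode = c("out", "in")) {
  mode <- match.arg(mode)
  n <- nrow(A)
  count_from <- function(v, steps) {
    if (steps == 0) return(1)
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sum(vapply(nb, function(u) A[v, u] * count_from(u, steps - 1), numeric(1)))
  }
  count_to <- function(v, steps) {
    if (steps == 0) return(1)
    nb <- which(A[, v] > 0)
    if (length(nb) == 0) return(0)
    sum(vapply(nb, function(u) A[u, v] * count_to(u, steps - 1), numeric(1)))
  }
  f <- if (mode == "out") count_from else count_to
  vapply(seq_len(n), f, numeric(1), steps = k)
}

# Maximum edge weight on the unique path between two tree nodes, found by
# exhaustive depth-first path search.
tree_path_max <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (e in seq_len(nrow(edges))) {
    i <- as.character(edges[e, 1]); j <- as.character(edges[e, 2])
    adj[[i]] <- rbind(adj[[i]], c(edges[e, 2], edges[e, 3]))
    adj[[j]] <- rbind(adj[[j]], c(edges[e, 1], edges[e, 3]))
  }
  found <- NULL
  dfs <- function(v, target, visited, best) {
    if (v == target) {
      found <<- best
      return(TRUE)
    }
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) return(FALSE)
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (!(u %in% visited)) {
        if (dfs(u, target, c(visited, u), max(best, nb[r, 2]))) return(TRUE)
      }
    }
    FALSE
  }
  dfs(from, to, from, 0)
  found
}

# Random weakly-connected digraph for property tests.
random_digraph <- function(n, p = 0.3, seed = 1, weighted = FALSE) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
      diag(A) <- 0
      if (weighted) A <- A * matrix(stats::runif(n * n, 0.5, 2), n, n)
      g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "directed")
      if (igraph::is_connected(g, mode = "weak")) break
    }
    directed_network(A)
  })
}

# Random partition over given labels.
random_partition <- function(labels, k, seed = 1) {
  withr::with_seed(seed, {
    p <- sample(seq_len(k) - 1L, length(labels), replace = TRUE)
    names(p) <- labels
    canonicalize_partition(p)
  })
}
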