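#' Planted-partition directed stochastic block model
#'
#' Independent Bernoulli directed edges for every ordered node pair, with
#' probability `p_in` when both endpoints share a block and `p_out`
#' otherwise. The generator retries with derived seeds (up to 20
#' attempts) until the realization is weakly connected, and returns the
#' planted partition alongside the network so tests never re-derive the
#' ground truth.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability.
#' @param seed integer seed; fixed seed gives a bit-identical network.
#' @return list with `net` (a [directed_network()]) and `partition`
#'   (named canonical partition of the planted blocks).
#' @export
generate_directed_sbm <- function(block_sizes, p_in = 0.3, p_out = 0.02,
                                  seed = 1L) {
  check_block_spec(block_sizes, p_in, p_out)
  N <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  P <- matrix(p_out, N, N)
  same <- outer(block, block, "==")
  P[same] <- p_in
  diag(P) <- 0
  for (attempt in 1:20) {
    A <- with_seed(derive_seed(seed, attempt - 1L), {
      matrix(as.numeric(stats::runif(N * N) < P), N, N)
    })
    net <- directed_network(A, node_names(N))
    if (is_weakly_connected(net)) {
      part <- canonicalize_partition(stats::setNames(block, net$labels))
      return(list(net = net, partition = part))
    }
  }
  stopf("could not generate a weakly connected network in 20 attempts; increase p_in/p_out")
}

#' Flow-trap generator: communities invisible to symmetrization
#'
#' Emulates groupings that exist only through retention of directed flow.
#' Within each block, edges follow a consistent cyclic orientation over a
#' random ordering of the block's nodes, so walkers circulate and are
#' retained. Every between-block pair receives at most one single-direction
#' edge, with total pair probability equal to `p_in`: with probability
#' `p_in - p_out` it points from the later block to the earlier one (the
#' earlier blocks act as attractors of attention, like heavily followed
#' media accounts) and with probability `p_out` the other way. In
#' expectation every unordered pair therefore carries the same edge
#' probability, the symmetrized network is a homogeneous random graph with
#' uniform expected degree — carrying no community signal — while the
#' directed flow is funnelled into and trapped within blocks.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in within-block (and total cross-pair) edge probability.
#' @param p_out probability of a "backward" cross edge (earlier block to
#'   later block); must not exceed `p_in`.
#' @param seed integer seed.
#' @return list with `net` and `partition` as in
#'   [generate_directed_sbm()].
#' @export
generate_flow_trap <- function(block_sizes, p_in = 0.5, p_out = 0.05,
                               seed = 1L) {
  check_block_spec(block_sizes, p_in, p_out)
  if (p_out > p_in) stopf("p_out must not exceed p_in")
  N <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  for (attempt in 1:20) {
    A <- with_seed(derive_seed(seed, attempt - 1L), {
      A <- matrix(0, N, N)
      # cyclic orientation within each block over a random node ordering
      for (b in seq_along(block_sizes)) {
        idx <- which(block == b)
        nb <- length(idx)
        if (nb < 2) next
        pos <- sample(nb)               # node -> position on the circle
        for (u in seq_len(nb - 1)) {
          for (v in (u + 1):nb) {
            if (stats::runif(1) < p_in) {
              gap <- (pos[v] - pos[u]) %% nb
              if (gap > 0 && gap <= nb / 2) {
                A[idx[u], idx[v]] <- 1   # forward along the circulation
              } else {
                A[idx[v], idx[u]] <- 1
              }
            }
          }
        }
      }
      # single-direction cross edges, biased toward earlier blocks
      for (u in seq_len(N - 1)) {
        for (v in (u + 1):N) {
          if (block[u] == block[v]) next
          r <- stats::runif(1)
          lo <- if (block[u] < block[v]) u else v  # earlier-block endpoint
          hi <- if (block[u] < block[v]) v else u
          if (r < p_in - p_out) {
            A[hi, lo] <- 1               # later block follows earlier
          } else if (r < p_in) {
            A[lo, hi] <- 1
          }
        }
      }
      A
    })
    net <- directed_network(A, node_names(N))
    if (is_weakly_connected(net)) {
      part <- canonicalize_partition(stats::setNames(block, net$labels))
      return(list(net = net, partition = part))
    }
  }
  stopf("could not generate a weakly connected network in 20 attempts; increase p_in/p_out")
}

#' Planted flow-role generator
#'
#' Bernoulli edges per ordered class pair, edge = follower -> followee.
#' The default template plants three role classes spanning the
#' reference-to-listener spectrum: 20 references (heavily followed,
#' follow nobody), 20 mediators (professionally attentive accounts that
#' follow every reference and each other with probability 0.5) and 60
#' listeners (passive recipients who follow references with probability
#' 0.9 and have no followers). The template keeps each class homogeneous
#' in its walk-count profile: listeners sit outside every cycle so their
#' features reduce to a pure out-degree spike (identical direction for
#' every member); mediators carry the only recurrent flow (long in/out
#' tails); references show long incoming tails with no outgoing paths,
#' and because all mediators follow all references those tails are
#' identical across the class.
#'
#' @param class_sizes named or unnamed integer vector of class sizes;
#'   default `c(references = 20, mediators = 20, listeners = 60)`.
#' @param wiring square matrix of follower-class -> followee-class edge
#'   probabilities; rows index the follower class. Default template
#'   described above.
#' @param seed integer seed.
#' @return list with `net` and `roles` (named canonical role vector,
#'   class order preserved).
#' @export
generate_role_planted <- function(class_sizes = c(references = 20,
                                                  mediators = 20,
                                                  listeners = 60),
                                  wiring = NULL, seed = 1L) {
  if (is.null(wiring)) {
    wiring <- rbind(references = c(0, 0, 0),
                    mediators  = c(1, 0.5, 0),
                    listeners  = c(0.9, 0, 0))
  }
  wiring <- as.matrix(wiring)
  if (nrow(wiring) != length(class_sizes) || ncol(wiring) != length(class_sizes)) {
    stopf("wiring must be a %d x %d matrix", length(class_sizes),
          length(class_sizes))
  }
  if (any(wiring < 0 | wiring > 1)) stopf("wiring probabilities must lie in [0, 1]")
  N <- sum(class_sizes)
  cls <- rep(seq_along(class_sizes), class_sizes)
  P <- wiring[cls, cls]
  diag(P) <- 0
  for (attempt in 1:20) {
    A <- with_seed(derive_seed(seed, attempt - 1L), {
      matrix(as.numeric(stats::runif(N * N) < P), N, N)
    })
    net <- directed_network(A, node_names(N))
    if (is_weakly_connected(net)) {
      roles <- canonicalize_partition(stats::setNames(cls, net$labels))
      return(list(net = net, roles = roles))
    }
  }
  stopf("could not generate a weakly connected network in 20 attempts; increase wiring probabilities")
}

#' Deterministic toy networks
#'
#' Canonical small graphs used across the example and test suites.
#'
#' @param name one of `"cycle"`, `"path"`, `"star_in"`, `"star_out"`,
#'   `"ring_of_cliques"`.
#' @param n number of nodes (for `ring_of_cliques`: number of cliques).
#' @param clique_size nodes per clique (`ring_of_cliques` only).
#' @return a [directed_network()].
#' @export
toy <- function(name = c("cycle", "path", "star_in", "star_out",
                         "ring_of_cliques"),
                n = 3, clique_size = 5) {
  name <- match.arg(name)
  if (name == "ring_of_cliques") {
    N <- n * clique_size
    A <- matrix(0, N, N)
    for (c in seq_len(n)) {
      idx <- (c - 1) * clique_size + seq_len(clique_size)
      A[idx, idx] <- 1
      nxt <- (c %% n) * clique_size + 1
      A[idx[clique_size], nxt] <- 1  # single directed bridge to next clique
    }
    diag(A) <- 0
    return(directed_network(A, node_names(N)))
  }
  if (n < 2) stopf("toy networks need n >= 2")
  A <- matrix(0, n, n)
  if (name == "cycle") {
    for (i in seq_len(n)) A[i, i %% n + 1] <- 1
  } else if (name == "path") {
    for (i in seq_len(n - 1)) A[i, i + 1] <- 1
  } else if (name == "star_in") {
    A[2:n, 1] <- 1   # leaves point at the hub
  } else if (name == "star_out") {
    A[1, 2:n] <- 1
  }
  directed_network(A, node_names(n))
}

node_names <- function(N) sprintf("n%03d", seq_len(N))

is_weakly_connected <- function(net) {
  igraph::is_connected(as_igraph(net), mode = "weak")
}

check_block_spec <- function(block_sizes, p_in, p_out) {
  if (length(block_sizes) < 1 || any(block_sizes < 1)) {
    stopf("block_sizes must be positive integers")
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stopf("probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}
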