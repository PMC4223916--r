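fixture_nets <- function() {
  names <- c("digraph_feedback.tsv", "digraph_hub.tsv", "digraph_dag.tsv")
  lapply(names, function(nm)
    read_edge_list(system.file("extdata", nm, package = "flowscope")))
}

test_that("leading eigenvalue matches a dense eigensolver and handles cycles and DAGs", {
  expect_equal(leading_eigenvalue(toy("cycle", 3)$A), 1, tolerance = 1e-9)
  # reciprocal pair
  A2 <- rbind(c(0, 1), c(1, 0))
  expect_equal(leading_eigenvalue(A2), 1, tolerance = 1e-9)
  # star plus chord vs dense eigendecomposition oracle
  A4 <- matrix(0, 4, 4)
  A4[1, 2:4] <- 1; A4[2, 1] <- 1; A4[3, 4] <- 1
  expect_equal(leading_eigenvalue(A4),
               max(abs(eigen(A4, only.values = TRUE)$values)),
               tolerance = 1e-8)
  # nilpotent (DAG) adjacency
  dag <- matrix(0, 3, 3); dag[1, 2] <- dag[2, 3] <- 1
  expect_equal(leading_eigenvalue(dag), 0, tolerance = 1e-9)
  # random weighted digraphs vs oracle
  for (s in 1:5) {
    A <- random_digraph(9, p = 0.3, seed = 40 + s, weighted = TRUE)$A
    expect_equal(leading_eigenvalue(A),
                 max(abs(eigen(A, only.values = TRUE)$values)),
                 tolerance = 1e-8)
  }
})

test_that("unscaled feature columns equal exhaustive walk-count enumeration", {
  for (net in fixture_nets()) {
    Xf <- build_feature_matrix(net, beta = 0.87, k_max = 4)
    counts <- unscaled_counts(Xf)
    K <- Xf$k_max
    for (k in seq_len(min(K, 4))) {
      expect_equal(unname(counts[, k]),
                   walk_counts_enum(net$A, k, "in"), tolerance = 1e-9)
      expect_equal(unname(counts[, K + k]),
                   walk_counts_enum(net$A, k, "out"), tolerance = 1e-9)
    }
  }
})

test_that("path endpoints carry the expected zero/one counts on a 3-path", {
  net <- read_edge_list(system.file("extdata", "toy_path.tsv",
                                    package = "flowscope"))
  Xf <- build_feature_matrix(net, k_max = 2)   # a->b->c, alpha = 1 (DAG)
  counts <- unscaled_counts(Xf)
  expect_equal(unname(counts["a", c("out_1", "out_2")]), c(1, 1))
  expect_equal(unname(counts["c", c("out_1", "out_2")]), c(0, 0))
  expect_equal(unname(counts["c", c("in_1", "in_2")]), c(1, 1))
  expect_equal(unname(counts["a", c("in_1", "in_2")]), c(0, 0))
  expect_equal(Xf$alpha, 1)  # nilpotent adjacency
})

test_that("auto k_max stops once columns decay and beta is validated", {
  net <- random_digraph(20, p = 0.25, seed = 51)
  Xf <- build_feature_matrix(net, beta = 0.5, k_max = "auto")
  expect_lt(Xf$k_max, 4 * net$N)
  expect_gte(Xf$k_max, 10)   # geometric decay at 0.5 reaches 1e-8 near k=27
  expect_true(all(Xf$X >= 0))
  expect_error(build_feature_matrix(net, beta = 1.2), "beta")
})

test_that("cosine similarity matches a naive pairwise oracle and its structural cases", {
  net <- random_digraph(8, p = 0.35, seed = 53, weighted = TRUE)
  Xf <- build_feature_matrix(net, k_max = 6)
  Y <- cosine_similarity(Xf)
  # naive double loop
  X <- Xf$X
  for (i in 1:8) {
    for (j in 1:8) {
      expected <- sum(X[i, ] * X[j, ]) /
        (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
      expect_equal(Y[i, j], min(expected, 1), tolerance = 1e-12)
    }
  }
  expect_equal(max(abs(Y - t(Y))), 0)
  expect_equal(unname(diag(Y)), rep(1, 8))
  expect_true(all(Y >= 0 & Y <= 1))

  # vertex-transitive cycle: all rows identical -> all similarities 1
  Yc <- cosine_similarity(build_feature_matrix(toy("cycle", 5)))
  expect_equal(max(abs(Yc - 1)), 0, tolerance = 1e-12)

  # 2-node path with K_max = 1: features orthogonal
  p2 <- network_from_edges(data.frame(s = "a", t = "b"))
  Y2 <- cosine_similarity(build_feature_matrix(p2, k_max = 1))
  expect_equal(unname(Y2["a", "b"]), 0)
})

test_that("automorphic nodes are fully similar and Y ignores global weight rescaling", {
  # star_in: all leaves are automorphic images of each other
  Ys <- cosine_similarity(build_feature_matrix(toy("star_in", 5), k_max = 3))
  leaves <- 2:5
  expect_equal(max(abs(Ys[leaves, leaves] - 1)), 0, tolerance = 1e-12)

  net <- random_digraph(10, p = 0.3, seed = 59, weighted = TRUE)
  net2 <- directed_network(net$A * 7.3, net$labels)
  Y1 <- cosine_similarity(build_feature_matrix(net, k_max = 5))
  Y2 <- cosine_similarity(build_feature_matrix(net2, k_max = 5))
  # tolerance reflects the power-iteration accuracy of lambda1
  expect_equal(Y1, Y2, tolerance = 1e-8)
})
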