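fixture <- function(name) system.file("extdata", name, package = "flowscope")

test_that("edge lists parse with first-appearance ordering, duplicate summing and self-loop handling", {
  net <- read_edge_list(fixture("toy_path.tsv"))
  expect_equal(net$N, 3L)
  expect_equal(n_edges(net), 2L)
  expect_equal(net$labels, c("a", "b", "c"))
  expect_equal(unname(net$A["a", "b"]), 1)

  # header autodetected via non-numeric third field; duplicate (a,b) summed
  netw <- read_edge_list(fixture("toy_weighted.tsv"))
  expect_equal(n_edges(netw), 2L)
  expect_equal(unname(netw$A["a", "b"]), 5)
  expect_equal(unname(netw$A["b", "c"]), 1.5)

  # self-loop dropped by default, retained on request
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\ta\t1", "a\tb\t1"), tmp)
  expect_message(net2 <- read_edge_list(tmp), "self-loop")
  expect_equal(n_edges(net2), 1L)
  net3 <- suppressMessages(read_edge_list(tmp, drop_self_loops = FALSE))
  expect_equal(n_edges(net3), 2L)
})

test_that("malformed rows, non-positive weights and empty files are rejected with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "c"), tmp)
  expect_error(read_edge_list(tmp), "line 2")
  writeLines(c("a\tb\t-1"), tmp)
  expect_error(read_edge_list(tmp), "line 1")
  writeLines(character(0), tmp)
  expect_error(read_edge_list(tmp), "empty")
})

test_that("write/read edge list round trip is the identity on canonicalized networks", {
  net <- random_digraph(12, p = 0.25, seed = 3, weighted = TRUE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tmp)
  back <- read_edge_list(tmp)
  expect_setequal(back$labels, net$labels)
  expect_equal(back$A[net$labels, net$labels], net$A, tolerance = 1e-15)
  # a second write/read cycle also preserves the labelled edge set
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(back, tmp2)
  back2 <- read_edge_list(tmp2)
  expect_setequal(back2$labels, back$labels)
  expect_identical(back2$A[back$labels, back$labels], back$A)
})

test_that("graphml round trip preserves the weighted adjacency", {
  net <- random_digraph(8, p = 0.3, seed = 5, weighted = TRUE)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, tmp)
  back <- read_graphml(tmp)
  expect_equal(back$A[net$labels, net$labels], net$A, tolerance = 1e-12)
})

test_that("largest weakly connected component keeps labels and breaks ties lexicographically", {
  # chain a->b->c plus isolated d
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- 1; A["b", "c"] <- 1
  lcc <- largest_weakly_connected_component(directed_network(A))
  expect_setequal(lcc$labels, c("a", "b", "c"))

  # two disjoint directed 3-cycles: tie goes to the component with the
  # lexicographically smallest member
  B <- matrix(0, 7, 7, dimnames = list(c("x1", "x2", "b3", "a1", "a2", "a3", "z"),
                                       c("x1", "x2", "b3", "a1", "a2", "a3", "z")))
  B["x1", "x2"] <- 1; B["x2", "b3"] <- 1; B["b3", "x1"] <- 1
  B["a1", "a2"] <- 1; B["a2", "a3"] <- 1; B["a3", "a1"] <- 1
  lcc2 <- largest_weakly_connected_component(directed_network(B))
  expect_setequal(lcc2$labels, c("a1", "a2", "a3"))
})

test_that("symmetrize averages the adjacency, conserves weight and is idempotent", {
  e <- network_from_edges(data.frame(s = "a", t = "b"))
  s <- symmetrize(e)
  expect_equal(unname(s$A["a", "b"]), 0.5)
  expect_equal(unname(s$A["b", "a"]), 0.5)
  expect_equal(total_weight(s), total_weight(e), tolerance = 1e-12)

  net <- random_digraph(10, p = 0.3, seed = 2, weighted = TRUE)
  s1 <- symmetrize(net)
  expect_equal(total_weight(s1), total_weight(net), tolerance = 1e-12)
  expect_equal(symmetrize(s1)$A, s1$A, tolerance = 1e-15)  # idempotent
  # already-symmetric input unchanged
  expect_equal(symmetrize(s1)$A, s1$A)
})

test_that("coarse-graining sums block weights, conserves total weight and errors on missing nodes", {
  g <- generate_directed_sbm(c(25, 25), p_in = 0.3, p_out = 0.02, seed = 1)
  cg <- coarse_grain(g$net, g$partition)
  expect_equal(cg$N, 2L)
  expect_equal(total_weight(cg), total_weight(g$net), tolerance = 1e-12)
  # planted structure: within-block coarse weights exceed cross-block
  expect_gt(min(diag(cg$A)), max(cg$A - diag(diag(cg$A))))

  # singleton grouping is the identity
  ident <- stats::setNames(g$net$labels, g$net$labels)
  expect_equal(coarse_grain(g$net, ident)$A, g$net$A)

  expect_error(coarse_grain(g$net, g$partition[-1]), "misses")
})

test_that("all-within-group edges coarse-grain to pure self-loops", {
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- 1; A["b", "a"] <- 1; A["c", "d"] <- 1; A["d", "c"] <- 1
  grouping <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  cg <- coarse_grain(directed_network(A), grouping)
  expect_equal(unname(diag(cg$A)), c(2, 2))
  expect_equal(sum(cg$A) - sum(diag(cg$A)), 0)
})

test_that("partition CSV round trip preserves the canonical form", {
  p <- random_partition(paste0("n", 1:9), 3, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(p, tmp)
  back <- read_partition_csv(tmp)
  expect_equal(back[names(p)], p)
})

test_that("matrices round trip through MatrixMarket", {
  M <- matrix(c(0, 1.5, 0, 2, 0, 0.25, 0, 0, 3), 3, 3)
  tmp <- withr::local_tempfile(fileext = ".mtx")
  write_mtx(M, tmp)
  back <- as.matrix(Matrix::readMM(tmp))
  expect_equal(back, M, ignore_attr = TRUE, tolerance = 1e-12)
})
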