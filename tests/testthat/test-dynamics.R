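test_that("transition matrix rows are stochastic and pi is stationary", {
  # single edge a->b with tau = 1: b is dangling -> uniform row
  e <- network_from_edges(data.frame(s = "a", t = "b"))
  proc <- markov_process(e, tau = 1)
  expect_equal(unname(proc$M), rbind(c(0, 1), c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(unname(proc$pi), c(1 / 3, 2 / 3), tolerance = 1e-10)

  # 2-cycle, tau = 1
  cyc2 <- toy("cycle", 2)
  p2 <- markov_process(cyc2, tau = 1)
  expect_equal(unname(p2$M), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(p2$pi), c(0.5, 0.5), tolerance = 1e-12)

  # directed 3-cycle with teleportation keeps the uniform distribution
  p3 <- markov_process(toy("cycle", 3), tau = 0.85)
  expect_equal(unname(p3$pi), rep(1 / 3, 3), tolerance = 1e-10)

  expect_error(markov_process(toy("cycle", 3), tau = 0), "tau")
  expect_error(markov_process(toy("cycle", 3), tau = 1.2), "tau")
})

test_that("propagator is the matrix exponential of the rate matrix", {
  expect_error(propagator(markov_process(toy("cycle", 3)), -1), ">= 0")

  proc <- markov_process(toy("cycle", 3), tau = 1)
  expect_equal(propagator(proc, 0), diag(3), ignore_attr = TRUE)

  # ergodic limit: rows converge to pi
  p2 <- markov_process(toy("cycle", 2), tau = 1)
  Pbig <- propagator(p2, 60)
  expect_equal(unname(Pbig[1, ]), c(0.5, 0.5), tolerance = 1e-10)

  # independent series-expansion oracle on a random 10-node graph
  net <- random_digraph(10, p = 0.3, seed = 7)
  proc10 <- markov_process(net, tau = 0.85)
  L <- proc10$M - diag(10)
  expect_equal(propagator(proc10, 0.7), expm_series(0.7 * L),
               tolerance = 1e-10, ignore_attr = TRUE)

  # rows of P(t) sum to one
  expect_equal(rowSums(propagator(proc10, 2.3)), rep(1, 10),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("stability has its closed forms and matches the brute-force double sum", {
  net <- random_digraph(8, p = 0.35, seed = 11)
  proc <- markov_process(net, tau = 0.85)

  one <- stats::setNames(rep(0L, 8), net$labels)
  for (t in c(0.1, 1, 5)) {
    expect_equal(stability(proc, one, t), 0, tolerance = 1e-12)
  }
  singles <- stats::setNames(0:7, net$labels)
  expect_equal(stability(proc, singles, 0), 1 - sum(proc$pi^2),
               tolerance = 1e-12)

  # trace formula == element-wise double sum on a random 3-way partition
  part <- random_partition(net$labels, 3, seed = 2)
  expect_equal(stability(proc, part, 1), stability_bruteforce(proc, part, 1),
               tolerance = 1e-12)

  expect_error(stability(proc, part[-1], 1), "misses")
})

test_that("quality matrix is symmetric with zero row sums and preserves the stability trace", {
  net <- random_digraph(9, p = 0.3, seed = 13)
  proc <- markov_process(net, tau = 0.85)
  for (t in c(0.2, 1.5)) {
    B <- quality_matrix(proc, t)
    expect_equal(max(abs(B - t(B))), 0, tolerance = 1e-14)
    expect_equal(max(abs(rowSums(B))), 0, tolerance = 1e-10)
    expect_equal(max(abs(colSums(B))), 0, tolerance = 1e-10)
    # trace(H' B H) equals stability via Pi P(t)
    part <- random_partition(net$labels, 3, seed = t * 10)
    H <- outer(part[proc$labels], sort(unique(part)), "==") * 1
    expect_equal(sum(diag(t(H) %*% B %*% H)), stability(proc, part, t),
                 tolerance = 1e-12)
  }
})

test_that("stationarity and degree-proportionality hold for undirected networks at tau 1", {
  net <- symmetrize(random_digraph(12, p = 0.3, seed = 17))
  proc <- markov_process(net, tau = 1)
  expect_equal(sum(abs(as.vector(proc$pi %*% proc$M) - proc$pi)), 0,
               tolerance = 1e-10)
  strength <- rowSums(net$A)
  expect_equal(unname(proc$pi), unname(strength / sum(strength)),
               tolerance = 1e-9)
})

test_that("stability of every partition decays to zero at large Markov time", {
  net <- random_digraph(8, p = 0.35, seed = 19)
  proc <- markov_process(net, tau = 0.85)
  part <- random_partition(net$labels, 3, seed = 5)
  expect_lt(abs(stability(proc, part, 200)), 1e-8)
})
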