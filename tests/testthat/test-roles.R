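role_pipeline <- function(seed, n_runs = 5) {
  g <- generate_role_planted(seed = seed)
  Xf <- build_feature_matrix(g$net)
  Y <- cosine_similarity(Xf)
  rsg <- rmst(similarity_to_distance(Y), gamma = 0.5, Y = Y)
  ra <- suppressWarnings(detect_roles(rsg, g$net, n_runs = n_runs, seed = 5))
  list(g = g, Xf = Xf, rsg = rsg, ra = ra)
}

test_that("a vertex-transitive network has exactly one role", {
  net <- toy("cycle", 8)
  Y <- cosine_similarity(build_feature_matrix(net))
  rsg <- rmst(similarity_to_distance(Y), gamma = 0.5, Y = Y)
  ra <- suppressWarnings(detect_roles(rsg, net, n_runs = 3, seed = 1))
  expect_equal(ra$n_roles, 1L)
})

test_that("planted roles are recovered and ordered by in-strength", {
  r <- role_pipeline(seed = 1)
  expect_equal(r$ra$n_roles, 3L)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(r$ra$roles, r$g$roles[names(r$ra$roles)])
  expect_gte(ari, 0.9)
  # role 0 = most followed (references)
  instr <- colSums(r$g$net$A)
  means <- tapply(instr[names(r$ra$roles)], r$ra$roles, mean)
  expect_true(all(diff(means) <= 0))
})

test_that("role flow profiles separate planted sources from sinks", {
  r <- role_pipeline(seed = 2)
  prof <- role_flow_profiles(r$ra, r$Xf)
  expect_equal(nrow(prof$incoming), r$ra$n_roles)
  expect_equal(ncol(prof$incoming), r$Xf$k_max)
  # references (role 0) receive more attention than listeners (last role)
  # at every path length with nonzero flow; converse for outgoing length 1
  last <- nrow(prof$incoming)
  expect_gt(prof$incoming[1, 1], prof$incoming[last, 1])
  expect_gt(prof$outgoing[last, 1], prof$outgoing[1, 1])
  expect_true(all(is.finite(prof$incoming)) && all(is.finite(prof$outgoing)))

  # single-role network: profile equals the column means of the whole X
  net <- toy("cycle", 6)
  Xf <- build_feature_matrix(net)
  one <- stats::setNames(rep(0L, 6), net$labels)
  p1 <- role_flow_profiles(one, Xf)
  counts <- unscaled_counts(Xf)
  expect_equal(unname(p1$incoming[1, ]),
               unname(colMeans(log1p(counts[, seq_len(Xf$k_max)]))),
               tolerance = 1e-9)
})

test_that("role mixes are exact member fractions and sum to one", {
  labs <- paste0("n", 1:10)
  part <- stats::setNames(c(rep(0L, 4), rep(1L, 6)), labs)
  roles <- stats::setNames(c(0L, 0L, 1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L), labs)
  mix <- role_mix(part, roles)
  expect_equal(unname(rowSums(mix)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(mix[1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(mix[2, ]), c(0.5, 0, 0.5))

  # naive counting oracle on a random assignment
  part2 <- random_partition(labs, 3, seed = 5)
  roles2 <- random_partition(labs, 4, seed = 6)
  mix2 <- role_mix(part2, roles2)
  for (cm in sort(unique(part2))) {
    members <- names(part2)[part2 == cm]
    for (rl in sort(unique(roles2))) {
      expect_equal(mix2[paste0("community_", cm), paste0("role_", rl)],
                   mean(roles2[members] == rl))
    }
  }
  # single-member community is a unit vector
  part3 <- stats::setNames(c(0L, rep(1L, 9)), labs)
  mix3 <- role_mix(part3, roles2)
  expect_equal(sum(mix3[1, ] == 1), 1L)
  expect_error(role_mix(part2[-1], roles2), "node set")
})

test_that("k-means organigram clustering separates point clouds and handles degeneracy", {
  mix <- rbind(matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE))
  mix <- mix + withr::with_seed(1, matrix(stats::runif(30, 0, 0.02), 10))
  mix <- mix / rowSums(mix)
  rownames(mix) <- paste0("c", 1:10)
  org <- cluster_role_mixes(mix, k = 2, seed = 1)
  expect_equal(org$k, 2L)
  expect_equal(length(unique(org$cluster[1:5])), 1L)
  expect_equal(length(unique(org$cluster[6:10])), 1L)
  expect_false(org$cluster[1] == org$cluster[6])

  # auto selection by silhouette on the same clean clouds
  org_auto <- cluster_role_mixes(mix, k = "auto", seed = 1)
  expect_equal(org_auto$k, 2L)

  # identical mixes -> degenerate, forced k = 1
  flat <- matrix(1 / 3, 6, 3, dimnames = list(paste0("c", 1:6), NULL))
  orgd <- cluster_role_mixes(flat, k = "auto", seed = 1)
  expect_true(orgd$degenerate)
  expect_equal(orgd$k, 1L)

  expect_error(cluster_role_mixes(mix, k = 10), "smaller")
})
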