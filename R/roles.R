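#' Detect flow roles from a role similarity graph
#'
#' Runs the Markov Stability sweep on the (undirected) RMST role
#' similarity graph and takes the representative partition of the most
#' robust plateau (longest window; ties broken by lowest mean within-run
#' VI). The number of communities found on the role similarity graph is
#' the number of flow roles — no role count is imposed a priori. Roles are
#' relabeled by descending mean in-strength of their members in the
#' original directed network, so role 0 collects the most-followed nodes
#' (references) and the last role the least-followed (listeners).
#'
#' @param rsg a `role_similarity_graph` from [rmst()].
#' @param net the original [directed_network()] (used only to order the
#'   role labels by in-strength).
#' @param times,n_runs,seed sweep parameters passed to
#'   [stability_sweep()]; the sweep runs with `tau = 1` since the role
#'   graph is undirected. Default grid: 40 log-spaced times in
#'   `[1e-2, 10^1.5]`, 10 runs.
#'
#' @details Every sweep exhibits a trivial plateau at very small Markov
#' times, where the walk has not moved and near-singleton partitions are
#' perfectly reproducible, and another at very large times where all
#' nodes merge. Neither is a candidate role structure — a "role" held by
#' single nodes, or one shared by everyone, carries no classification —
#' so plateau selection skips windows whose representative partition is
#' all-in-one or mostly singletons (more than half of its communities
#' have a single member).
#' @param vi_tol,min_plateau plateau selection parameters, see
#'   [select_robust_partitions()]. The role default `vi_tol = 0.1 log(N)`
#'   is deliberately coarser than the sweep default: role structure is
#'   coarse (a few classes over many nodes), and a plateau should not be
#'   vetoed because a handful of boundary nodes flicker between classes
#'   across optimizer restarts — on 100 nodes a single flickering node
#'   already contributes VI of order `0.09`.
#' @return A `role_assignment`: list with `roles` (named integer vector),
#'   `n_roles`, `window` (the selected plateau, or `NULL` with
#'   `fallback = TRUE` when no plateau exists), and the underlying
#'   `sweep`.
#' @export
detect_roles <- function(rsg, net, times = NULL, n_runs = 10, seed = 1L,
                         vi_tol = NULL, min_plateau = 5) {
  if (is.null(times)) times <- 10^seq(-2, 1.5, length.out = 40)
  rnet <- rsg_as_network(rsg)
  sw <- stability_sweep(rnet, times = times, n_runs = n_runs, tau = 1,
                        seed = seed)
  if (is.null(vi_tol)) vi_tol <- 0.1 * log(length(sw$labels))
  wins <- select_robust_partitions(sw, vi_tol = vi_tol,
                                   min_plateau = min_plateau)
  # the granular small-t regime (mostly singleton communities) is never a
  # role structure; the all-in-one plateau is kept only as a last resort,
  # since a single role is the right answer for a homogeneous network
  wins <- Filter(function(w) !singleton_dominated(w$partition), wins)
  multi <- Filter(function(w) n_communities(w$partition) > 1, wins)
  if (length(multi) > 0) wins <- multi
  fallback <- length(wins) == 0
  if (fallback) {
    cand <- which(!vapply(sw$partitions, trivial_partition, logical(1)))
    if (length(cand) > 0) {
      warning("no robust plateau found; using the most reproducible non-trivial partition")
      ti <- cand[which.min(sw$vi_runs[cand])]
    } else {
      # every scale is trivial (singletons or all-in-one): the network
      # carries no role differentiation at all
      warning("no non-trivial partition at any scale; reporting a single role")
      onerole <- which(vapply(sw$partitions, function(p)
        n_communities(p) == 1, logical(1)))
      ti <- if (length(onerole) > 0) onerole[length(onerole)]
            else ceiling(length(times) / 2)
    }
    part <- sw$partitions[[ti]]
    window <- NULL
  } else {
    len <- vapply(wins, function(w) length(w$indices), integer(1))
    meanvi <- vapply(wins, function(w) mean(sw$vi_runs[w$indices]), numeric(1))
    best <- order(-len, meanvi)[1]
    window <- wins[[best]]
    part <- window$partition
  }
  roles <- relabel_by_in_strength(part, net)
  structure(list(roles = roles, n_roles = n_communities(roles),
                 window = window, fallback = fallback, sweep = sw),
            class = "role_assignment")
}

# More than half of the communities are singletons (the granular regime).
singleton_dominated <- function(part) {
  sizes <- table(part)
  length(sizes) > 1 && mean(sizes == 1) > 0.5
}

# All-in-one or singleton-dominated.
trivial_partition <- function(part) {
  length(unique(part)) == 1 || singleton_dominated(part)
}

# Relabel communities 0..k-1 by descending mean in-strength of members.
relabel_by_in_strength <- function(part, net) {
  instr <- colSums(net$A)
  means <- vapply(split(names(part), part),
                  function(m) mean(instr[m]), numeric(1))
  new_of_old <- order(order(-means)) - 1L  # rank by descending mean
  out <- new_of_old[match(part, as.integer(names(means)))]
  # names(means) are the old labels as character in split order
  names(out) <- names(part)
  out
}

#' @export
print.role_assignment <- function(x, ...) {
  cat(sprintf("role_assignment: %d role(s) over %d nodes%s\n",
              x$n_roles, length(x$roles),
              if (isTRUE(x$fallback)) " (no plateau; median-time fallback)"
              else ""))
  invisible(x)
}

#' In/out flow profiles per role
#'
#' For every role, the mean over members of `log1p` of the unscaled walk
#' counts at each length, separately for the incoming and outgoing
#' blocks — the curves that characterize each role's pattern of received
#' and emitted attention at all path lengths. Means of very large counts
#' are computed on the log scale to avoid overflow.
#'
#' @param roles a `role_assignment` (or named role vector).
#' @param Xf the `flow_feature_matrix` of the same network.
#' @return list with `incoming` and `outgoing`: matrices of
#'   `n_roles x K_max` profile values.
#' @export
role_flow_profiles <- function(roles, Xf) {
  rv <- if (inherits(roles, "role_assignment")) roles$roles else roles
  if (!setequal(names(rv), Xf$labels)) stopf("role and feature node sets differ")
  rv <- rv[Xf$labels]
  K <- Xf$k_max
  # log1p of unscaled counts, computed stably: log(count) = log(x) - k log(alpha)
  la <- log(Xf$alpha)
  logc <- log(Xf$X)  # -Inf where zero
  logc <- sweep(logc, 2, c(seq_len(K), seq_len(K)) * la, "-")
  l1p <- ifelse(logc > 30, logc, log1p(exp(logc)))  # log1p(e^x) ~ x for large x
  l1p[Xf$X == 0] <- 0
  groups <- sort(unique(rv))
  prof <- t(vapply(groups, function(g) colMeans(l1p[rv == g, , drop = FALSE]),
                  numeric(2 * K)))
  rownames(prof) <- paste0("role_", groups)
  list(incoming = prof[, seq_len(K), drop = FALSE],
       outgoing = prof[, K + seq_len(K), drop = FALSE])
}

#' Role mix of communities
#'
#' For each community of a partition, the fraction of its members holding
#' each role; every row sums to one. The role mix summarizes a
#' community's internal informational organization.
#'
#' @param partition named partition vector over the nodes.
#' @param roles a `role_assignment` (or named role vector) on the same
#'   node set.
#' @return matrix of communities x roles with rows summing to 1.
#' @export
role_mix <- function(partition, roles) {
  rv <- if (inherits(roles, "role_assignment")) roles$roles else roles
  if (!setequal(names(partition), names(rv))) {
    stopf("partition and roles cover different node sets")
  }
  rv <- rv[names(partition)]
  tab <- table(partition, rv)
  mix <- tab / rowSums(tab)
  m <- matrix(as.numeric(mix), nrow(tab), ncol(tab),
              dimnames = list(paste0("community_", rownames(tab)),
                              paste0("role_", colnames(tab))))
  m
}

#' Cluster communities by their role mixes into organigram types
#'
#' Plain k-means on the role-fraction vectors; communities in the same
#' cluster share an informational organigram (e.g. reference-dominated
#' broadcast groups versus balanced dialogue groups). With `k = "auto"`
#' the cluster count is chosen in `2 .. min(8, m - 1)` by maximum mean
#' silhouette width; degenerate inputs (all mixes identical) force a
#' single cluster.
#'
#' @param mix community x role matrix from [role_mix()].
#' @param k number of organigram types, or `"auto"`.
#' @param n_restarts random k-means initializations (best inertia kept).
#' @param seed integer seed.
#' @return An `organigram_clustering`: list with `k`, `cluster` (named),
#'   `centroids`, `silhouette` (per candidate k when auto), `degenerate`.
#' @export
cluster_role_mixes <- function(mix, k = "auto", n_restarts = 50, seed = 1L) {
  mix <- as.matrix(mix)
  m <- nrow(mix)
  if (m < 2) stopf("need at least 2 communities to cluster")
  degenerate <- all(apply(mix, 2, function(col) diff(range(col)) == 0))
  if (degenerate) {
    cl <- rep(1L, m)
    names(cl) <- rownames(mix)
    return(structure(list(k = 1L, cluster = cl,
                          centroids = mix[1, , drop = FALSE],
                          silhouette = NULL, degenerate = TRUE),
                     class = "organigram_clustering"))
  }
  auto <- identical(k, "auto")
  n_distinct <- nrow(unique(mix))
  if (!auto && k >= m) stopf("k must be smaller than the number of communities")
  if (!auto && k > n_distinct) stopf("k exceeds the number of distinct mixes (%d)",
                                     n_distinct)
  sil_scores <- NULL
  fit_k <- function(kk) {
    with_seed(derive_seed(seed, kk),
              stats::kmeans(mix, centers = kk, nstart = n_restarts,
                            iter.max = 100))
  }
  if (auto) {
    upper <- min(8, m - 1, n_distinct)
    if (upper < 2) {
      k <- 1
    } else {
      ks <- 2:upper
      dmat <- stats::dist(mix)
      sil_scores <- vapply(ks, function(kk) {
        km <- fit_k(kk)
        if (length(unique(km$cluster)) < 2) return(-Inf)
        mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
      }, numeric(1))
      k <- ks[which.max(sil_scores)]
      names(sil_scores) <- ks
    }
  }
  km <- fit_k(k)
  cl <- km$cluster
  names(cl) <- rownames(mix)
  structure(list(k = as.integer(k), cluster = cl, centroids = km$centers,
                 silhouette = sil_scores, degenerate = FALSE),
            class = "organigram_clustering")
}

#' @export
print.organigram_clustering <- function(x, ...) {
  cat(sprintf("organigram_clustering: %d type(s) over %d communities%s\n",
              x$k, length(x$cluster),
              if (isTRUE(x$degenerate)) " (degenerate: identical mixes)"
              else ""))
  invisible(x)
}

#' Cumulative count distributions per role
#'
#' Plotting hook for externally supplied per-node activity counts (e.g.
#' message or retweet tallies): draws one empirical complementary CDF per
#' role on log-log axes, so heavy-tailed roles (references, engaged
#' leaders) separate visually from passive ones. No count data ships with
#' the package.
#'
#' @param counts named non-negative numeric vector of per-node counts.
#' @param roles a `role_assignment` (or named role vector) covering the
#'   same nodes.
#' @param ... further arguments passed to [graphics::plot()].
#' @return (invisibly) a list of per-role sorted count vectors.
#' @export
plot_role_count_cdf <- function(counts, roles, ...) {
  rv <- if (inherits(roles, "role_assignment")) roles$roles else roles
  common <- intersect(names(counts), names(rv))
  if (length(common) == 0) stopf("counts and roles share no node labels")
  rv <- rv[common]
  counts <- counts[common]
  groups <- sort(unique(rv))
  sorted <- lapply(groups, function(g) sort(counts[rv == g], decreasing = TRUE))
  names(sorted) <- paste0("role_", groups)
  xmax <- max(1, unlist(counts))
  graphics::plot(NA, xlim = c(1, xmax), ylim = c(1e-2, 1), log = "xy",
                 xlab = "count", ylab = "P(X >= x)", ...)
  for (i in seq_along(sorted)) {
    x <- sorted[[i]][sorted[[i]] > 0]
    if (length(x) == 0) next
    graphics::lines(x, seq_along(x) / length(sorted[[i]]), type = "s",
                    col = i, lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(sorted), col = seq_along(sorted),
                   lwd = 2, bty = "n")
  invisible(sorted)
}
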