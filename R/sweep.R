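#' Markov Stability sweep across a grid of Markov times
#'
#' For each time `t` in the grid, builds the symmetric quality matrix
#' `B(t)` of the teleported walk and maximizes stability with `n_runs`
#' independently seeded Louvain runs, keeping the best-scoring partition.
#' Short times resolve many small, granular communities; long times fewer
#' and coarser ones. The robustness diagnostics (`vi_runs`, the mean
#' pairwise variation of information across the optimizer restarts at each
#' time, and `vi_cross`, the VI between the best partitions at different
#' times) identify plateaus where the partition is reproducible and
#' persistent — the hallmark of a meaningful scale.
#'
#' @param net a [directed_network()].
#' @param times increasing positive time grid; default 100 logarithmically
#'   spaced points in `[1e-2, 1e1]`.
#' @param n_runs Louvain restarts per time (default 100).
#' @param tau teleportation retention passed to [markov_process()].
#' @param seed master seed; per-(time, run) seeds are derived from it by
#'   counter and recorded in the result.
#' @param proc optionally a precomputed [markov_process()]; `tau` is then
#'   ignored.
#' @param verbose log progress per time point.
#' @return A `partition_sequence`: list with `times`, `partitions` (one
#'   canonical partition per time), `stability`, `k`, `vi_runs`,
#'   `vi_cross`, `seeds`, `n_runs`, `tau`, `seed`, `pi`, `labels`.
#' @export
stability_sweep <- function(net, times = NULL, n_runs = 100, tau = 0.85,
                            seed = 1L, proc = NULL, verbose = FALSE) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  if (is.null(proc)) proc <- markov_process(net, tau = tau)
  if (is.null(times)) times <- 10^seq(-2, 1, length.out = 100)
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stopf("times must be strictly increasing and positive")
  }
  Tn <- length(times)
  partitions <- vector("list", Tn)
  r_best <- numeric(Tn)
  k_best <- integer(Tn)
  vi_runs <- numeric(Tn)
  seeds <- matrix(0L, Tn, n_runs)
  counter <- 0L
  for (ti in seq_len(Tn)) {
    B <- quality_matrix(proc, times[ti])
    runs <- vector("list", n_runs)
    scores <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      counter <- counter + 1L
      s <- derive_seed(seed, counter)
      seeds[ti, r] <- s
      p <- louvain_optimize(B, seed = s)
      runs[[r]] <- p
      scores[r] <- attr(p, "objective")
    }
    best <- which.max(scores)
    partitions[[ti]] <- runs[[best]]
    r_best[ti] <- scores[best]
    k_best[ti] <- n_communities(runs[[best]])
    vi_runs[ti] <- mean_pairwise_vi(runs)
    if (verbose) {
      fs_log("sweep", sprintf("t=%.4g k=%d r=%.6g vi_runs=%.4g",
                              times[ti], k_best[ti], r_best[ti], vi_runs[ti]))
    }
  }
  vi_cross <- matrix(0, Tn, Tn)
  if (Tn > 1) {
    for (i in seq_len(Tn - 1)) {
      for (j in (i + 1):Tn) {
        vi_cross[i, j] <- vi_cross[j, i] <-
          variation_of_information(partitions[[i]], partitions[[j]])
      }
    }
  }
  structure(list(times = times, partitions = partitions, stability = r_best,
                 k = k_best, vi_runs = vi_runs, vi_cross = vi_cross,
                 seeds = seeds, n_runs = n_runs, tau = proc$tau, seed = seed,
                 pi = proc$pi, labels = proc$labels),
            class = "partition_sequence")
}

mean_pairwise_vi <- function(parts) {
  m <- length(parts)
  if (m < 2) return(0)
  tot <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      tot <- tot + variation_of_information(parts[[i]], parts[[j]])
    }
  }
  tot / (m * (m - 1) / 2)
}

#' @export
print.partition_sequence <- function(x, ...) {
  cat(sprintf(
    "partition_sequence: %d times in [%.3g, %.3g], k from %d to %d, %d run(s)/time\n",
    length(x$times), min(x$times), max(x$times), x$k[1],
    x$k[length(x$k)], x$n_runs))
  invisible(x)
}

#' Summarize a sweep as a data frame
#' @param object a `partition_sequence`.
#' @param ... unused.
#' @return data frame with columns time, k, stability, vi_runs.
#' @export
summary.partition_sequence <- function(object, ...) {
  data.frame(time = object$times, k = object$k,
             stability = object$stability, vi_runs = object$vi_runs)
}

#' Select robust partitions from a sweep
#'
#' Scans the time grid for maximal contiguous windows in which the
#' optimizer restarts agree (`vi_runs <= vi_tol` at every grid point) and
#' the best partitions are mutually consistent (pairwise cross-time VI
#' `<= vi_tol`), keeping windows spanning at least `min_plateau` grid
#' points. Long low-VI plateaus signal partitions that are robust both to
#' the optimizer's randomness and to the choice of Markov time.
#'
#' @param seq a `partition_sequence` from [stability_sweep()].
#' @param vi_tol VI tolerance; default `0.02 * log(N)`.
#' @param min_plateau minimum window length in grid points (default 5).
#' @return list of windows; each has `t_start`, `t_end`, `indices`, `k`,
#'   and `partition` (the modal canonical partition of the window). May be
#'   empty.
#' @export
select_robust_partitions <- function(seq, vi_tol = NULL, min_plateau = 5) {
  Tn <- length(seq$times)
  if (is.null(vi_tol)) vi_tol <- 0.02 * log(length(seq$labels))
  ok <- seq$vi_runs <= vi_tol
  # largest b such that [a, b] is all ok with pairwise cross-VI <= tol
  # (the constraint is hereditary: subwindows of valid windows are valid)
  b_max <- integer(Tn)
  for (a in seq_len(Tn)) {
    if (!ok[a]) { b_max[a] <- a - 1L; next }
    b <- a
    while (b < Tn && ok[b + 1] &&
           all(seq$vi_cross[a:(b + 1), b + 1] <= vi_tol)) {
      b <- b + 1L
    }
    b_max[a] <- b
  }
  windows <- list()
  covered <- 0L  # largest end index of any already-reported window
  for (a in seq_len(Tn)) {
    bm <- b_max[a]
    if (bm < a || bm <= covered) next  # invalid start or contained earlier
    if (bm - a + 1L >= min_plateau) {
      idx <- a:bm
      rep_part <- modal_partition(seq$partitions[idx])
      windows[[length(windows) + 1]] <- list(
        t_start = seq$times[a], t_end = seq$times[bm], indices = idx,
        k = n_communities(rep_part), partition = rep_part)
    }
    covered <- max(covered, bm)
  }
  windows
}

# Most frequent canonical partition in a list; ties -> earliest.
modal_partition <- function(parts) {
  keys <- vapply(parts, function(p) paste(p, collapse = ","), character(1))
  tab <- table(factor(keys, levels = unique(keys)))
  parts[[match(names(tab)[which.max(tab)], keys)]]
}
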