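#' Canonicalize a partition
#'
#' Partitions are named integer vectors mapping node label to community
#' label. Canonical form relabels communities `0 .. k-1` in order of each
#' community's smallest member index, so two partitions are equal up to
#' relabeling iff their canonical forms are identical.
#'
#' @param partition named vector (any label type) over the node set.
#' @return named integer vector with contiguous labels starting at 0.
#' @export
canonicalize_partition <- function(partition) {
  f <- match(partition, unique(partition))  # first-occurrence order
  out <- f - 1L
  names(out) <- names(partition)
  out
}

#' Number of communities of a partition
#' @param partition a partition vector.
#' @return integer count of distinct community labels.
#' @export
n_communities <- function(partition) length(unique(partition))

#' Variation of information between two partitions
#'
#' `VI = 2 H(joint) - H(p1) - H(p2)` with natural logarithms: a metric on
#' the space of partitions of the same node set. It is zero iff the
#' partitions coincide up to relabeling, symmetric, satisfies the triangle
#' inequality, and is bounded above by `log(N)`.
#'
#' @param p1,p2 partitions over the same node set (named vectors, or
#'   unnamed vectors of equal length in identical node order).
#' @param normalized divide by `log(N)` so the result lies in \[0, 1\].
#' @return numeric VI in nats.
#' @export
variation_of_information <- function(p1, p2, normalized = FALSE) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stopf("partitions cover different node sets")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stopf("partitions have different sizes")
  }
  n <- length(p1)
  joint <- table(p1, p2) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  vi <- 2 * ent(as.vector(joint)) - ent(rowSums(joint)) - ent(colSums(joint))
  vi <- max(vi, 0)  # clip tiny negative rounding
  if (normalized) vi / log(n) else vi
}
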