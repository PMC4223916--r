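#' Directed weighted networks
#'
#' A `directed_network` wraps a dense weighted adjacency matrix `A` whose
#' rows are edge sources and columns edge targets, together with the node
#' labels that give every matrix a stable, reproducible index order
#' (first-appearance order on load). `A[i, j] > 0` means node `i` points at
#' node `j`; in a follower network the edge records declared interest
#' (follower -> followee) while content travels the opposite way.
#'
#' @param A square numeric matrix with non-negative entries; dimnames are
#'   used as node labels if present.
#' @param labels character vector of unique node labels; defaults to the
#'   dimnames of `A` or `V1..VN`.
#' @return A `directed_network` object: a list with elements `A` (named
#'   adjacency matrix), `labels`, and `N`.
#' @export
directed_network <- function(A, labels = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stopf("adjacency matrix must be square")
  if (any(A < 0)) stopf("adjacency weights must be non-negative")
  if (is.null(labels)) labels <- rownames(A) %||% paste0("V", seq_len(nrow(A)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stopf("node labels must be unique")
  if (length(labels) != nrow(A)) stopf("labels length does not match matrix")
  dimnames(A) <- list(labels, labels)
  structure(list(A = A, labels = labels, N = nrow(A)),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges, total weight %.6g\n",
              x$N, sum(x$A > 0), sum(x$A)))
  invisible(x)
}

#' Number of edges of a directed network
#' @param net a `directed_network`.
#' @return integer count of directed edges with positive weight.
#' @export
n_edges <- function(net) sum(net$A > 0)

#' Build a network from an edge table
#'
#' Nodes are ordered by first appearance (sources before targets within a
#' row); duplicate ordered pairs have their weights summed; self-loops are
#' dropped by default (with a message) since follower networks have none.
#'
#' @param edges data frame with columns source, target and optionally
#'   weight (positive).
#' @param drop_self_loops drop self-loops (default `TRUE`); they are always
#'   reported when present.
#' @param verbose print a one-line summary.
#' @return a [directed_network()].
#' @export
network_from_edges <- function(edges, drop_self_loops = TRUE, verbose = FALSE) {
  if (nrow(edges) == 0) stopf("edge table is empty")
  src <- as.character(edges[[1]])
  dst <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, nrow(edges))
  if (anyNA(w)) stopf("weight column contains non-numeric values")
  if (any(w <= 0)) {
    stopf("non-positive weight at row %d", which(w <= 0)[1])
  }
  loops <- src == dst
  if (any(loops)) {
    fs_log("graph_io", sprintf("%d self-loop(s) %s", sum(loops),
                               if (drop_self_loops) "dropped" else "retained"),
           verbose = TRUE)
    if (drop_self_loops) {
      src <- src[!loops]; dst <- dst[!loops]; w <- w[!loops]
      if (length(src) == 0) stopf("no edges remain after dropping self-loops")
    }
  }
  labels <- unique(as.vector(rbind(src, dst)))
  A <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (r in seq_along(src)) A[src[r], dst[r]] <- A[src[r], dst[r]] + w[r]
  net <- directed_network(A, labels)
  if (verbose) {
    dangling <- sum(rowSums(net$A) == 0)
    fs_log("graph_io", sprintf("N=%d, %d edges, %d dangling node(s)",
                               net$N, n_edges(net), dangling))
  }
  net
}

#' Read a directed network from a delimited edge list
#'
#' Each data row is `source<delim>target[<delim>weight]`. A header row is
#' autodetected when the third field of the first row is non-numeric (or
#' when the first two fields are literally "source"/"target"). Duplicate
#' ordered pairs are summed; rows without a weight get weight 1.
#'
#' @param path file path.
#' @param delimiter field separator; default tab.
#' @param weighted use the third column as weights when present.
#' @param drop_self_loops drop self-loops (default `TRUE`).
#' @param verbose log a load summary.
#' @return a [directed_network()].
#' @export
read_edge_list <- function(path, delimiter = "\t", weighted = TRUE,
                           drop_self_loops = TRUE, verbose = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty edge-list file: %s", path)
  rows <- strsplit(lines, delimiter, fixed = TRUE)
  first <- trimws(rows[[1]])
  has_header <- FALSE
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
    has_header <- TRUE
  } else if (length(first) >= 2 &&
             identical(tolower(first[1:2]), c("source", "target"))) {
    has_header <- TRUE
  }
  if (has_header) {
    rows <- rows[-1]
    if (length(rows) == 0) stopf("edge-list file has a header but no data rows")
  }
  offset <- as.integer(has_header)
  n <- length(rows)
  src <- character(n); dst <- character(n); w <- rep(1, n)
  for (r in seq_len(n)) {
    f <- trimws(rows[[r]])
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      stopf("malformed row at line %d of %s", r + offset, path)
    }
    src[r] <- f[1]; dst[r] <- f[2]
    if (weighted && length(f) >= 3 && nzchar(f[3])) {
      wi <- suppressWarnings(as.numeric(f[3]))
      if (is.na(wi)) stopf("non-numeric weight at line %d of %s", r + offset, path)
      if (wi <= 0) stopf("non-positive weight at line %d of %s", r + offset, path)
      w[r] <- wi
    }
  }
  network_from_edges(data.frame(source = src, target = dst, weight = w,
                                stringsAsFactors = FALSE),
                     drop_self_loops = drop_self_loops, verbose = verbose)
}

#' Write a network as a delimited edge list
#'
#' Edges are written in row-major (source-index, target-index) order so a
#' read/write round trip is the identity on canonicalized networks.
#'
#' @param net a `directed_network`.
#' @param path output path.
#' @param delimiter field separator; default tab.
#' @param header write a `source target weight` header row.
#' @export
write_edge_list <- function(net, path, delimiter = "\t", header = FALSE) {
  m <- which(net$A > 0, arr.ind = TRUE)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  df <- data.frame(source = net$labels[m[, 1]], target = net$labels[m[, 2]],
                   weight = format(net$A[m], digits = 17,
                                   trim = TRUE, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste(c("source", "target", "weight"),
                               collapse = delimiter), con)
  writeLines(paste(df$source, df$target, df$weight, sep = delimiter), con)
  invisible(path)
}

#' Convert to/from igraph
#' @param net a `directed_network`.
#' @return an igraph directed weighted graph / a `directed_network`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$A, mode = "directed",
                                      weighted = TRUE)
}

#' @rdname as_igraph
#' @param g an igraph graph; undirected graphs are taken as reciprocal.
#' @export
from_igraph <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = TRUE))
  labels <- igraph::V(g)$name %||% paste0("V", seq_len(nrow(A)))
  directed_network(A, labels)
}

#' Read / write GraphML
#' @param path file path.
#' @return a [directed_network()].
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  from_igraph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname read_graphml
#' @param net a `directed_network`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Largest weakly connected component
#'
#' Returns the induced subnetwork on the largest weakly connected node set,
#' preserving original labels and their relative order. Ties between
#' equally sized components are broken in favour of the component holding
#' the lexicographically smallest member label.
#'
#' @param net a `directed_network`.
#' @return a `directed_network` on the component's nodes.
#' @export
largest_weakly_connected_component <- function(net) {
  if (net$N < 1) stopf("network has no nodes")
  comp <- igraph::components(as_igraph(net), mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest lexicographic member label wins
    mins <- vapply(best, function(c) min(net$labels[comp$membership == c]),
                   character(1))
    best <- best[order(mins)][1]
  }
  keep <- which(comp$membership == best)
  directed_network(net$A[keep, keep, drop = FALSE], net$labels[keep])
}

#' Symmetrize a directed network
#'
#' Replaces the adjacency by `(A + t(A)) / 2`, discarding edge orientation
#' while conserving total edge weight, so that stability sweeps of the
#' directed and undirected versions of a network are directly comparable.
#'
#' @param net a `directed_network`.
#' @return a `directed_network` with symmetric adjacency.
#' @export
symmetrize <- function(net) {
  directed_network((net$A + t(net$A)) / 2, net$labels)
}

#' Coarse-grain a network by a node grouping
#'
#' Aggregates nodes into groups; the weight from group g to g' is the sum
#' of all edge weights from members of g to members of g', including the
#' diagonal (within-group weight becomes a self-loop). Total weight is
#' conserved.
#'
#' @param net a `directed_network`.
#' @param grouping named vector mapping every node label to a group label.
#' @return a `directed_network` over the group labels.
#' @export
coarse_grain <- function(net, grouping) {
  miss <- setdiff(net$labels, names(grouping))
  if (length(miss) > 0) stopf("grouping misses node(s): %s",
                              paste(utils::head(miss, 5), collapse = ", "))
  g <- as.character(grouping[net$labels])
  glabels <- unique(g)
  H <- outer(g, glabels, "==") * 1
  directed_network(t(H) %*% net$A %*% H, glabels)
}

#' Total edge weight
#' @param net a `directed_network`.
#' @return the sum of all edge weights.
#' @export
total_weight <- function(net) sum(net$A)

#' Read / write partitions as CSV
#'
#' Partition files have columns `node,label`.
#'
#' @param path file path.
#' @return named integer vector (a partition).
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- as.integer(as.factor(df[[2]])) - 1L
  names(p) <- as.character(df[[1]])
  canonicalize_partition(p)
}

#' @rdname read_partition_csv
#' @param partition named vector mapping node label to community label.
#' @export
write_partition_csv <- function(partition, path) {
  utils::write.csv(data.frame(node = names(partition),
                              label = unname(partition)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a matrix in MatrixMarket format
#'
#' Convenience export for feature, similarity and transition matrices.
#'
#' @param M numeric matrix (dense or sparse).
#' @param path output path (conventionally `.mtx`).
#' @export
write_mtx <- function(M, path) {
  M <- as.matrix(M)
  dimnames(M) <- NULL  # force the general (non-symmetric) sparse class
  Matrix::writeMM(Matrix::Matrix(M, sparse = TRUE, doDiag = FALSE), path)
  invisible(path)
}
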