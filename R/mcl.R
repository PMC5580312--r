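#' Markov clustering of a weighted graph
#'
#' Standard MCL on an undirected non-negatively weighted graph: self-loops
#' are added with the node's maximum incident weight (1 for isolated nodes),
#' columns are normalised to a stochastic matrix, and expansion (matrix
#' squaring) alternates with inflation (elementwise power and renormalising)
#' and pruning of small entries until the matrix stops changing. Clusters are
#' the connected components of the non-zero pattern of the limit matrix, in
#' which every node is attached to its attractor(s); a node drawn to several
#' attractors is resolved into the component where its steady-state mass is
#' largest, which the component construction yields directly.
#'
#' @param edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (>= 0), or a 3-column matrix; at most one edge per unordered pair.
#' @param nodes optional character vector of node ids (to include isolated
#'   nodes); defaults to the ids present in \code{edges}.
#' @param inflation inflation exponent (default 2).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @param max_iter iteration cap; non-convergence returns the current
#'   partition with a warning.
#' @return object of class \code{cluster_set}: list with \code{membership}
#'   (named integer vector), \code{clusters} (list of character vectors,
#'   decreasing size), \code{inflation}, \code{iterations},
#'   \code{converged}.
#' @examples
#' tri <- data.frame(from = c("a","b","c","x","y","z"),
#'                   to   = c("b","c","a","y","z","x"), weight = 1)
#' mcl_cluster(tri)$clusters
#' @export
mcl_cluster <- function(edges, nodes = NULL, inflation = 2, prune = 1e-5,
                        tol = 1e-6, max_iter = 100L) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    names(edges)[1:3] <- c("from", "to", "weight")
    stopifnot(all(edges$weight >= 0))
  }
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  n <- length(nodes)
  stopifnot(n >= 1)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$from, nodes); j <- match(edges$to, nodes)
    M[cbind(i, j)] <- pmax(M[cbind(i, j)], edges$weight)
    M[cbind(j, i)] <- M[cbind(i, j)]
  }
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalise <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  M <- normalise(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M             # expansion
    M2 <- M2^inflation        # inflation
    M2[M2 < prune] <- 0
    M2 <- normalise(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations; returning current partition")
  adj <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- clusters[order(-vapply(clusters, length, 0L),
                             vapply(clusters, function(x) min(x), ""))]
  names(clusters) <- NULL
  clusters <- lapply(clusters, sort)
  membership <- setNames(rep(seq_along(clusters), lengths(clusters)),
                         unlist(clusters))
  out <- list(membership = membership[nodes], clusters = clusters,
              inflation = inflation, iterations = it, converged = converged)
  class(out) <- "cluster_set"
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set>", length(x$membership), "nodes in", length(x$clusters),
      "clusters (inflation", x$inflation, ",", x$iterations, "iterations)\n")
  invisible(x)
}

#' Read / write graphs in ABC format
#'
#' Tab-separated \code{from to weight} lines, the common interchange format
#' of MCL implementations.
#'
#' @param path file path.
#' @return \code{read_abc}: a data.frame with \code{from}, \code{to},
#'   \code{weight}.
#' @export
read_abc <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("from", "to", "weight")[seq_len(ncol(d))]
  if (is.null(d$weight)) d$weight <- 1
  d
}

#' @rdname read_abc
#' @param edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
write_abc <- function(edges, path) {
  write.table(edges[, c("from", "to", "weight")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
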