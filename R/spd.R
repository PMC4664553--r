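#' All-pairs shortest-path distances on a PFN
#'
#' Edge weights (similarities) are transformed to nonnegative lengths, then
#' shortest paths are computed per connected component; unreachable pairs
#' are `Inf`.  The default transform `1 - |s|` maps correlation-type
#' similarities in \[-1, 1\] to lengths in \[0, 1\]; `"inverse"` uses
#' `1 / |s|` for unbounded measures such as mutual information.
#'
#' @param network weighted `igraph`; an unweighted graph gets unit lengths.
#' @param transform `"one_minus_abs"` (default) or `"inverse"`.
#' @param algorithm passed to [igraph::distances()]; Dijkstra by default
#'   since lengths are nonnegative, Bellman-Ford available for parity with
#'   negative-length-capable pipelines.
#' @return symmetric numeric matrix of distances (named by vertex).
#' @export
shortest_path_matrix <- function(network,
                                 transform = c("one_minus_abs", "inverse"),
                                 algorithm = c("dijkstra", "bellman-ford")) {
  transform <- match.arg(transform)
  algorithm <- match.arg(algorithm)
  len <- edge_lengths(network, transform)
  igraph::distances(network, weights = len, algorithm = algorithm)
}

edge_lengths <- function(network, transform = "one_minus_abs") {
  w <- igraph::E(network)$weight
  if (is.null(w)) return(rep(1, igraph::ecount(network)))
  len <- switch(transform,
                one_minus_abs = 1 - abs(w),
                inverse = 1 / abs(w))
  if (any(len < 0)) stop("similarity transform produced negative lengths")
  len
}

#' Local path index (LPI) matrix
#'
#' `LPI = A^2 + epsilon * A^3` on the binary adjacency matrix `A`: the
#' number of 2-step paths plus `epsilon`-weighted 3-step walks between each
#' node pair.  The diagonal is zeroed (closed walks carry no between-node
#' information for boundary reassignment).
#'
#' @param network `igraph`.
#' @param epsilon weight of 3-step walks, default 0.01.
#' @return symmetric dense matrix.
#' @export
lpi_matrix <- function(network, epsilon = 0.01) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A@x[] <- 1
  A2 <- A %*% A
  L <- A2 + epsilon * (A2 %*% A)
  L <- as.matrix(L)
  diag(L) <- 0
  dimnames(L) <- list(igraph::V(network)$name, igraph::V(network)$name)
  L
}

#' Mean within-cluster shortest-path distance
#' @param spd_submatrix square distance submatrix of the cluster's nodes.
#' @return mean over the unordered node pairs.
#' @export
mean_spd <- function(spd_submatrix) {
  n <- nrow(spd_submatrix)
  if (is.null(n) || n < 2L) stop("cluster must contain at least 2 nodes")
  mean(spd_submatrix[upper.tri(spd_submatrix)])
}

#' Cluster compactness at a resolution scale
#'
#' `nu = mean(SPD) / log(|V|)^alpha` with the natural logarithm: the average
#' shortest-path distance within the cluster, normalized by the small-world
#' scaling of the diameter with cluster size.  Smaller values indicate more
#' compact clusters; `alpha` is the resolution parameter (at `alpha = 0`,
#' `nu` is the raw mean distance).
#'
#' @param spd_submatrix square distance submatrix of the cluster's nodes
#'   (at least 2 nodes; sizes below 3 are legal but the log-normalization
#'   inflates them, so such clusters are never scored in the hierarchy).
#' @param alpha resolution parameter, `>= 0`.
#' @return the compactness value `nu`.
#' @export
compactness <- function(spd_submatrix, alpha) {
  stopifnot(alpha >= 0)
  mean_spd(spd_submatrix) / log(nrow(spd_submatrix))^alpha
}
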