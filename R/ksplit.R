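#' k-medoids partition on a shortest-path distance matrix
#'
#' Thin wrapper around PAM (partitioning around medoids) with the
#' deterministic greedy BUILD initialisation followed by the swap phase, on
#' a precomputed SPD matrix.
#'
#' @param spd_matrix square distance matrix (finite entries).
#' @param k number of clusters, `2 <= k < n`.
#' @return integer label vector named by the matrix's rownames.
#' @export
kmedoids_spd <- function(spd_matrix, k) {
  n <- nrow(spd_matrix)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of nodes")
  if (any(!is.finite(spd_matrix))) stop("distance matrix has non-finite entries")
  fit <- cluster::pam(spd_matrix, k = k, diss = TRUE, keep.diss = FALSE,
                      keep.data = FALSE)
  setNames(as.integer(fit$clustering), rownames(spd_matrix))
}

#' Boundary-node reassignment by local path index
#'
#' Boundary nodes (nodes with neighbours in at least two clusters) are
#' iteratively reassigned to the cluster maximizing their summed LPI to the
#' cluster's members, until the labelling is a fixed point.  Updates are
#' applied asynchronously in node order within each sweep (avoiding the
#' two-cycles a synchronous update can enter); ties keep the current
#' membership (or take the smallest cluster id if the current cluster is
#' not among the maximizers), so the procedure is deterministic.
#'
#' @param labels integer cluster labels named by node.
#' @param network `igraph` over the same nodes.
#' @param lpi LPI matrix from [lpi_matrix()] (computed if missing).
#' @param max_iter sweep cap; a warning is emitted if reached.
#' @return updated label vector (clusters that empty out are dropped).
#' @export
boundary_update <- function(labels, network, lpi = NULL, max_iter = 100L) {
  nodes <- igraph::V(network)$name
  stopifnot(!is.null(names(labels)), all(nodes %in% names(labels)))
  labels <- labels[nodes]
  if (is.null(lpi)) lpi <- lpi_matrix(network)
  adj <- igraph::as_adj_list(network)
  for (it in seq_len(max_iter)) {
    nbr_lab <- lapply(adj, function(v) unique(labels[as.integer(v)]))
    boundary <- which(vapply(nbr_lab, length, 0L) >= 2L)
    changed <- FALSE
    for (i in boundary) {
      ks <- sort(unique(labels))
      mu <- vapply(ks, function(l) sum(lpi[i, labels == l]), 0)
      cand <- ks[mu >= max(mu) - 1e-12]
      cur <- labels[i]
      new <- if (cur %in% cand) cur else min(cand)
      if (new != cur) {
        labels[i] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
    if (it == max_iter)
      warning("boundary update did not converge within ", max_iter,
              " sweeps")
  }
  labels
}

#' Newman modularity of a partition
#'
#' `Q = sum_l (e_ll / m - (d_l / 2m)^2)` on the unweighted graph, where
#' `e_ll` is the number of within-cluster edges and `d_l` the summed degree
#' of cluster `l`.
#'
#' @param network `igraph`.
#' @param labels integer labels named by node.
#' @return modularity value.
#' @export
newman_modularity <- function(network, labels) {
  if (igraph::ecount(network) == 0L) stop("modularity of an empty graph is undefined")
  labels <- labels[igraph::V(network)$name]
  igraph::modularity(network, membership = as.integer(factor(labels)))
}

#' One divisive split: k-medoids + boundary correction, k chosen by modularity
#'
#' Runs [kmedoids_spd()] followed by [boundary_update()] for k = 2, 3, ...,
#' recording the modularity `Q_k` of each corrected partition, and stops
#' once no k within `dk` steps of the current best improves Q.  Returns the
#' argmax-Q partition.  Clusters emptied by the boundary correction are
#' dropped (the effective cluster count can be below k).
#'
#' @param network cluster subgraph to split.
#' @param spd SPD matrix of `network` (computed if missing).
#' @param dk search window beyond the current best k (default 10).
#' @param lpi optional LPI matrix of `network`.
#' @return list: `labels` (best partition, `NULL` when no split with
#'   positive modularity exists), `k` (effective cluster count), `Q`, and
#'   `profile` (data frame of k vs Q).
#' @export
k_split <- function(network, spd = NULL, dk = 10L, lpi = NULL) {
  n <- igraph::vcount(network)
  if (n < 4L) return(list(labels = NULL, k = 1L, Q = NA_real_,
                          profile = data.frame(k = integer(), Q = numeric())))
  if (is.null(spd)) spd <- shortest_path_matrix(network)
  if (is.null(lpi)) lpi <- lpi_matrix(network)
  best_q <- -Inf; best_labels <- NULL; best_k <- 1L
  prof_k <- integer(0); prof_q <- numeric(0)
  k <- 2L
  while (k <= n - 1L && k <= best_k + dk) {
    labels <- kmedoids_spd(spd, k)
    labels <- boundary_update(labels, network, lpi)
    q <- if (length(unique(labels)) < 2L) -Inf
         else newman_modularity(network, labels)
    prof_k <- c(prof_k, k); prof_q <- c(prof_q, q)
    if (q > best_q) {
      best_q <- q
      best_labels <- labels
      best_k <- k
    }
    k <- k + 1L
  }
  if (!is.finite(best_q) || best_q <= 0)
    return(list(labels = NULL, k = 1L, Q = best_q,
                profile = data.frame(k = prof_k, Q = prof_q)))
  # relabel 1..K in order of appearance
  best_labels <- setNames(as.integer(factor(best_labels,
                                            levels = unique(best_labels))),
                          names(best_labels))
  list(labels = best_labels, k = length(unique(best_labels)), Q = best_q,
       profile = data.frame(k = prof_k, Q = prof_q))
}
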