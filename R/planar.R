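#' Test whether a graph is planar
#'
#' Linear-time planarity test based on the left-right criterion, applied to
#' the graph as a whole (a graph is planar iff all of its connected
#' components are).
#'
#' @param graph an `igraph` object, or a 2-column edge matrix (character or
#'   integer endpoints).
#' @param n_nodes number of nodes when `graph` is an integer edge matrix
#'   whose vertices are `1..n_nodes`; ignored for `igraph` input.
#' @return `TRUE` iff the graph can be embedded in the plane (equivalently,
#'   on the sphere).
#' @examples
#' is_planar(igraph::make_full_graph(4))  # TRUE
#' is_planar(igraph::make_full_graph(5))  # FALSE: K5
#' @export
is_planar <- function(graph, n_nodes = NULL) {
  el <- edge_matrix0(graph, n_nodes)
  .lr_planar_cpp(el$edges, el$n)
}

# normalize graph input to a 0-based integer edge matrix + node count
edge_matrix0 <- function(graph, n_nodes = NULL) {
  if (inherits(graph, "igraph")) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    storage.mode(el) <- "integer"
    return(list(edges = el - 1L, n = igraph::vcount(graph)))
  }
  if (is.matrix(graph) && ncol(graph) == 2L) {
    if (is.character(graph)) {
      ids <- sort(unique(as.vector(graph)))
      el <- matrix(match(graph, ids), ncol = 2L)
      return(list(edges = el - 1L, n = length(ids), ids = ids))
    }
    el <- graph
    storage.mode(el) <- "integer"
    n <- if (is.null(n_nodes)) max(el, 0L) else as.integer(n_nodes)
    return(list(edges = el - 1L, n = n))
  }
  stop("`graph` must be an igraph object or a 2-column edge matrix")
}

#' Maximum edge count of a planar graph (Euler relation)
#'
#' A simple planar graph on `n >= 3` nodes has at most `3 * (n - 2)` edges;
#' planar maximally filtered graphs attain this bound.
#'
#' @param n_nodes integer node count, `>= 3`.
#' @return integer, `3 * (n_nodes - 2)`.
#' @examples
#' euler_max_edges(3)  # 3: a triangle
#' @export
euler_max_edges <- function(n_nodes) {
  if (any(n_nodes < 3)) stop("the Euler bound requires n_nodes >= 3")
  as.integer(round(3 * (n_nodes - 2)))
}

# ranked_pairs -> 0-based integer pair matrix over the node universe
pairs_matrix0 <- function(pairs) {
  stopifnot(inherits(pairs, "ranked_pairs"))
  nodes <- attr(pairs, "nodes")
  cbind(match(pairs$node1, nodes), match(pairs$node2, nodes)) - 1L
}

pfn_graph <- function(pairs, accepted_idx, nodes) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$node1[accepted_idx], to = pairs$node2[accepted_idx],
               weight = pairs$similarity[accepted_idx]),
    directed = FALSE, vertices = data.frame(name = nodes))
  g
}

#' Serial planar maximally filtered graph (PMFG) embedding
#'
#' Reference construction: walks the ranked pair list in order and accepts
#' each pair iff the graph including it remains planar, stopping only when
#' the Euler bound is reached or the list is exhausted.  Rejections are
#' permanent because the graph only grows.
#'
#' @param pairs a `ranked_pairs` data frame (see [filter_and_rank()]).
#' @return an `igraph` planar network; edge attribute `weight` carries the
#'   (signed) similarity.
#' @export
serial_embed <- function(pairs) {
  nodes <- attr(pairs, "nodes")
  pm <- pairs_matrix0(pairs)
  acc <- .pmfg_serial_cpp(pm, length(nodes))
  g <- pfn_graph(pairs, acc, nodes)
  g$termination <- "exhausted"
  g$n_accepted <- length(acc)
  g
}

#' Screen candidate pairs against a fixed planar graph
#'
#' For each candidate pair `ij`, tests independently whether `G + ij` is
#' planar.  Because any subgraph of a planar graph is planar and the
#' embedding only grows `G`, a candidate failing this screen can never be
#' accepted later; the screen is therefore a safe batched pre-filter whose
#' result does not depend on evaluation order.
#'
#' @param graph planar `igraph` over the same node universe as `candidates`.
#' @param candidates 2-column character matrix (or data frame with `node1`,
#'   `node2`) of candidate pairs.
#' @return logical vector: `TRUE` for candidates that embed on `graph`.
#' @export
pcp_screen <- function(graph, candidates) {
  if (is.data.frame(candidates))
    candidates <- as.matrix(candidates[, c("node1", "node2")])
  nodes <- igraph::V(graph)$name
  idx <- matrix(match(candidates, nodes), ncol = 2L)
  if (anyNA(idx)) stop("candidate nodes missing from `graph`")
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  .pcp_screen_cpp(el - 1L, igraph::vcount(graph), idx - 1L)
}

#' Build a planar filtered network (PFN) from ranked pairs
#'
#' Orchestrates the full construction: a serial embedding phase and, once
#' the sliding-window acceptance rate drops below `pcp_trigger`, a batched
#' screening phase in which blocks of `batch_size` candidates are pre-tested
#' against the current graph before the surviving pairs are embedded
#' serially in rank order.  The screened construction returns the same edge
#' set as the purely serial one; screening only removes pairs that are
#' certain to be rejected.
#'
#' Construction stops at the first satisfied condition:
#' \itemize{
#'   \item the pair list is exhausted (maximal embedding),
#'   \item the edge count reaches `ceiling(saturation * 3 * (|V| - 2))`,
#'   \item the cumulative number of rejected pairs reaches
#'     `reject_budget_mult * |V|`.
#' }
#'
#' @param pairs a `ranked_pairs` data frame.
#' @param saturation fraction of the Euler bound at which to stop, in
#'   (0, 1]; default 0.95.  Use 1 for a full PMFG.
#' @param reject_budget_mult stop after this many rejected pairs per node
#'   (default 20); `Inf` disables the budget.
#' @param use_pcp enable the batched screening phase (default `TRUE`).
#' @param batch_size candidates per screening batch; the reference setting
#'   is 1000 per worker (default 1000).
#' @param pcp_trigger acceptance-rate threshold that activates screening
#'   (default 0.10).
#' @param window number of most recent tested pairs over which the
#'   acceptance rate is measured (default 1000).
#' @return an `igraph` PFN.  Graph attributes record the termination
#'   condition (`"exhausted"`, `"saturation"` or `"reject_budget"`) and the
#'   tested/accepted/rejected counters; `$acceptance_rate` is
#'   `|E| / (3 (|V|-2))`.
#' @export
build_pfn <- function(pairs, saturation = 0.95, reject_budget_mult = 20,
                      use_pcp = TRUE, batch_size = 1000L,
                      pcp_trigger = 0.10, window = 1000L) {
  if (!is.numeric(saturation) || saturation <= 0 || saturation > 1)
    stop("`saturation` must lie in (0, 1]")
  if (nrow(pairs) == 0L) stop("empty pair list")
  nodes <- attr(pairs, "nodes")
  n <- length(nodes)
  pm <- pairs_matrix0(pairs)
  emax <- if (n >= 3) euler_max_edges(n) else 1L
  cap <- as.integer(ceiling(saturation * emax))
  budget <- if (is.finite(reject_budget_mult)) reject_budget_mult * n else -1
  res <- .fpfnc_cpp(pm, n, cap, budget, isTRUE(use_pcp),
                    as.integer(batch_size), pcp_trigger, as.integer(window))
  g <- pfn_graph(pairs, res$accepted, nodes)
  g$termination <- c("exhausted", "saturation", "reject_budget")[res$termination + 1L]
  g$n_tested <- res$n_tested
  g$n_accepted <- res$n_accepted
  g$n_rejected <- res$n_rejected
  g$n_batches <- res$n_batches
  g$pcp_activated <- as.numeric(res$pcp_activated)  # numeric: GML-safe
  g$acceptance_rate <- res$n_accepted / emax
  g
}

#' Topological diagnostics of a network
#'
#' Fits a power law to the inverse-cumulative (complementary CDF) degree
#' distribution by ordinary least squares on log-log scale and reports the
#' implied degree exponent `gamma` (density exponent, `P(k) ~ k^-gamma`,
#' recovered from the CCDF slope as `gamma = 1 - slope`), together with the
#' unweighted diameter of the largest connected component.
#'
#' @param network an `igraph` object.
#' @return list with `gamma` (NA when the degree sequence is degenerate,
#'   i.e. fewer than 3 distinct positive degrees), `degenerate` flag,
#'   `diameter`, and the fitted points (`fit`: degree, ccdf).
#' @export
degree_diagnostics <- function(network) {
  deg <- igraph::degree(network)
  ks <- sort(unique(deg[deg > 0]))
  ccdf <- vapply(ks, function(k) mean(deg > k), 0)
  keep <- ccdf > 0
  fit <- data.frame(k = ks[keep], ccdf = ccdf[keep])
  degenerate <- nrow(fit) < 3L
  gamma <- NA_real_
  if (!degenerate) {
    sl <- stats::coef(stats::lm(log10(ccdf) ~ log10(k), data = fit))[2L]
    gamma <- unname(1 - sl)
  }
  comp <- igraph::components(network)
  giant <- igraph::induced_subgraph(network,
                                    which(comp$membership == which.max(comp$csize)))
  diam <- igraph::diameter(giant, weights = NA)
  list(gamma = gamma, degenerate = degenerate, diameter = diam, fit = fit)
}
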