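#' Within-cluster connectivity of every node
#'
#' For each node, the summed magnitude of edge weights to neighbours in the
#' same cluster (`c^w(v_i, alpha)` for the partition at a scale).
#' Singleton clusters contribute 0.
#'
#' @param pfn weighted `igraph`.
#' @param membership cluster labels named by node (e.g. from
#'   [partition_at_alpha()]).
#' @return numeric vector named by node.
#' @export
within_cluster_connectivity <- function(pfn, membership) {
  nodes <- igraph::V(pfn)$name
  membership <- membership[nodes]
  el <- igraph::as_edgelist(pfn, names = TRUE)
  w <- abs(igraph::E(pfn)$weight)
  if (is.null(w)) w <- rep(1, nrow(el))
  same <- membership[el[, 1L]] == membership[el[, 2L]] &
    !is.na(membership[el[, 1L]]) & !is.na(membership[el[, 2L]])
  cw <- setNames(numeric(length(nodes)), nodes)
  if (any(same)) {
    add1 <- tapply(w[same], el[same, 1L], sum)
    add2 <- tapply(w[same], el[same, 2L], sum)
    cw[names(add1)] <- cw[names(add1)] + add1
    cw[names(add2)] <- cw[names(add2)] + add2
  }
  cw
}

#' Internal validity indices of a partition
#'
#' Four standard internal indices on a dissimilarity matrix, all oriented
#' so that larger values indicate better clusterings:
#' \itemize{
#'   \item average silhouette width,
#'   \item normalized Hubert Gamma: the raw Gamma statistic (mean distance
#'     between pairs in different clusters) standardized against `n_perm`
#'     random relabelings,
#'   \item Dunn's index: minimum between-cluster (single-linkage) distance
#'     over maximum within-cluster diameter,
#'   \item separation index: mean between-cluster distance over mean
#'     within-cluster distance.
#' }
#'
#' @param labels integer labels (>= 2 nonempty clusters).
#' @param distance_matrix square dissimilarity matrix.
#' @param n_perm permutations for the Gamma normalization.
#' @param seed integer seed for the permutations.
#' @return named numeric vector: `silhouette`, `normalized_gamma`, `dunn`,
#'   `separation`.
#' @export
validity_indices <- function(labels, distance_matrix, n_perm = 100L,
                             seed = NULL) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  stopifnot(nrow(distance_matrix) == n)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  if (max(tabulate(labels)) < 2L)
    stop("validity indices undefined for singleton-only clusterings")
  ut <- upper.tri(distance_matrix)
  dv <- distance_matrix[ut]
  between <- outer(labels, labels, "!=")[ut]
  sil <- mean(cluster::silhouette(labels, dmatrix = distance_matrix)[, "sil_width"])
  gamma_raw <- function(btw) mean(dv[btw])
  g_obs <- gamma_raw(between)
  g_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    lb <- sample(labels)
    gamma_raw(outer(lb, lb, "!=")[ut])
  }, 0))
  sdg <- sd(g_perm)
  ngamma <- if (is.na(sdg) || sdg == 0) 0 else (g_obs - mean(g_perm)) / sdg
  min_between <- min(dv[between])
  max_diam <- max(dv[!between], 0)
  dunn <- if (max_diam == 0) Inf else min_between / max_diam
  mean_within <- mean(dv[!between])
  separation <- if (is.nan(mean_within) || mean_within == 0) Inf
                else mean(dv[between]) / mean_within
  c(silhouette = sil, normalized_gamma = ngamma, dunn = dunn,
    separation = separation)
}

#' Combined normalized-rank score over candidate cluster numbers
#'
#' Each internal index ranks the candidate k values (rank 1 = best under
#' that index); the combined score of k is the summed log of its normalized
#' ranks, `score(k) = sum_m log(rank(k, m) / (n_scales - 1))`, and the
#' chosen k minimizes the score (ties take the smallest k).
#'
#' @param index_table data frame with a `k` column and one column per
#'   index (all oriented larger-is-better).
#' @param n_scales the normalization constant `|Phi|` (defaults to
#'   `nrow(index_table) + 1`, i.e. k ranges over `2..|Phi| - 1`).
#' @return list: `k` (chosen), `scores` (data frame of k and score).
#' @export
combined_rank_score <- function(index_table, n_scales = nrow(index_table) + 1L) {
  stopifnot("k" %in% names(index_table), nrow(index_table) >= 1L)
  idx_cols <- setdiff(names(index_table), "k")
  denom <- max(n_scales - 1L, 2L)
  ranks <- vapply(idx_cols, function(m) {
    v <- index_table[[m]]
    as.numeric(rank(-v, ties.method = "min"))
  }, numeric(nrow(index_table)))
  ranks <- matrix(ranks, nrow = nrow(index_table))
  score <- rowSums(log(ranks / denom))
  k <- index_table$k[order(score, index_table$k)][1L]
  list(k = k, scores = data.frame(k = index_table$k, score = score))
}

#' Group resolution scales by their connectivity profiles
#'
#' Scales (columns of the connectivity matrix `C^w`) are clustered by
#' k-medoids on the pairwise Euclidean distances between their per-node
#' connectivity vectors; the number of groups is chosen by
#' [combined_rank_score()] over the internal validity indices for
#' `k = 2 .. n_scales - 1`.  Fewer than 3 scales form a single group.
#'
#' @param cw nodes x scales connectivity matrix (columns named by alpha).
#' @param seed integer seed (used by the Gamma normalization).
#' @param max_k optional cap on the candidate group counts.
#' @return list: `labels` (group id per scale), `groups` (list of scale
#'   names per group), `k`, `indices` (the validity table) and `scores`.
#' @export
group_scales <- function(cw, seed = NULL, max_k = NULL) {
  ns <- ncol(cw)
  scale_names <- colnames(cw)
  if (ns < 3L) {
    labels <- setNames(rep(1L, ns), scale_names)
    return(list(labels = labels, groups = list(scale_names), k = 1L,
                indices = NULL, scores = NULL))
  }
  d <- as.matrix(dist(t(cw)))
  kmax <- ns - 1L
  if (!is.null(max_k)) kmax <- min(kmax, max_k)
  seeds <- derive_seeds(seed, kmax)
  rows <- list()
  parts <- list()
  for (k in 2L:kmax) {
    lab <- kmedoids_spd(d, k)
    parts[[as.character(k)]] <- lab
    vi <- tryCatch(validity_indices(lab, d, seed = seeds[[k]]),
                   error = function(e) NULL)
    if (is.null(vi)) next
    rows[[as.character(k)]] <- data.frame(k = k, t(vi))
  }
  if (length(rows) == 0L) {
    labels <- setNames(rep(1L, ns), scale_names)
    return(list(labels = labels, groups = list(scale_names), k = 1L,
                indices = NULL, scores = NULL))
  }
  tab <- do.call(rbind, rows)
  pick <- combined_rank_score(tab, n_scales = ns)
  labels <- parts[[as.character(pick$k)]]
  groups <- split(scale_names, labels)
  list(labels = labels, groups = unname(groups), k = pick$k,
       indices = tab, scores = pick$scores)
}

#' Hub p-values for one cluster against random planar nulls
#'
#' Generates `n_s` random maximal planar networks of the cluster's size
#' carrying weights resampled from the cluster's own edge weights, and for
#' each member node computes the add-one estimate of the probability that a
#' random node is at least as connected:
#' `p_i = (1 + mean #\{random nodes with connectivity >= c^w_i\}) / (1 + |V_l|)`.
#'
#' @param cluster_graph the cluster's weighted subgraph.
#' @param n_s number of random networks (default 100).
#' @param seed integer seed.
#' @return numeric p-values named by node (all 1 for clusters below 3
#'   nodes).
#' @export
hub_pvalues <- function(cluster_graph, n_s = 100L, seed = NULL) {
  nodes <- igraph::V(cluster_graph)$name
  nl <- length(nodes)
  if (nl < 3L)
    return(setNames(rep(1, nl), nodes))
  w <- abs(igraph::E(cluster_graph)$weight)
  if (is.null(w) || length(w) == 0L) w <- 1
  cw <- igraph::strength(cluster_graph,
                         weights = abs(igraph::E(cluster_graph)$weight))
  seeds <- derive_seeds(seed, 2L * n_s)
  null_conn <- unlist(lapply(seq_len(n_s), function(b) {
    gr <- t2_random_planar(nl, seed = seeds[[2L * b - 1L]])
    m <- igraph::ecount(gr)
    wr <- with_seed(seeds[[2L * b]],
                    if (length(w) == m) sample(w) else sample(w, m, replace = TRUE))
    igraph::strength(gr, weights = wr)
  }))
  ns_sorted <- sort(null_conn)
  cnt_ge <- length(ns_sorted) - findInterval(cw, ns_sorted, left.open = TRUE)
  setNames((1 + cnt_ge / n_s) / (1 + nl), nodes)
}

#' Combined multiscale hub statistic
#'
#' `S_i = sum over the scale group of -log10 p_i(alpha)`; zero p-values are
#' clipped to the smallest positive double with a warning.
#'
#' @param p_values vector of per-scale p-values in (0, 1].
#' @return the combined statistic (0 when all p = 1).
#' @export
multiscale_hub_statistic <- function(p_values) {
  if (any(p_values == 0, na.rm = TRUE)) {
    warning("p = 0 clipped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  sum(-log10(p_values), na.rm = TRUE)
}

#' Significance of combined hub statistics
#'
#' Builds the null by shuffling the node x scale p-value matrix over both
#' dimensions `N_s` times, recomputing the combined statistic for every
#' node each time, and pooling all null statistics.  Nominal p-values use
#' the add-one exceedance estimator and are Bonferroni-corrected for the
#' number of network nodes.
#'
#' @param p_matrix nodes x scales matrix of per-scale hub p-values.
#' @param N_s number of shuffles (default 100).
#' @param n_network_nodes Bonferroni denominator (defaults to
#'   `nrow(p_matrix)`).
#' @param seed integer seed.
#' @param sig_threshold hub call threshold on the corrected p (default
#'   0.05).
#' @return data frame: `node`, `S`, `p_nominal`, `p_corrected`, `is_hub`.
#' @export
hub_significance <- function(p_matrix, N_s = 100L,
                             n_network_nodes = nrow(p_matrix), seed = NULL,
                             sig_threshold = 0.05) {
  stopifnot(is.matrix(p_matrix))
  pm <- pmax(p_matrix, .Machine$double.xmin)
  S <- rowSums(-log10(pm))
  null_S <- with_seed(seed, {
    unlist(lapply(seq_len(N_s), function(b) {
      shuf <- matrix(sample(pm), nrow = nrow(pm))
      rowSums(-log10(shuf))
    }))
  })
  ns_sorted <- sort(null_S)
  cnt <- length(ns_sorted) - findInterval(S, ns_sorted, left.open = TRUE)
  p_nom <- (1 + cnt) / (1 + length(ns_sorted))
  p_cor <- pmin(1, p_nom * n_network_nodes)
  data.frame(node = rownames(p_matrix), S = S, p_nominal = p_nom,
             p_corrected = p_cor, is_hub = p_cor < sig_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect hub sets across scale groups
#' @param hub_sets list of character vectors (one per scale group).
#' @return character vector of nodes significant in every group.
#' @export
intersect_multiscale_hubs <- function(hub_sets) {
  stopifnot(length(hub_sets) >= 1L)
  Reduce(intersect, hub_sets)
}

#' Multiscale hub analysis of a clustered PFN
#'
#' End-to-end hub identification: determines the scale set Phi (grid
#' resolutions whose partition contains at least one significant cluster),
#' computes the within-cluster connectivity matrix `C^w`, groups scales by
#' connectivity profile, scores every node's per-scale connectivity against
#' random planar nulls, combines evidence within each scale group and calls
#' hubs at Bonferroni-corrected p < `sig_threshold`; multiscale hubs are
#' hubs in every scale group.
#'
#' @param pfn weighted planar `igraph`.
#' @param hierarchy a `cluster_hierarchy` from [run_mca()].
#' @param n_s random networks per cluster for per-scale p-values.
#' @param N_s shuffles for the combined-statistic null.
#' @param sig_threshold hub threshold on the corrected p.
#' @param seed master seed.
#' @return a `hub_analysis` list: `table` (node x scale-group hub table),
#'   `multiscale_hubs`, `scale_groups`, `phi`, `cw`, `p_matrix`.
#' @export
run_mha <- function(pfn, hierarchy, n_s = 100L, N_s = 100L,
                    sig_threshold = 0.05, seed = NULL) {
  nodes <- igraph::V(pfn)$name
  grid <- hierarchy$alpha_grid
  parts <- lapply(grid, function(a) partition_at_alpha(hierarchy, a))
  names(parts) <- format_alpha(grid)
  # Phi: scales whose partition includes a significant non-root cluster
  sig_ids <- names(Filter(function(cl) {
    !cl$is_root && !is.na(cl$p_value) && cl$p_value <= hierarchy$sig_threshold
  }, hierarchy$clusters))
  in_phi <- vapply(parts, function(p) any(p %in% sig_ids), TRUE)
  if (!any(in_phi)) {
    return(structure(list(table = data.frame(), multiscale_hubs = character(0),
                          scale_groups = list(), phi = numeric(0),
                          cw = NULL, p_matrix = NULL),
                     class = "hub_analysis"))
  }
  phi <- grid[in_phi]
  parts <- parts[in_phi]
  cw <- vapply(parts, function(p) within_cluster_connectivity(pfn, p),
               numeric(length(nodes)))
  rownames(cw) <- nodes
  seeds <- derive_seeds(seed, 3L)
  sg <- group_scales(cw, seed = seeds[[1L]])
  # per-scale hub p-values, cached per cluster id (clusters recur across
  # many scales)
  cache <- new.env(parent = emptyenv())
  cseeds <- new.env(parent = emptyenv())
  cluster_p <- function(cid) {
    if (!is.null(cache[[cid]])) return(cache[[cid]])
    rec <- hierarchy$clusters[[cid]]
    sub <- igraph::induced_subgraph(pfn, rec$nodes)
    if (is.null(cseeds[[cid]])) {
      cseeds[[cid]] <- if (is.null(seeds[[2L]])) NULL else
        (seeds[[2L]] + length(ls(cseeds))) %% (.Machine$integer.max - 1L)
    }
    cache[[cid]] <- hub_pvalues(sub, n_s = n_s, seed = cseeds[[cid]])
    cache[[cid]]
  }
  p_matrix <- matrix(1, nrow = length(nodes), ncol = length(phi),
                     dimnames = list(nodes, colnames(cw)))
  for (j in seq_along(phi)) {
    part <- parts[[j]]
    for (cid in unique(part[!is.na(part)])) {
      members <- names(part)[!is.na(part) & part == cid]
      if (length(members) < 3L) next
      pv <- cluster_p(cid)
      p_matrix[members, j] <- pv[members]
    }
  }
  # combine within each scale group
  out_rows <- list()
  hub_sets <- list()
  gseeds <- derive_seeds(seeds[[3L]], length(sg$groups))
  for (gi in seq_along(sg$groups)) {
    cols <- sg$groups[[gi]]
    sub_p <- p_matrix[, cols, drop = FALSE]
    hs <- hub_significance(sub_p, N_s = N_s,
                           n_network_nodes = length(nodes),
                           seed = gseeds[[gi]],
                           sig_threshold = sig_threshold)
    hs$scale_group <- gi
    hs$cw <- rowMeans(cw[, cols, drop = FALSE])[hs$node]
    out_rows[[gi]] <- hs
    hub_sets[[gi]] <- hs$node[hs$is_hub]
  }
  tab <- do.call(rbind, out_rows)
  ms <- intersect_multiscale_hubs(hub_sets)
  tab$is_multiscale_hub <- tab$node %in% ms
  tab <- tab[, c("node", "scale_group", "cw", "S", "p_nominal",
                 "p_corrected", "is_hub", "is_multiscale_hub")]
  structure(list(table = tab, multiscale_hubs = ms,
                 scale_groups = sg, phi = phi, cw = cw,
                 p_matrix = p_matrix),
            class = "hub_analysis")
}

format_alpha <- function(a) formatC(a, format = "g", digits = 6)

#' @exportS3Method base::print
print.hub_analysis <- function(x, ...) {
  cat("Multiscale hub analysis:", length(x$phi), "scales in",
      length(x$scale_groups$groups), "groups;",
      length(x$multiscale_hubs), "multiscale hubs\n")
  if (length(x$multiscale_hubs))
    cat("  multiscale hubs:", paste(utils::head(x$multiscale_hubs, 10L),
                                    collapse = ", "), "\n")
  invisible(x)
}
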