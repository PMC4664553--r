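#' Default resolution-parameter grid
#'
#' Geometric grid of `n` values between `from` and `to`; resolutions
#' observed in practice on co-expression PFNs span roughly 0.03-7, so the
#' default 0.02-10 range brackets them.
#'
#' @param from,to grid end points (both > 0).
#' @param n number of grid points.
#' @return ascending numeric vector.
#' @export
mca_alpha_grid <- function(from = 0.02, to = 10, n = 50L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Split acceptance by compactness improvement
#'
#' A split is accepted at a given resolution iff at least one child is
#' strictly more compact than the parent (`nu_l < nu_o` for some `l`).
#'
#' @param nu_parent parent compactness at the evaluation scale.
#' @param child_nus numeric vector of child compactness values at the same
#'   scale.
#' @return `TRUE` to accept, `FALSE` to reject (ties reject).
#' @export
split_decision <- function(nu_parent, child_nus) {
  any(child_nus < nu_parent)
}

#' Characteristic resolution of a child cluster
#'
#' The largest grid resolution (not exceeding the parent's characteristic
#' value) at which the child is strictly more compact than its parent,
#' comparing `nu` of both at the same alpha.  Because
#' `nu_child(a) / nu_parent(a)` is increasing in `a` for a smaller child,
#' the admissible set is a lower interval of the grid and its maximum is
#' well defined.
#'
#' @param spd_mean_parent,n_parent mean SPD and size of the parent.
#' @param spd_mean_child,n_child mean SPD and size of the child (size >= 3;
#'   smaller clusters return `NA`).
#' @param alpha_parent the parent's characteristic resolution (upper bound).
#' @param alpha_grid ascending grid of candidate resolutions.
#' @return list: `alpha_char` (`NA_real_` if no grid value qualifies) and
#'   `admissible` (the qualifying grid values).
#' @export
characteristic_alpha <- function(spd_mean_parent, n_parent,
                                 spd_mean_child, n_child,
                                 alpha_parent, alpha_grid) {
  if (n_child < 3L || n_child >= n_parent)
    return(list(alpha_char = NA_real_, admissible = numeric(0)))
  grid <- alpha_grid[alpha_grid <= alpha_parent]
  if (length(grid) == 0L)
    return(list(alpha_char = NA_real_, admissible = numeric(0)))
  nu_o <- spd_mean_parent / log(n_parent)^grid
  nu_l <- spd_mean_child / log(n_child)^grid
  adm <- grid[nu_l < nu_o]
  list(alpha_char = if (length(adm)) max(adm) else NA_real_, admissible = adm)
}

#' Significance of a cluster's compactness against a random planar null
#'
#' The null model is a random maximal planar network of the parent's size
#' ([t2_random_planar()]) carrying the parent's link weights (permuted;
#' sampled with replacement when the random network has more edges than the
#' parent).  `n_rand` connected node subsets of the cluster's size are
#' drawn by snowball sampling and their compactness `nu'` computed; the
#' p-value is the add-one-estimated probability that a random subset is at
#' least as compact: `p = (1 + #{nu' <= nu_l}) / (1 + n_rand)`.
#'
#' @param parent_network the parent cluster's subgraph (weighted `igraph`).
#' @param cluster_nodes character vector of the child's node names.
#' @param alpha resolution at which compactness is evaluated.
#' @param n_rand number of null subsets (default 100).
#' @param seed integer seed.
#' @param transform similarity-to-length transform, see
#'   [shortest_path_matrix()].
#' @return list: `p_value`, `nu` (observed), `nu_null` (null values).
#' @export
compactness_significance <- function(parent_network, cluster_nodes, alpha,
                                     n_rand = 100L, seed = NULL,
                                     transform = "one_minus_abs") {
  n_child <- length(cluster_nodes)
  n_parent <- igraph::vcount(parent_network)
  if (n_child < 3L || n_parent < 4L) {
    warning("cluster too small for a compactness null; returning p = 1")
    return(list(p_value = 1, nu = NA_real_, nu_null = numeric(0)))
  }
  sub <- igraph::induced_subgraph(parent_network, cluster_nodes)
  nu_obs <- compactness(shortest_path_matrix(sub, transform), alpha)
  seeds <- derive_seeds(seed, 2L + n_rand)
  gr <- t2_random_planar(n_parent, seed = seeds[[1L]])
  w <- abs(igraph::E(parent_network)$weight)
  if (is.null(w) || length(w) == 0L) w <- rep(0, igraph::ecount(gr))
  m <- igraph::ecount(gr)
  igraph::E(gr)$weight <- with_seed(seeds[[2L]], {
    if (length(w) == m) sample(w) else sample(w, m, replace = TRUE)
  })
  nu_null <- vapply(seq_len(n_rand), function(b) {
    vs <- sample_connected_subset(gr, n_child, seed = seeds[[2L + b]])
    gs <- igraph::induced_subgraph(gr, vs)
    compactness(shortest_path_matrix(gs, transform), alpha)
  }, 0)
  p <- (1 + sum(nu_null <= nu_obs)) / (1 + n_rand)
  list(p_value = p, nu = nu_obs, nu_null = nu_null)
}

#' Multiscale clustering of a planar filtered network
#'
#' Divisive decomposition of a PFN into a cluster hierarchy.  Roots are the
#' connected components.  Each cluster of size >= 4 is split by
#' [k_split()]; every child is carried as a connected cluster (label groups
#' that the boundary correction disconnects are separated into components).
#' A child receives a characteristic resolution via
#' [characteristic_alpha()]; the split is accepted iff at least one child
#' has one.  Accepted children with a characteristic resolution are scored
#' against the random planar null ([compactness_significance()]) and the
#' recursion continues into children that are significant
#' (`p <= sig_threshold`) and large enough.  The recursion stops when no
#' child is more compact than its parent at any admissible resolution, or
#' no child is significantly compact.
#'
#' @param pfn weighted planar `igraph` from [build_pfn()].
#' @param alpha_grid resolution grid (default [mca_alpha_grid()]).
#' @param dk modularity search window for [k_split()].
#' @param n_rand null subsets per significance test.
#' @param sig_threshold significance level for recursing (default 0.05).
#' @param min_size smallest cluster eligible for splitting (default 4).
#' @param seed master seed; all nested Monte-Carlo stages derive from it.
#' @param transform similarity-to-length transform.
#' @param epsilon LPI 3-walk weight.
#' @return a `cluster_hierarchy` object: list of cluster records
#'   (`id`, `parent`, `nodes`, `size`, `spd_mean`, `alpha_char`, `nu`,
#'   `p_value`, `is_root`) plus the grid and settings.  Use
#'   [hierarchy_table()] and [partition_at_alpha()] to consume it.
#' @export
run_mca <- function(pfn, alpha_grid = mca_alpha_grid(), dk = 10L,
                    n_rand = 100L, sig_threshold = 0.05, min_size = 4L,
                    seed = NULL, transform = "one_minus_abs",
                    epsilon = 0.01) {
  alpha_grid <- sort(alpha_grid)
  alpha_max <- max(alpha_grid)
  comp <- igraph::components(pfn)
  clusters <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    paste0("c", counter)
  }
  queue <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- igraph::V(pfn)$name[comp$membership == ci]
    id <- new_id()
    sub <- igraph::induced_subgraph(pfn, nodes)
    spd_mean <- if (length(nodes) >= 2L)
      mean_spd(shortest_path_matrix(sub, transform)) else NA_real_
    clusters[[id]] <- list(id = id, parent = NA_character_, nodes = nodes,
                           size = length(nodes), spd_mean = spd_mean,
                           alpha_char = alpha_max, p_value = NA_real_,
                           is_root = TRUE)
    if (length(nodes) >= min_size) queue[[length(queue) + 1L]] <- id
  }
  seed_pool <- derive_seeds(seed, 1L)[[1L]]
  task <- 0L
  next_seed <- function() {
    if (is.null(seed_pool)) return(NULL)
    task <<- task + 1L
    (seed_pool + task) %% (.Machine$integer.max - 1L)
  }
  while (length(queue) > 0L) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    rec <- clusters[[id]]
    sub <- igraph::induced_subgraph(pfn, rec$nodes)
    spd <- shortest_path_matrix(sub, transform)
    lpi <- lpi_matrix(sub, epsilon)
    ks <- k_split(sub, spd = spd, dk = dk, lpi = lpi)
    if (is.null(ks$labels)) next  # no split with positive modularity
    # children: connected pieces of each label group
    memb <- split(names(ks$labels), ks$labels)
    children <- list()
    for (grp in memb) {
      gs <- igraph::induced_subgraph(sub, grp)
      cc <- igraph::components(gs)
      for (pi in seq_len(cc$no))
        children[[length(children) + 1L]] <-
          igraph::V(gs)$name[cc$membership == pi]
    }
    # characteristic alpha per child
    infos <- lapply(children, function(nodes) {
      if (length(nodes) < 2L)
        return(list(nodes = nodes, spd_mean = NA_real_, alpha_char = NA_real_))
      sm <- mean_spd(spd[nodes, nodes, drop = FALSE])
      ca <- characteristic_alpha(rec$spd_mean, rec$size, sm, length(nodes),
                                 rec$alpha_char, alpha_grid)
      list(nodes = nodes, spd_mean = sm, alpha_char = ca$alpha_char)
    })
    if (!any(vapply(infos, function(x) !is.na(x$alpha_char), TRUE)))
      next  # split rejected: no child more compact at any admissible scale
    for (info in infos) {
      cid <- new_id()
      pval <- NA_real_
      if (!is.na(info$alpha_char)) {
        sig <- compactness_significance(sub, info$nodes, info$alpha_char,
                                        n_rand = n_rand, seed = next_seed(),
                                        transform = transform)
        pval <- sig$p_value
      }
      clusters[[cid]] <- list(id = cid, parent = id, nodes = info$nodes,
                              size = length(info$nodes),
                              spd_mean = info$spd_mean,
                              alpha_char = info$alpha_char, p_value = pval,
                              is_root = FALSE)
      if (length(info$nodes) >= min_size && !is.na(info$alpha_char) &&
          !is.na(pval) && pval <= sig_threshold)
        queue[[length(queue) + 1L]] <- cid
    }
  }
  structure(list(clusters = clusters, alpha_grid = alpha_grid,
                 sig_threshold = sig_threshold,
                 nodes = igraph::V(pfn)$name),
            class = "cluster_hierarchy")
}

#' Tabular view of a cluster hierarchy
#'
#' @param hierarchy a `cluster_hierarchy`.
#' @return data frame with one row per cluster: `cluster_id`, `parent_id`,
#'   `size`, `spd_mean`, `alpha_char`, `nu` (compactness at the cluster's
#'   own characteristic resolution), `p_value`, `node_list`
#'   (comma-separated).
#' @export
hierarchy_table <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "cluster_hierarchy"))
  rows <- lapply(hierarchy$clusters, function(cl) {
    nu <- if (!is.na(cl$alpha_char) && !is.na(cl$spd_mean) && cl$size >= 2L)
      cl$spd_mean / log(cl$size)^cl$alpha_char else NA_real_
    data.frame(cluster_id = cl$id, parent_id = cl$parent, size = cl$size,
               spd_mean = cl$spd_mean, alpha_char = cl$alpha_char, nu = nu,
               p_value = cl$p_value,
               node_list = paste(cl$nodes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @exportS3Method base::print
print.cluster_hierarchy <- function(x, ...) {
  tab <- hierarchy_table(x)
  cat("Multiscale cluster hierarchy:", nrow(tab), "clusters over",
      length(x$nodes), "nodes\n")
  cat("  roots:", sum(is.na(tab$parent_id)),
      " significant non-root clusters (p <=", x$sig_threshold, "):",
      sum(!is.na(tab$p_value) & tab$p_value <= x$sig_threshold), "\n")
  print(utils::head(tab[, c("cluster_id", "parent_id", "size", "alpha_char",
                            "p_value")], 10L))
  invisible(x)
}

#' Flat partition of the network at a resolution scale
#'
#' Assigns every node to the deepest cluster containing it whose
#' characteristic resolution is at least `alpha` and whose compactness is
#' significant (roots always qualify).  This realises the hierarchy as one
#' partition per scale: small `alpha` exposes fine compact clusters, large
#' `alpha` only the coarse ones.
#'
#' @param hierarchy a `cluster_hierarchy`.
#' @param alpha resolution value.
#' @return character vector of cluster ids named by node.
#' @export
partition_at_alpha <- function(hierarchy, alpha) {
  cl <- hierarchy$clusters
  active <- vapply(cl, function(x) {
    x$is_root || (!is.na(x$alpha_char) && x$alpha_char >= alpha &&
                    !is.na(x$p_value) &&
                    x$p_value <= hierarchy$sig_threshold)
  }, TRUE)
  depth <- vapply(cl, function(x) {
    d <- 0L
    p <- x$parent
    while (!is.na(p)) {
      d <- d + 1L
      p <- cl[[p]]$parent
    }
    d
  }, 0L)
  out <- setNames(rep(NA_character_, length(hierarchy$nodes)),
                  hierarchy$nodes)
  ord <- order(depth)  # shallow to deep: deeper assignments overwrite
  for (i in ord) {
    if (!active[i]) next
    # a non-root is usable only if its whole ancestry is active
    ok <- TRUE
    p <- cl[[i]]$parent
    while (!is.na(p)) {
      if (!active[[p]]) { ok <- FALSE; break }
      p <- cl[[p]]$parent
    }
    if (ok) out[cl[[i]]$nodes] <- cl[[i]]$id
  }
  out
}
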