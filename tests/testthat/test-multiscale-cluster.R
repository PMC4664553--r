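test_that("shortest paths match hand values and a Floyd-Warshall oracle", {
  # path a-b-c with unit lengths (weight 0 similarity -> length 1)
  pth <- graph_from_edges(data.frame(node1 = c("a", "b"), node2 = c("b", "c"),
                                     weight = c(0, 0)))
  d <- shortest_path_matrix(pth)
  expect_equal(d["a", "c"], 2)
  # triangle with one heavy edge: the detour wins
  tri <- graph_from_edges(data.frame(node1 = c("a", "a", "b"),
                                     node2 = c("b", "c", "c"),
                                     weight = c(0.9, 0.9, 0.1)))
  d <- shortest_path_matrix(tri)  # lengths 0.1, 0.1, 0.9
  expect_equal(d["b", "c"], 0.2)
  # oracle on a random planar network
  g <- t2_random_planar(30, seed = 3)
  igraph::V(g)$name <- paste0("n", 1:30)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 0.9)
  d <- shortest_path_matrix(g)
  len <- matrix(Inf, 30, 30, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  lv <- 1 - abs(igraph::E(g)$weight)
  for (k in seq_len(nrow(el))) {
    len[el[k, 1], el[k, 2]] <- min(len[el[k, 1], el[k, 2]], lv[k])
    len[el[k, 2], el[k, 1]] <- min(len[el[k, 2], el[k, 1]], lv[k])
  }
  expect_equal(d, floyd_warshall(len), tolerance = 1e-12)
  # both algorithms agree
  expect_equal(shortest_path_matrix(g, algorithm = "bellman-ford"), d)
})

test_that("LPI counts 2- and 3-step walks exactly", {
  pth <- graph_from_edges(data.frame(node1 = c("a", "b"), node2 = c("b", "c")))
  L <- lpi_matrix(pth)
  expect_equal(L["a", "c"], 1)        # one 2-path, no 3-walk
  tri <- graph_from_edges(data.frame(node1 = c("a", "a", "b"),
                                     node2 = c("b", "c", "c")))
  L <- lpi_matrix(tri)
  expect_equal(L["a", "b"], 1 + 0.01 * 3)  # 1.03: one 2-path, three 3-walks
  # edgeless graph
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- letters[1:3]
  expect_true(all(lpi_matrix(g0) == 0))
})

test_that("compactness matches the hand-enumerated star and is monotone in
           alpha", {
  # star on 10 nodes with unit lengths: 9 pairs at d=1, 36 at d=2
  st <- igraph::make_star(10, "undirected", center = 1)
  igraph::V(st)$name <- paste0("n", 1:10)
  igraph::E(st)$weight <- 0  # length 1
  spd <- shortest_path_matrix(st)
  expect_equal(mean_spd(spd), 1.8)
  expect_equal(compactness(spd, 1), 1.8 / log(10))
  expect_equal(compactness(spd, 0), mean_spd(spd))  # alpha = 0: raw SPD
  alphas <- c(0.5, 1, 2, 4)
  nus <- vapply(alphas, function(a) compactness(spd, a), 0)
  expect_true(all(diff(nus) < 0))  # |V| > e: strictly decreasing
  expect_error(compactness(spd[1, 1, drop = FALSE], 1), "at least 2")
})

test_that("k-medoids recovers separated blocks and attains the exhaustive
           optimum on a small instance", {
  # two tight blocks far apart
  d <- as.matrix(dist(c(0, 0.1, 0.2, 10, 10.1, 10.2)))
  rownames(d) <- colnames(d) <- paste0("p", 1:6)
  lab <- kmedoids_spd(d, 2)
  expect_equal(length(unique(lab[1:3])), 1L)
  expect_equal(length(unique(lab[4:6])), 1L)
  expect_false(lab[1] == lab[4])
  expect_error(kmedoids_spd(d, 1), "at least 2")
  expect_error(kmedoids_spd(d, 6), "smaller")
  # exhaustive medoid-search oracle, n = 12, k = 3
  set.seed(20)
  pts <- c(rnorm(4, 0, 0.3), rnorm(4, 5, 0.3), rnorm(4, 11, 0.3))
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("q", 1:12)
  lab <- kmedoids_spd(dm, 3)
  obj <- function(medoids) sum(apply(dm[, medoids, drop = FALSE], 1, min))
  best <- min(combn(12, 3, obj))
  got <- sum(vapply(split(seq_len(12), lab), function(ix) {
    min(vapply(ix, function(m) sum(dm[ix, m]), 0))
  }, 0))
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("boundary correction restores mislabeled bridge nodes and is
           idempotent", {
  # two triangles joined by a bridge
  df <- data.frame(node1 = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
                   node2 = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"))
  g <- graph_from_edges(df)
  lpi <- lpi_matrix(g)
  truth <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                    c("a1", "a2", "a3", "b1", "b2", "b3"))
  # mislabel a bridge endpoint
  wrong <- truth; wrong["b1"] <- 1L
  fixed <- boundary_update(wrong, g, lpi)
  expect_identical(fixed, truth[names(fixed)])
  # direct evaluation of the membership rule for the mislabeled node
  mu1 <- sum(lpi["b1", c("a1", "a2", "a3")])
  mu2 <- sum(lpi["b1", c("b2", "b3")])
  expect_gt(mu2, mu1)
  # fixed point: no boundary node moves again
  expect_identical(boundary_update(fixed, g, lpi), fixed)
  # a partition with no boundary nodes is untouched
  comps <- igraph::components(igraph::delete_edges(g, 7))$membership
  expect_identical(boundary_update(setNames(as.integer(comps), names(comps)),
                                   g2 <- igraph::delete_edges(g, 7)),
                   setNames(as.integer(comps), names(comps)))
})

test_that("modularity matches hand computations and separates planted from
           random labels", {
  two_tri <- graph_from_edges(data.frame(
    node1 = c("a1", "a1", "a2", "b1", "b1", "b2"),
    node2 = c("a2", "a3", "a3", "b2", "b3", "b3")))
  labs <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                   c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(newman_modularity(two_tri, labs), 0.5)
  # one community over a connected graph: Q = 0
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("n", 1:6)
  expect_equal(newman_modularity(ring, setNames(rep(1L, 6), paste0("n", 1:6))), 0)
  expect_error(newman_modularity(igraph::make_empty_graph(3, directed = FALSE),
                                 1:3), "empty")
  # planted labels beat random labels on planted-partition planar graphs
  wins <- 0
  for (s in 1:20) {
    rp <- local({
      set.seed(s)
      n <- 24
      sim <- matrix(runif(n * n, 0, 0.2), n)
      blk <- rep(1:2, each = 12)
      boost <- outer(blk, blk, "==") * 0.6
      sim <- pmin((sim + t(sim)) / 2 + boost, 0.95)
      ids <- sprintf("x%02d", 1:n)
      dimnames(sim) <- list(ids, ids)
      filter_and_rank(sim, fdr_threshold = 1)
    })
    g <- build_pfn(rp, saturation = 1, reject_budget_mult = Inf)
    planted <- setNames(rep(1:2, each = 12), sprintf("x%02d", 1:24))
    set.seed(s + 100)
    random <- setNames(sample(planted), names(planted))
    if (newman_modularity(g, planted) > newman_modularity(g, random))
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("k_split finds planted blocks and bounds its exploration", {
  set.seed(77)
  n <- 60
  sim <- matrix(runif(n * n, 0, 0.1), n)
  blk <- rep(1:3, each = 20)
  sim <- pmin((sim + t(sim)) / 2 + outer(blk, blk, "==") * 0.8, 0.95)
  ids <- sprintf("y%02d", 1:n)
  dimnames(sim) <- list(ids, ids)
  g <- build_pfn(filter_and_rank(sim, fdr_threshold = 1),
                 saturation = 1, reject_budget_mult = Inf)
  ks <- k_split(g, dk = 10)
  expect_false(is.null(ks$labels))
  planted <- setNames(blk, ids)
  expect_gte(adjusted_rand(ks$labels[ids], planted), 0.9)
  # exploration stops within dk of the best k
  best_k_tried <- ks$profile$k[which.max(ks$profile$Q)]
  expect_lte(max(ks$profile$k), best_k_tried + 10)
  # a clique-like block refuses to split further than Q allows
  expect_true(all(ks$profile$Q <= ks$Q))
})

test_that("characteristic alpha follows the compactness crossing and
           shrinks with the admissible grid", {
  grid <- mca_alpha_grid()
  # child identical to parent: never more compact
  ca <- characteristic_alpha(2, 50, 2, 50, max(grid), grid)
  expect_true(is.na(ca$alpha_char))
  # very tight child in a loose parent: admissible everywhere up to the bound
  ca <- characteristic_alpha(5, 60, 0.01, 10, max(grid), grid)
  expect_equal(ca$alpha_char, max(grid))
  # moderately tight child: the crossing lands inside the grid
  ca_mid <- characteristic_alpha(5, 60, 0.5, 10, max(grid), grid)
  adm_direct <- grid[0.5 / log(10)^grid < 5 / log(60)^grid]
  expect_equal(ca_mid$admissible, adm_direct)
  expect_equal(ca_mid$alpha_char, max(adm_direct))
  expect_lt(ca_mid$alpha_char, max(grid))
  # lowering the parent bound can only lower or remove the result
  ca2 <- characteristic_alpha(5, 60, 0.5, 10, 1.0, grid)
  expect_lte(ca2$alpha_char, 1.0)
  # split acceptance is strict
  expect_false(split_decision(1, c(1, 1)))
  expect_true(split_decision(1, c(1.2, 0.9)))
  expect_false(split_decision(1, c(1.2, 1.3)))
})

test_that("compactness significance flags a planted near-clique but not the
           parent itself, deterministically", {
  set.seed(5)
  # sparse ring parent with an embedded dense block
  ring_n <- 40
  df <- data.frame(node1 = paste0("r", 1:ring_n),
                   node2 = paste0("r", c(2:ring_n, 1)),
                   weight = runif(ring_n, 0.1, 0.3))
  blk <- t(combn(paste0("r", 1:8), 2))
  df <- rbind(df, data.frame(node1 = blk[, 1], node2 = blk[, 2],
                             weight = runif(nrow(blk), 0.85, 0.95)))
  df <- df[!duplicated(paste(pmin(df$node1, df$node2),
                             pmax(df$node1, df$node2))), ]
  g <- graph_from_edges(df)
  sig <- compactness_significance(g, paste0("r", 1:8), alpha = 1,
                                  n_rand = 100, seed = 42)
  expect_lte(sig$p_value, 0.05)
  # the whole parent as its own "cluster" is not callable
  expect_warning(
    whole <- compactness_significance(g, paste0("r", 1:3), alpha = 1,
                                      n_rand = 10, seed = 1),
    NA)
  sig2 <- compactness_significance(g, paste0("r", 1:8), alpha = 1,
                                   n_rand = 100, seed = 42)
  expect_identical(sig$p_value, sig2$p_value)  # same seed, same p
})

test_that("run_mca returns a forest whose children partition their parents
           and recovers planted modules", {
  d <- planted_design(n_samples = 200, module_sizes = rep(25, 4),
                      loading = 0.8, seed = 31)
  gen <- generate_expression(d)
  pfn <- build_pfn(expression_pairs(gen$expr))
  h <- run_mca(pfn, seed = 13)
  tab <- hierarchy_table(h)
  expect_s3_class(h, "cluster_hierarchy")
  # structural contract: children partition their parent exactly
  for (id in tab$cluster_id) {
    kids <- tab$cluster_id[!is.na(tab$parent_id) & tab$parent_id == id]
    if (length(kids) == 0) next
    kid_nodes <- unlist(lapply(kids, function(k) h$clusters[[k]]$nodes))
    expect_setequal(kid_nodes, h$clusters[[id]]$nodes)
    expect_equal(length(kid_nodes), length(unique(kid_nodes)))
  }
  # roots cover the network
  roots <- tab$cluster_id[is.na(tab$parent_id)]
  expect_setequal(unlist(lapply(roots, function(r) h$clusters[[r]]$nodes)),
                  igraph::V(pfn)$name)
  # planted modules are recovered at some scale
  jac <- sapply(h$alpha_grid, function(a)
    mean(module_jaccards(partition_at_alpha(h, a), gen$modules) >= 0.5))
  expect_gte(max(jac), 0.75)
  # every partition is a valid labeling of all nodes
  p <- partition_at_alpha(h, 1)
  expect_false(anyNA(p))
  expect_setequal(names(p), igraph::V(pfn)$name)
})

test_that("a clique-like block yields a root-only hierarchy", {
  set.seed(6)
  n <- 12
  sim <- matrix(runif(n * n, 0.7, 0.95), n)
  sim <- (sim + t(sim)) / 2
  ids <- sprintf("c%02d", 1:n)
  dimnames(sim) <- list(ids, ids)
  g <- build_pfn(filter_and_rank(sim, fdr_threshold = 1),
                 saturation = 1, reject_budget_mult = Inf)
  h <- run_mca(g, seed = 2)
  tab <- hierarchy_table(h)
  # no significant sub-structure below the root
  sig_children <- tab[!is.na(tab$parent_id) & !is.na(tab$p_value) &
                        tab$p_value <= 0.05, ]
  expect_lte(nrow(sig_children), 1)
})
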