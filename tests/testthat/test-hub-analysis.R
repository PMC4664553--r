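test_that("within-cluster connectivity matches hand values and a brute-force
           oracle, and columns conserve total within weight", {
  tri <- graph_from_edges(data.frame(node1 = c("a", "a", "b"),
                                     node2 = c("b", "c", "c"),
                                     weight = 0.5))
  memb <- setNames(rep("x", 3), c("a", "b", "c"))
  cw <- within_cluster_connectivity(tri, memb)
  expect_equal(unname(cw[c("a", "b", "c")]), c(1, 1, 1))
  # a node whose neighbours are all outside its cluster scores 0
  memb2 <- setNames(c("x", "y", "y"), c("a", "b", "c"))
  expect_equal(unname(within_cluster_connectivity(tri, memb2)["a"]), 0)
  # oracle on a random membership
  g <- t2_random_planar(30, seed = 12)
  igraph::V(g)$name <- paste0("n", 1:30)
  igraph::E(g)$weight <- runif(igraph::ecount(g))
  set.seed(1)
  memb3 <- setNames(sample(1:3, 30, TRUE), igraph::V(g)$name)
  cw3 <- within_cluster_connectivity(g, memb3)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  oracle <- vapply(igraph::V(g)$name, function(v)
    sum(A[v, names(memb3)[memb3 == memb3[v]]]), 0)
  expect_equal(cw3, oracle)
  expect_equal(sum(cw3), 2 * sum(igraph::E(g)$weight[apply(
    igraph::as_edgelist(g), 1, function(e) memb3[e[1]] == memb3[e[2]])]))
})

test_that("validity indices behave at the extremes and silhouette matches a
           direct a/b oracle", {
  # two clusters, zero within-distance, positive between-distance
  d <- matrix(5, 6, 6); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  vi <- validity_indices(rep(1:2, each = 3), d, n_perm = 50, seed = 1)
  expect_equal(unname(vi["silhouette"]), 1)
  expect_true(is.infinite(vi["dunn"]))
  expect_gt(vi["normalized_gamma"], 0)
  # random labels on random distances: silhouette near zero
  set.seed(8)
  sils <- replicate(100, {
    dm <- as.matrix(dist(runif(12)))
    validity_indices(sample(1:2, 12, TRUE), dm, n_perm = 5, seed = 2)["silhouette"]
  })
  expect_lt(abs(mean(sils)), 0.1)
  # direct silhouette oracle on a 10-point example
  set.seed(9)
  x <- c(rnorm(5), rnorm(5, 4))
  dm <- as.matrix(dist(x))
  lab <- rep(1:2, each = 5)
  a <- vapply(1:10, function(i) mean(dm[i, setdiff(which(lab == lab[i]), i)]), 0)
  b <- vapply(1:10, function(i) mean(dm[i, which(lab != lab[i])]), 0)
  expect_equal(unname(validity_indices(lab, dm, n_perm = 5, seed = 3)["silhouette"]),
               mean((b - a) / pmax(a, b)))
  expect_error(validity_indices(1:6, d), "singleton")
})

test_that("combined rank score reproduces a hand-evaluated toy table and is
           monotone in ranks", {
  tab <- data.frame(k = 2:6,
                    silhouette = c(0.9, 0.5, 0.4, 0.3, 0.2),
                    dunn = c(2.0, 1.0, 0.9, 0.8, 0.7),
                    gamma = c(3.0, 2.0, 1.5, 1.0, 0.5),
                    sep = c(1.8, 1.1, 1.0, 0.9, 0.8))
  pick <- combined_rank_score(tab, n_scales = 6)
  expect_equal(pick$k, 2)  # rank 1 by every index: dominant
  # hand evaluation: score(k) = sum_m log(rank / (6 - 1))
  hand <- vapply(seq_len(5), function(r) 4 * log(r / 5), 0)
  expect_equal(pick$scores$score, hand)
  # worsening one rank strictly increases that k's score
  tab2 <- tab
  tab2$dunn[1] <- 0.1  # k=2 drops to rank 5 under dunn
  pick2 <- combined_rank_score(tab2, n_scales = 6)
  expect_gt(pick2$scores$score[1], pick$scores$score[1])
  # invariance under strictly monotone transforms of one index
  tab3 <- tab
  tab3$gamma <- exp(tab3$gamma)
  expect_equal(combined_rank_score(tab3, n_scales = 6)$scores$score,
               pick$scores$score)
})

test_that("scale grouping separates duplicated profiles exactly and is
           column-order invariant", {
  set.seed(4)
  X <- rnorm(50); Y <- rnorm(50) + 3
  cw <- cbind(X, X, X, Y, Y, Y) + matrix(rnorm(300, sd = 1e-3), 50)
  colnames(cw) <- paste0("a", 1:6)
  sg <- group_scales(cw, seed = 1)
  expect_equal(sg$k, 2)
  expect_setequal(sg$groups[[which(vapply(sg$groups, function(g) "a1" %in% g, TRUE))]],
                  c("a1", "a2", "a3"))
  # permutation of columns regroups identically
  perm <- c(4, 1, 5, 2, 6, 3)
  sg2 <- group_scales(cw[, perm], seed = 1)
  part1 <- lapply(sg$groups, sort)
  part2 <- lapply(sg2$groups, sort)
  expect_setequal(part1, part2)
  # fewer than 3 scales: a single group
  expect_equal(group_scales(cw[, 1:2], seed = 1)$k, 1)
})

test_that("planted profile blocks in a noisy connectivity matrix are
           recovered in most seeds", {
  hits <- 0
  for (s in 1:25) {
    set.seed(s)
    profs <- matrix(rnorm(40 * 3, sd = 3), 40, 3)
    cw <- profs[, rep(1:3, each = 4)] + matrix(rnorm(40 * 12, sd = 0.3), 40)
    colnames(cw) <- paste0("a", 1:12)
    sg <- group_scales(cw, seed = s)
    truth <- rep(1:3, each = 4)
    if (sg$k == 3 && adjusted_rand(sg$labels, truth) == 1) hits <- hits + 1
  }
  expect_gte(hits, 23)  # >= 90%
})

test_that("per-scale hub p-values are monotone in connectivity with weak
           nodes near p = 1 and strong stars significant", {
  # strong star-like cluster: hub weight far above the planar null
  n <- 20
  df <- data.frame(node1 = "hub", node2 = paste0("leaf", 1:(n - 1)),
                   weight = 0.95)
  ring <- data.frame(node1 = paste0("leaf", 1:(n - 1)),
                     node2 = paste0("leaf", c(2:(n - 1), 1)), weight = 0.1)
  g <- graph_from_edges(rbind(df, ring))
  p <- hub_pvalues(g, n_s = 100, seed = 21)
  expect_lt(p["hub"], 0.05)
  # monotone nonincreasing in c^w
  cw <- igraph::strength(g, weights = abs(igraph::E(g)$weight))
  expect_true(all(diff(p[order(cw)]) <= 1e-12))
  # a node with zero connectivity has p near 1
  g2 <- igraph::add_vertices(g, 1)
  igraph::V(g2)$name[n + 1] <- "isolated"
  p2 <- hub_pvalues(g2, n_s = 50, seed = 22)
  expect_gt(p2["isolated"], 0.9)
  expect_identical(hub_pvalues(g, n_s = 50, seed = 5),
                   hub_pvalues(g, n_s = 50, seed = 5))
})

test_that("the combined hub statistic follows the printed formula and is
           additive over scale partitions", {
  expect_equal(multiscale_hub_statistic(c(1, 1, 1)), 0)
  expect_equal(multiscale_hub_statistic(c(0.01, 0.001)), 5)
  p <- c(0.3, 0.05, 0.2, 0.01)
  expect_equal(multiscale_hub_statistic(p),
               multiscale_hub_statistic(p[1:2]) + multiscale_hub_statistic(p[3:4]))
  expect_warning(s0 <- multiscale_hub_statistic(c(0, 0.1)), "clipped")
  expect_true(is.finite(s0))
})

test_that("hub significance calls no hubs on uniform noise and flags an
           extreme node, reproducibly", {
  set.seed(30)
  calls <- vapply(1:20, function(s) {
    pm <- matrix(runif(60 * 5), 60, dimnames = list(paste0("n", 1:60), NULL))
    sum(hub_significance(pm, N_s = 100, seed = s)$is_hub)
  }, 0)
  expect_lte(mean(calls > 1), 0.05)
  expect_lte(median(calls), 1)
  # one node with machine-minimum p across scales is always flagged
  pm <- matrix(runif(60 * 5), 60, dimnames = list(paste0("n", 1:60), NULL))
  pm["n7", ] <- .Machine$double.xmin
  hs <- hub_significance(pm, N_s = 100, seed = 3)
  expect_true(hs$is_hub[hs$node == "n7"])
  hs2 <- hub_significance(pm, N_s = 100, seed = 3)
  expect_identical(hs$p_corrected, hs2$p_corrected)
})

test_that("multiscale hub intersection follows set semantics", {
  expect_setequal(intersect_multiscale_hubs(list(c("a", "b", "c"),
                                                 c("b", "c", "d"), "c")), "c")
  expect_length(intersect_multiscale_hubs(list("a", "b")), 0)
  expect_setequal(intersect_multiscale_hubs(list(c("a", "b"), c("a", "b"))),
                  c("a", "b"))
})
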