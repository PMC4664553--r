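# shared in-code fixtures for the test suite

# ranked pair list of the complete graph on a random symmetric similarity
# matrix (no filtering): input for PMFG construction tests
random_similarity_pairs <- function(n, seed, names = sprintf("v%03d", seq_len(n))) {
  set.seed(seed)
  s <- matrix(runif(n * n), n)
  s <- (s + t(s)) / 2
  dimnames(s) <- list(names, names)
  filter_and_rank(s, fdr_threshold = 1)
}

# O(n^3) Floyd-Warshall all-pairs shortest paths, independent of igraph
floyd_warshall <- function(len_matrix) {
  d <- len_matrix
  n <- nrow(d)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

# weighted igraph from an edge data frame (node1, node2, weight)
graph_from_edges <- function(df, vertices = NULL) {
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
}

# adjusted Rand index between two labelings (independent contingency-table
# implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- ai * bj / np
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# best-match Jaccard of each gold module against a partition
module_jaccards <- function(partition, gold_labels) {
  mods <- setdiff(unique(gold_labels), "bg")
  vapply(mods, function(m) {
    gm <- names(gold_labels)[gold_labels == m]
    cands <- unique(partition[!is.na(partition)])
    if (length(cands) == 0L) return(0)
    max(vapply(cands, function(cid) {
      cm <- names(partition)[!is.na(partition) & partition == cid]
      length(intersect(gm, cm)) / length(union(gm, cm))
    }, 0))
  }, 0)
}

# standard pearson-route ranked pairs from an expression matrix
expression_pairs <- function(expr, fdr_threshold = 0.05) {
  sim <- compute_similarity(expr, "pearson")
  pv <- matrix(NA_real_, nrow(sim), ncol(sim), dimnames = dimnames(sim))
  ut <- upper.tri(sim)
  pv[ut] <- fisher_z_pvalue(pmin(pmax(sim[ut], -1 + 1e-15), 1 - 1e-15),
                            ncol(expr))
  pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  filter_and_rank(sim, pvals = pv, fdr_threshold = fdr_threshold)
}
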