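# Brute-force planarity oracle via Kuratowski's theorem: a graph is planar
# iff it contains no subdivision of K5 or K3,3.  Exhaustive backtracking
# search over branch-vertex sets and internally-disjoint connecting paths;
# exponential, intended for graphs of about a dozen nodes.  Completely
# independent of the package's left-right planarity test.

adj_from_edges <- function(el, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1L]; v <- el[k, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# find internally-disjoint paths linking each pair in `pairs` (2-col matrix
# of branch vertices), avoiding branch vertices internally; `used` marks
# interior vertices already consumed by earlier paths
link_paths <- function(adj, branch, pairs, used) {
  if (nrow(pairs) == 0L) return(TRUE)
  u <- pairs[1L, 1L]; v <- pairs[1L, 2L]
  rest <- pairs[-1L, , drop = FALSE]
  other_branch <- setdiff(branch, c(u, v))
  # DFS over simple paths from u to v
  path_dfs <- function(cur, interior) {
    for (w in adj[[cur]]) {
      if (w == v) {
        used2 <- used
        used2[interior] <- TRUE
        if (link_paths(adj, branch, rest, used2)) return(TRUE)
      } else if (!w %in% other_branch && w != u && !used[w] &&
                 !w %in% interior) {
        if (path_dfs(w, c(interior, w))) return(TRUE)
      }
    }
    FALSE
  }
  path_dfs(u, integer(0))
}

has_subdivision <- function(adj, n, kind = c("k5", "k33")) {
  kind <- match.arg(kind)
  deg <- lengths(adj)
  if (kind == "k5") {
    cand <- which(deg >= 4L)
    if (length(cand) < 5L) return(FALSE)
    for (B in utils::combn(cand, 5L, simplify = FALSE)) {
      pairs <- t(utils::combn(B, 2L))
      if (link_paths(adj, B, pairs, logical(n))) return(TRUE)
    }
    FALSE
  } else {
    cand <- which(deg >= 3L)
    if (length(cand) < 6L) return(FALSE)
    for (S in utils::combn(cand, 6L, simplify = FALSE)) {
      firsts <- utils::combn(S[-1L], 2L, simplify = FALSE)
      for (ab in firsts) {  # triples containing S[1]: fixes the side split
        left <- c(S[1L], ab)
        right <- setdiff(S, left)
        pairs <- as.matrix(expand.grid(left, right))
        if (link_paths(adj, S, pairs, logical(n))) return(TRUE)
      }
    }
    FALSE
  }
}

# Kuratowski-based planarity verdict (edge-bound shortcut only ever
# declares nonplanarity, which is sound)
planar_bruteforce <- function(el, n) {
  if (n <= 2L || nrow(el) == 0L) return(TRUE)
  if (nrow(el) > 3L * n - 6L) return(FALSE)
  adj <- adj_from_edges(el, n)
  !has_subdivision(adj, n, "k5") && !has_subdivision(adj, n, "k33")
}
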