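#' Pairwise co-expression similarity
#'
#' Computes a symmetric gene-by-gene similarity matrix from an expression
#' matrix (genes in rows, samples in columns).  Three measures are supported:
#' Pearson correlation, a plug-in mutual information estimate on
#' equal-frequency bins, and Euclidean distance mapped to a bounded
#' similarity via `1 / (1 + d)`.
#'
#' Mutual information uses equal-frequency discretization of each gene into
#' `ceiling(sqrt(M))` bins (`M` = number of samples) followed by the plug-in
#' entropy estimator; only the ranking of pairs matters downstream, so no
#' bias correction is applied.
#'
#' @param expr numeric matrix, genes x samples, with row and column names.
#' @param method one of `"pearson"`, `"mi"`, `"euclidean"`.
#' @return symmetric numeric matrix with `NA` diagonal.  Genes with zero
#'   variance are flagged via the `"flagged"` attribute and, under Pearson,
#'   their rows/columns are set to `NA`.
#' @export
compute_similarity <- function(expr, method = c("pearson", "mi", "euclidean")) {
  method <- match.arg(method)
  check_expression(expr)
  n <- nrow(expr)
  flagged <- rownames(expr)[apply(expr, 1L, sd) == 0]
  s <- switch(method,
    pearson = {
      if (length(flagged))
        warning("zero-variance genes excluded from correlation: ",
                paste(flagged, collapse = ", "))
      suppressWarnings(cor(t(expr)))
    },
    mi = mi_matrix(expr),
    euclidean = {
      d <- as.matrix(dist(expr))
      1 / (1 + d)
    }
  )
  diag(s) <- NA_real_
  dimnames(s) <- list(rownames(expr), rownames(expr))
  attr(s, "method") <- method
  attr(s, "flagged") <- flagged
  s
}

# plug-in mutual information on equal-frequency bins
mi_matrix <- function(expr) {
  m <- ncol(expr)
  nb <- ceiling(sqrt(m))
  disc <- t(apply(expr, 1L, function(x) {
    as.integer(ceiling(rank(x, ties.method = "first") / m * nb))
  }))
  n <- nrow(expr)
  out <- matrix(0, n, n)
  marg <- lapply(seq_len(n), function(i) tabulate(disc[i, ], nb) / m)
  hm <- vapply(marg, function(p) -sum(p[p > 0] * log(p[p > 0])), 0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      joint <- tabulate((disc[i, ] - 1L) * nb + disc[j, ], nb * nb) / m
      joint <- joint[joint > 0]
      hij <- -sum(joint * log(joint))
      out[i, j] <- out[j, i] <- hm[i] + hm[j] - hij
    }
  }
  out
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix (genes x samples)")
  if (anyNA(expr)) stop("`expr` contains missing values")
  if (ncol(expr) < 3L) stop("at least 3 samples are required")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("`expr` must carry unique gene identifiers as rownames")
  invisible(TRUE)
}

#' Two-sided p-value for a correlation via Fisher's Z-transformation
#'
#' Tests `H0: rho = 0` using `z = atanh(r) * sqrt(n - 3)` against the
#' standard normal distribution.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @param n_samples number of samples used to estimate `r` (>= 4).
#' @return two-sided p-value(s) in (0, 1].  `|r| = 1` returns the smallest
#'   positive double with a warning (the analytic limit is 0).
#' @export
fisher_z_pvalue <- function(r, n_samples) {
  stopifnot(n_samples >= 4L)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  p <- 2 * pnorm(-abs(atanh(r)) * sqrt(n_samples - 3))
  sat <- !is.na(r) & abs(r) == 1
  if (any(sat)) {
    warning("|r| = 1: p-value clipped to the smallest positive double")
    p[sat] <- .Machine$double.xmin
  }
  p
}

#' Permutation-based global FDR for similarity values
#'
#' Estimates, for every gene pair, the false discovery rate of calling its
#' similarity significant, by permuting each gene's samples independently
#' (which preserves marginal expression distributions while destroying
#' co-expression).  For a pair with observed similarity `s`,
#' `FDR(s) = mean permuted count of similarities >= s / observed count >= s`,
#' clipped to \[0, 1\].  For signed measures (Pearson) magnitudes are
#' compared.
#'
#' @param expr expression matrix, genes x samples.
#' @param method similarity measure, see [compute_similarity()].
#' @param n_perm number of permutations (>= 1); small values limit the
#'   resolution of the estimate (a warning is emitted below 10).
#' @param seed integer seed; the same seed reproduces the same FDR matrix.
#' @return symmetric matrix of FDR estimates with `NA` diagonal.
#' @export
permutation_fdr <- function(expr, method = c("pearson", "mi", "euclidean"),
                            n_perm = 10L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1L)
  if (n_perm < 10L)
    warning("n_perm < 10 gives a coarse FDR resolution")
  obs <- compute_similarity(expr, method)
  ut <- upper.tri(obs)
  score <- if (method == "pearson") abs(obs) else obs
  sobs <- score[ut]
  m <- ncol(expr)
  null_sorted <- with_seed(seed, {
    null <- numeric(0)
    for (b in seq_len(n_perm)) {
      perm <- expr
      for (i in seq_len(nrow(expr))) perm[i, ] <- perm[i, sample.int(m)]
      sp <- compute_similarity(perm, method)
      spv <- if (method == "pearson") abs(sp[ut]) else sp[ut]
      null <- c(null, spv)
    }
    sort(null)
  })
  os <- sort(sobs)
  n_null_ge <- length(null_sorted) -
    findInterval(sobs, null_sorted, left.open = TRUE)
  n_obs_ge <- length(os) - findInterval(sobs, os, left.open = TRUE)
  fdr_v <- pmin(1, pmax(0, (n_null_ge / n_perm) / pmax(n_obs_ge, 1L)))
  fdr <- obs
  fdr[ut] <- fdr_v
  fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
  diag(fdr) <- NA_real_
  attr(fdr, "method") <- method
  attr(fdr, "flagged") <- attr(obs, "flagged")
  fdr
}

#' Filter gene pairs by FDR and rank them for planar embedding
#'
#' Retains pairs passing the FDR threshold and returns them in the strict
#' order the embedding consumes: descending similarity (by magnitude by
#' default, sign kept as an attribute of the pair), ties broken
#' lexicographically by `(min_id, max_id)` so that reruns are bit-identical.
#'
#' If `fdr` is omitted and `pvals` is supplied, Benjamini-Hochberg adjusted
#' p-values are used as the FDR (the correlation route); otherwise supply a
#' permutation FDR matrix from [permutation_fdr()].
#'
#' @param sim_matrix symmetric similarity matrix ([compute_similarity()]).
#' @param pvals optional symmetric matrix of nominal p-values.
#' @param fdr optional symmetric matrix of FDR estimates.
#' @param fdr_threshold retain pairs with `fdr < fdr_threshold` (default 0.05).
#' @param rank_by `"absolute"` (default) ranks by `|similarity|`;
#'   `"signed"` ranks by the signed value.
#' @return a `ranked_pairs` data frame with columns `node1`, `node2`,
#'   `similarity`, `p_value`, `fdr`; attribute `"nodes"` holds the node
#'   universe (sorted).
#' @export
filter_and_rank <- function(sim_matrix, pvals = NULL, fdr = NULL,
                            fdr_threshold = 0.05,
                            rank_by = c("absolute", "signed")) {
  rank_by <- match.arg(rank_by)
  ids <- rownames(sim_matrix)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(sim_matrix)))
  ut <- which(upper.tri(sim_matrix), arr.ind = TRUE)
  s <- sim_matrix[ut]
  p <- if (!is.null(pvals)) pvals[ut] else rep(NA_real_, length(s))
  q <- if (!is.null(fdr)) fdr[ut]
       else if (!is.null(pvals)) p.adjust(p, method = "BH")
       else rep(0, length(s))
  keep <- !is.na(s) & !is.na(q) & q < fdr_threshold
  if (!any(keep))
    stop("no pairs pass fdr < ", fdr_threshold,
         "; consider relaxing the threshold")
  i <- ut[keep, 1L]; j <- ut[keep, 2L]
  n1 <- pmin(ids[i], ids[j]); n2 <- pmax(ids[i], ids[j])
  s <- s[keep]; p <- p[keep]; q <- q[keep]
  key <- if (rank_by == "absolute") -abs(s) else -s
  o <- order(key, n1, n2, method = "radix")
  out <- data.frame(node1 = n1[o], node2 = n2[o], similarity = s[o],
                    p_value = p[o], fdr = q[o], stringsAsFactors = FALSE)
  structure(out,
            nodes = sort(unique(c(out$node1, out$node2))),
            rank_by = rank_by,
            class = c("ranked_pairs", "data.frame"))
}

#' Assemble a ranked pair list from a precomputed edge list
#'
#' Convenience constructor for workflows that start from externally computed
#' similarities (`node1`, `node2`, `similarity` columns); applies the same
#' ordering contract as [filter_and_rank()].
#'
#' @param df data frame with columns `node1`, `node2`, `similarity` and
#'   optionally `p_value`, `fdr`.
#' @param rank_by see [filter_and_rank()].
#' @return a `ranked_pairs` data frame.
#' @export
as_ranked_pairs <- function(df, rank_by = c("absolute", "signed")) {
  rank_by <- match.arg(rank_by)
  stopifnot(all(c("node1", "node2", "similarity") %in% names(df)))
  n1 <- pmin(as.character(df$node1), as.character(df$node2))
  n2 <- pmax(as.character(df$node1), as.character(df$node2))
  if (any(n1 == n2)) stop("self-pairs are not allowed")
  if (anyDuplicated(paste(n1, n2))) stop("duplicate pairs in input")
  s <- as.numeric(df$similarity)
  key <- if (rank_by == "absolute") -abs(s) else -s
  o <- order(key, n1, n2, method = "radix")
  out <- data.frame(node1 = n1[o], node2 = n2[o], similarity = s[o],
                    p_value = if ("p_value" %in% names(df)) df$p_value[o] else NA_real_,
                    fdr = if ("fdr" %in% names(df)) df$fdr[o] else NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, nodes = sort(unique(c(n1, n2))), rank_by = rank_by,
            class = c("ranked_pairs", "data.frame"))
}
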