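#' Module eigengene: first principal component of a cluster
#'
#' PCA of the standardized cluster submatrix (genes x samples); the
#' eigengene is the first right singular vector (per-sample scores), with
#' its sign fixed so that it correlates positively with the mean expression
#' of the cluster.
#'
#' @param expr expression matrix, genes x samples.
#' @param cluster_nodes gene identifiers (>= 2 present in `expr`).
#' @return numeric vector named by sample; attribute `var_explained` gives
#'   the fraction of variance captured.
#' @export
module_eigengene <- function(expr, cluster_nodes) {
  genes <- intersect(cluster_nodes, rownames(expr))
  if (length(genes) < 2L) stop("cluster must have at least 2 genes in `expr`")
  x <- expr[genes, , drop = FALSE]
  xs <- t(scale(t(x)))  # standardize each gene
  xs[is.na(xs)] <- 0    # zero-variance genes contribute nothing
  sv <- svd(xs, nu = 0L, nv = 1L)
  eg <- sv$v[, 1L]
  avg <- colMeans(x)
  if (sd(avg) > 0 && cor(eg, avg) < 0) eg <- -eg
  names(eg) <- colnames(expr)
  attr(eg, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  eg
}

#' Correlation between an eigengene and a sample trait
#'
#' Pearson correlation with a Fisher-Z p-value; two-level factors are coded
#' 0/1 (point-biserial).  Missing trait values are dropped pairwise.
#'
#' @param eigengene numeric vector named by sample.
#' @param trait numeric vector or 2-level factor, aligned by name when
#'   named.
#' @return list: `r`, `p_value`, `n` (paired samples).  Constant traits
#'   give `NA` with a message.
#' @export
trait_association <- function(eigengene, trait) {
  if (is.factor(trait) || is.character(trait)) {
    lev <- unique(stats::na.omit(trait))
    if (length(lev) != 2L) stop("categorical traits must have exactly 2 levels")
    trait <- as.numeric(factor(trait, levels = lev)) - 1
  }
  if (!is.null(names(trait)) && !is.null(names(eigengene))) {
    common <- intersect(names(eigengene), names(trait))
    eigengene <- eigengene[common]
    trait <- trait[common]
  }
  ok <- !is.na(eigengene) & !is.na(trait)
  eigengene <- eigengene[ok]; trait <- trait[ok]
  n <- length(trait)
  if (n < 3L) stop("need at least 3 paired samples")
  if (sd(trait) == 0 || sd(eigengene) == 0) {
    message("constant trait or eigengene: association undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(eigengene, trait)
  p <- if (n >= 4L) fisher_z_pvalue(r, n) else NA_real_
  list(r = r, p_value = p, n = n)
}

#' Median-split logrank test of an eigengene against survival
#'
#' Samples are split into low/high groups at the median eigengene value
#' (ties at the median go to the low group) and the standard two-group
#' logrank statistic compares their survival curves; p from chi-square with
#' 1 degree of freedom.
#'
#' @param eigengene numeric vector named by sample.
#' @param survival data frame with columns `sample`, `time`, `event`.
#' @return list: `statistic`, `p_value`, `groups` (the factor used).
#' @export
median_split_logrank <- function(eigengene, survival) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival)))
  if (any(survival$time < 0)) stop("negative survival times")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")
  common <- intersect(names(eigengene), survival$sample)
  if (length(common) < 4L) stop("need at least 4 samples with survival data")
  sv <- survival[match(common, survival$sample), ]
  eg <- eigengene[common]
  grp <- factor(ifelse(eg <= median(eg), "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("one median-split group is empty")
  if (sum(sv$event) == 0L) {
    warning("no events observed; logrank p = 1")
    return(list(statistic = 0, p_value = 1, groups = grp))
  }
  fit <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ grp)
  list(statistic = unname(fit$chisq),
       p_value = pchisq(fit$chisq, df = 1L, lower.tail = FALSE),
       groups = grp)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a p-value vector (`stats::p.adjust` with
#' `method = "BH"`); kept as a named step so association tables document
#' their correction.
#'
#' @param pvals numeric p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted values, never below the input.
#' @export
bh_fdr <- function(pvals) p.adjust(pvals, method = "BH")

#' Gene-set enrichment of a cluster by Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 overlap table of a
#' cluster and a gene set within a gene universe, plus a Bonferroni helper
#' for a family of tests.
#'
#' @param cluster_nodes,gene_set,universe character vectors; cluster and
#'   set must be subsets of the universe.
#' @param n_tests Bonferroni family size (default 1).
#' @return list: `odds_ratio` (conditional MLE), `p_value`,
#'   `p_bonferroni`, `table` (the 2x2 matrix).
#' @export
cluster_signature_enrichment <- function(cluster_nodes, gene_set, universe,
                                         n_tests = 1L) {
  if (length(gene_set) == 0L) stop("empty gene set")
  cluster_nodes <- unique(cluster_nodes); gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(cluster_nodes %in% universe) || !all(gene_set %in% universe))
    stop("cluster and gene set must be subsets of the universe")
  a <- length(intersect(cluster_nodes, gene_set))
  b <- length(setdiff(cluster_nodes, gene_set))
  cc <- length(setdiff(gene_set, cluster_nodes))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2L,
                dimnames = list(c("in_set", "out_set"),
                                c("in_cluster", "out_cluster")))
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       p_bonferroni = min(1, ft$p.value * n_tests), table = tab)
}

#' Cluster-trait association analysis
#'
#' Summarizes every hierarchy cluster (with >= `min_genes` genes) by its
#' eigengene and associates it with each trait column (correlation +
#' Fisher-Z p) and, when survival data are given, with survival via the
#' median-split logrank test.  P-values are BH-adjusted across clusters
#' within each trait.
#'
#' @param expr expression matrix.
#' @param hierarchy a `cluster_hierarchy`.
#' @param traits optional data frame of traits (rownames = samples).
#' @param survival optional data frame (`sample`, `time`, `event`).
#' @param min_genes smallest cluster summarized (default 3).
#' @return data frame in long format: `cluster_id`, `trait`, `statistic`
#'   (`r` or logrank chi-square), `p_value`, `fdr`, `n`.
#' @export
run_cta <- function(expr, hierarchy, traits = NULL, survival = NULL,
                    min_genes = 3L) {
  tab <- hierarchy_table(hierarchy)
  keep <- tab$size >= min_genes
  ids <- tab$cluster_id[keep]
  if (length(ids) == 0L) stop("no clusters with >= ", min_genes, " genes")
  egs <- lapply(ids, function(id)
    module_eigengene(expr, hierarchy$clusters[[id]]$nodes))
  names(egs) <- ids
  rows <- list()
  if (!is.null(traits)) {
    for (tn in colnames(traits)) {
      tv <- traits[[tn]]
      names(tv) <- rownames(traits)
      res <- lapply(ids, function(id) {
        out <- tryCatch(trait_association(egs[[id]], tv),
                        error = function(e) list(r = NA_real_,
                                                 p_value = NA_real_, n = NA))
        data.frame(cluster_id = id, trait = tn, statistic = out$r,
                   p_value = out$p_value, n = out$n)
      })
      res <- do.call(rbind, res)
      res$fdr <- bh_fdr(res$p_value)
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!is.null(survival)) {
    res <- lapply(ids, function(id) {
      out <- tryCatch(median_split_logrank(egs[[id]], survival),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_))
      data.frame(cluster_id = id, trait = "survival_logrank",
                 statistic = out$statistic, p_value = out$p_value,
                 n = nrow(survival))
    })
    res <- do.call(rbind, res)
    res$fdr <- bh_fdr(res$p_value)
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    return(data.frame(cluster_id = character(), trait = character(),
                      statistic = numeric(), p_value = numeric(),
                      n = integer(), fdr = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
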