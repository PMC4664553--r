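#' Planted co-expression design
#'
#' Specification of a synthetic expression data set with known module
#' structure, generated by a latent-factor model: every gene of a module
#' loads on the module's factor (`x = loading * f + noise_sd * eps`), so
#' the expected within-module correlation has the closed form
#' `loading^2 / (loading^2 + noise_sd^2)`.  With the default
#' `noise_sd = sqrt(1 - loading^2)` genes have unit variance and the
#' within-module correlation is `loading^2`.  Optional two-level designs
#' nest sub-module factors inside super-module factors
#' (`x = super_loading * f_super + sub_loading * f_sub + noise_sd * eps`).
#' Hub genes get their loadings inflated by `hub_multiplier` (squared
#' loadings capped at 0.98), making them the most connected genes of their
#' module.
#'
#' @param n_samples number of samples.
#' @param module_sizes integer vector of module sizes (one-level design).
#' @param loading factor loading of module genes, in (0, 1).
#' @param n_background genes with no module membership (pure noise).
#' @param n_super,subs_per_super,sub_size two-level design: number of
#'   super-modules, nested sub-modules per super-module, genes per
#'   sub-module.  When `n_super > 0` the one-level arguments are ignored.
#' @param super_loading,sub_loading loadings on the shared and nested
#'   factors of a two-level design.
#' @param hubs_per_module number of hub genes per (sub-)module.
#' @param hub_multiplier loading inflation factor for hubs.
#' @param noise_sd residual standard deviation; `NULL` (default) completes
#'   gene variance to 1.
#' @param hazard_ratio survival hazard ratio per unit of the first module's
#'   factor (used by [generate_survival()] via the stored truth).
#' @param censoring_rate expected fraction of censored samples.
#' @param seed master seed for [generate_expression()].
#' @return a `planted_design` list.
#' @export
planted_design <- function(n_samples = 200L,
                           module_sizes = rep(25L, 4L),
                           loading = 0.8,
                           n_background = 0L,
                           n_super = 0L, subs_per_super = 3L, sub_size = 20L,
                           super_loading = 0.7, sub_loading = 0.6,
                           hubs_per_module = 0L, hub_multiplier = 1.2,
                           noise_sd = NULL,
                           hazard_ratio = 1, censoring_rate = 0.3,
                           seed = NULL) {
  stopifnot(n_samples >= 3L, loading > 0, loading < 1,
            super_loading > 0, sub_loading > 0,
            super_loading^2 + sub_loading^2 < 1)
  design <- list(n_samples = as.integer(n_samples),
                 module_sizes = as.integer(module_sizes),
                 loading = loading, n_background = as.integer(n_background),
                 n_super = as.integer(n_super),
                 subs_per_super = as.integer(subs_per_super),
                 sub_size = as.integer(sub_size),
                 super_loading = super_loading, sub_loading = sub_loading,
                 hubs_per_module = as.integer(hubs_per_module),
                 hub_multiplier = hub_multiplier, noise_sd = noise_sd,
                 hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate, seed = seed)
  class(design) <- "planted_design"
  design
}

#' Generate expression data with planted modules
#'
#' Simulates the latent-factor model described in [planted_design()] and
#' returns the expression matrix together with the gold-standard labels
#' needed to evaluate network construction and clustering: module labels
#' (`"bg"` for background genes), two-level super/sub labels where
#' applicable, the planted hub genes, the latent factors, and the gold
#' co-expression edge set (all within-module gene pairs; for two-level
#' designs, within-sub-module pairs).
#'
#' @param design a `planted_design`.
#' @return list: `expr` (genes x samples matrix), `modules`, `super_modules`
#'   (or `NULL`), `hubs`, `factors` (samples x factors), `gold_edges`
#'   (2-column matrix of gene pairs).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  with_seed(design$seed, {
    m <- design$n_samples
    two_level <- design$n_super > 0L
    if (two_level) {
      n_sub_total <- design$n_super * design$subs_per_super
      sizes <- rep(design$sub_size, n_sub_total)
      super_of_sub <- rep(seq_len(design$n_super), each = design$subs_per_super)
    } else {
      sizes <- design$module_sizes
      super_of_sub <- NULL
    }
    n_module_genes <- sum(sizes)
    n_genes <- n_module_genes + design$n_background
    gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    sample_ids <- sprintf("s%0*d", nchar(m), seq_len(m))
    sub_label <- c(rep(seq_along(sizes), sizes), rep(0L, design$n_background))
    expr <- matrix(0, n_genes, m, dimnames = list(gene_ids, sample_ids))
    f_sub <- matrix(rnorm(length(sizes) * m), nrow = m,
                    ncol = length(sizes))
    f_super <- if (two_level)
      matrix(rnorm(design$n_super * m), nrow = m,
             ncol = design$n_super) else NULL
    hubs <- character(0)
    for (g in seq_len(n_genes)) {
      mod <- sub_label[g]
      if (mod == 0L) {
        sd0 <- if (is.null(design$noise_sd)) 1 else design$noise_sd
        expr[g, ] <- rnorm(m, sd = sd0)
        next
      }
      pos_in_mod <- g - c(0L, cumsum(sizes))[mod]
      is_hub <- pos_in_mod <= design$hubs_per_module
      if (is_hub) hubs <- c(hubs, gene_ids[g])
      mult <- if (is_hub) design$hub_multiplier else 1
      if (two_level) {
        ls_ <- design$super_loading * mult
        lb <- design$sub_loading * mult
        tot <- ls_^2 + lb^2
        if (tot > 0.98) { sc <- sqrt(0.98 / tot); ls_ <- ls_ * sc; lb <- lb * sc }
        sd0 <- if (is.null(design$noise_sd)) sqrt(1 - ls_^2 - lb^2)
               else design$noise_sd
        expr[g, ] <- ls_ * f_super[, super_of_sub[mod]] +
          lb * f_sub[, mod] + rnorm(m, sd = sd0)
      } else {
        lam <- min(design$loading * mult, sqrt(0.98))
        sd0 <- if (is.null(design$noise_sd)) sqrt(1 - lam^2) else design$noise_sd
        expr[g, ] <- lam * f_sub[, mod] + rnorm(m, sd = sd0)
      }
    }
    modules <- setNames(ifelse(sub_label == 0L, "bg",
                               paste0("m", sub_label)), gene_ids)
    super_modules <- if (two_level)
      setNames(ifelse(sub_label == 0L, "bg",
                      paste0("M", super_of_sub[pmax(sub_label, 1L)])),
               gene_ids) else NULL
    gold <- do.call(rbind, lapply(unique(sub_label[sub_label > 0L]),
                                  function(mod) {
      gs <- gene_ids[sub_label == mod]
      t(combn(gs, 2L))
    }))
    factors <- cbind(f_sub, f_super)
    colnames(factors) <- c(sprintf("f_sub%d", seq_len(ncol(f_sub))),
                           if (two_level)
                             sprintf("f_super%d", seq_len(design$n_super)))
    rownames(factors) <- sample_ids
    list(expr = expr, modules = modules, super_modules = super_modules,
         hubs = hubs, factors = factors, gold_edges = gold)
  })
}

#' Simulate survival outcomes driven by a latent factor
#'
#' Exponential survival with log-hazard linear in the (standardized) score:
#' `h_i = h0 * hazard_ratio^z_i`.  Censoring is independent exponential
#' with its rate chosen so the expected censored fraction is
#' `censoring_rate` under the baseline hazard; `censoring_rate = 0` yields
#' no censoring.
#'
#' @param score numeric vector named by sample (e.g. a latent factor or
#'   eigengene truth).
#' @param hazard_ratio hazard ratio per unit of the standardized score.
#' @param censoring_rate expected censored fraction in \[0, 1).
#' @param seed integer seed.
#' @param baseline_hazard baseline event rate (default 1).
#' @return data frame: `sample`, `time`, `event`.
#' @export
generate_survival <- function(score, hazard_ratio = 1, censoring_rate = 0.3,
                              seed = NULL, baseline_hazard = 1) {
  stopifnot(censoring_rate >= 0, censoring_rate < 1)
  z <- as.numeric(scale(score))
  n <- length(score)
  with_seed(seed, {
    h <- baseline_hazard * hazard_ratio^z
    t_event <- rexp(n, rate = h)
    if (censoring_rate > 0) {
      c_rate <- baseline_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(sample = if (is.null(names(score)))
                 paste0("s", seq_len(n)) else names(score),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' AUC-ROC of a network against a gold-standard edge set
#'
#' Scores every node pair by the negative weighted shortest-path distance
#' in the inferred network (closer = more likely to interact), labels pairs
#' positive iff they are gold edges, and computes the area under the ROC
#' curve by the Mann-Whitney rank statistic with midranks for ties.
#' Unreachable pairs receive the worst score.
#'
#' @param network weighted `igraph`.
#' @param gold_edges 2-column matrix/data frame of node name pairs (must be
#'   a subset of the network's node universe).
#' @param transform similarity-to-length transform for the path distances.
#' @return the AUC (0.5 = uninformative).
#' @export
evaluate_against_gold <- function(network, gold_edges,
                                  transform = "one_minus_abs") {
  nodes <- igraph::V(network)$name
  gm <- as.matrix(gold_edges)[, 1:2, drop = FALSE]
  if (!all(gm %in% nodes)) stop("gold edges mention nodes absent from the network")
  spd <- shortest_path_matrix(network, transform)
  ut <- which(upper.tri(spd), arr.ind = TRUE)
  score <- -spd[ut]
  score[!is.finite(score)] <- -.Machine$double.xmax
  key <- paste(pmin(nodes[ut[, 1L]], nodes[ut[, 2L]]),
               pmax(nodes[ut[, 1L]], nodes[ut[, 2L]]))
  gold_key <- paste(pmin(gm[, 1L], gm[, 2L]), pmax(gm[, 1L], gm[, 2L]))
  pos <- key %in% gold_key
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need both gold and non-gold pairs")
  r <- rank(score)  # midranks
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Write a synthetic fixture data set to disk
#'
#' Generates expression, survival and gold-standard tables from a design
#' and writes them as tab-delimited text (`expression.tsv`, `traits.tsv`,
#' `survival.tsv`, `gold_modules.tsv`, `gold_edges.tsv`).
#'
#' @param design a `planted_design`.
#' @param dir output directory (created if needed).
#' @return invisibly, the generated object list.
#' @export
write_fixtures <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_expression(design)
  seeds <- derive_seeds(design$seed, 2L)
  surv <- generate_survival(setNames(gen$factors[, 1L],
                                     rownames(gen$factors)),
                            hazard_ratio = design$hazard_ratio,
                            censoring_rate = design$censoring_rate,
                            seed = seeds[[1L]])
  traits <- data.frame(factor1 = gen$factors[, 1L],
                       noise = with_seed(seeds[[2L]],
                                         rnorm(design$n_samples)),
                       row.names = rownames(gen$factors))
  write_expression(gen$expr, file.path(dir, "expression.tsv"))
  write.table(data.frame(sample = rownames(traits), traits),
              file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(surv, file.path(dir, "survival.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(gen$modules), module = gen$modules,
                         is_hub = names(gen$modules) %in% gen$hubs),
              file.path(dir, "gold_modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(node1 = gen$gold_edges[, 1L],
                         node2 = gen$gold_edges[, 2L]),
              file.path(dir, "gold_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(gen, list(survival = surv, traits = traits)))
}
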