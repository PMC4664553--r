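#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its reference
#' default: FDR threshold 0.05 for pair filtering, screening trigger at a
#' 10% acceptance rate with batches of 1000 candidates, saturation at 95%
#' of the Euler bound, a rejection budget of 20 pairs per node, LPI
#' `epsilon = 0.01`, modularity search window `dk = 10`, and 100
#' Monte-Carlo replicates for every null (`n_rand`, `n_s`, `N_s`).
#'
#' @param method similarity measure (`"pearson"`, `"mi"`, `"euclidean"`).
#' @param fdr_threshold pair filter threshold.
#' @param rank_by rank pairs by `"absolute"` or `"signed"` similarity.
#' @param saturation,reject_budget_mult,use_pcp,batch_size,pcp_trigger,window
#'   see [build_pfn()].
#' @param alpha_grid,dk,n_rand,sig_threshold,min_size see [run_mca()].
#' @param n_s,N_s see [run_mha()].
#' @param transform,epsilon length transform and LPI weight.
#' @param n_perm permutations for [permutation_fdr()] (non-correlation
#'   similarity measures).
#' @param seed master seed for the whole run.
#' @return a `pfn_config` list.
#' @export
pfn_config <- function(method = "pearson", fdr_threshold = 0.05,
                       rank_by = "absolute", saturation = 0.95,
                       reject_budget_mult = 20, use_pcp = TRUE,
                       batch_size = 1000L, pcp_trigger = 0.10,
                       window = 1000L, alpha_grid = mca_alpha_grid(),
                       dk = 10L, n_rand = 100L, sig_threshold = 0.05,
                       min_size = 4L, n_s = 100L, N_s = 100L,
                       transform = "one_minus_abs", epsilon = 0.01,
                       n_perm = 10L, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$saturation <= 0 || cfg$saturation > 1)
    stop("`saturation` must lie in (0, 1]")
  class(cfg) <- "pfn_config"
  cfg
}

#' Run the full co-expression network pipeline
#'
#' Executes similarity computation, pair filtering/ranking, planar network
#' construction, multiscale clustering, hub analysis and (when traits or
#' survival are supplied) cluster-trait association, writing every result
#' table plus a JSON run manifest to `out_dir`.  A failure in a late stage
#' preserves the outputs of earlier stages; the manifest records where the
#' run stopped.  Re-running with the same inputs and config reproduces the
#' tables byte for byte.
#'
#' @param expr expression matrix or path to a tab-delimited expression file.
#' @param out_dir output directory.
#' @param traits optional trait data frame (or file path).
#' @param survival optional survival data frame (or file path).
#' @param config a [pfn_config()].
#' @param skip_cta skip the association stage even if traits are given.
#' @return invisibly, a list with the in-memory results (`pairs`, `pfn`,
#'   `hierarchy`, `mha`, `cta`) and `out_dir`.
#' @export
run_pipeline <- function(expr, out_dir, traits = NULL, survival = NULL,
                         config = pfn_config(), skip_cta = FALSE) {
  stopifnot(inherits(config, "pfn_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (is.character(survival)) survival <- read_survival(survival)
  manifest <- list(package_version = as.character(utils::packageVersion("pfnet")),
                   config = config[setdiff(names(config), "alpha_grid")],
                   alpha_grid_range = range(config$alpha_grid),
                   alpha_grid_n = length(config$alpha_grid),
                   n_genes = nrow(expr), n_samples = ncol(expr),
                   stages = list(), failed_stage = NULL)
  seeds <- derive_seeds(config$seed, 4L)
  finish <- function(res) {
    m <- manifest
    if (is.null(m$failed_stage)) m$failed_stage <- NULL  # drop, not {}
    m <- Filter(Negate(is.null), m)
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(res)
  }
  res <- list(out_dir = out_dir)
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$failed_stage <<- list(stage = name,
                                     message = conditionMessage(e))
      NULL
    })
  }

  pairs <- run_stage("similarity", {
    sim <- compute_similarity(expr, config$method)
    if (config$method == "pearson") {
      pv <- matrix(NA_real_, nrow(sim), ncol(sim), dimnames = dimnames(sim))
      ut <- upper.tri(sim)
      pv[ut] <- fisher_z_pvalue(pmin(pmax(sim[ut], -1 + 1e-15), 1 - 1e-15),
                                ncol(expr))
      pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
      filter_and_rank(sim, pvals = pv, fdr_threshold = config$fdr_threshold,
                      rank_by = config$rank_by)
    } else {
      q <- permutation_fdr(expr, config$method, n_perm = config$n_perm,
                           seed = seeds[[1L]])
      filter_and_rank(sim, fdr = q, fdr_threshold = config$fdr_threshold,
                      rank_by = config$rank_by)
    }
  })
  if (is.null(pairs)) return(finish(res))
  manifest$stages$similarity <- list(n_pairs = nrow(pairs),
                                     n_nodes = length(attr(pairs, "nodes")))
  write.table(pairs, file.path(out_dir, "ranked_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res$pairs <- pairs

  pfn <- run_stage("pfn", {
    build_pfn(pairs, saturation = config$saturation,
              reject_budget_mult = config$reject_budget_mult,
              use_pcp = config$use_pcp, batch_size = config$batch_size,
              pcp_trigger = config$pcp_trigger, window = config$window)
  })
  if (is.null(pfn)) return(finish(res))
  manifest$stages$pfn <- list(n_nodes = igraph::vcount(pfn),
                              n_edges = igraph::ecount(pfn),
                              termination = pfn$termination,
                              n_tested = pfn$n_tested,
                              n_rejected = pfn$n_rejected,
                              acceptance_rate = pfn$acceptance_rate)
  write_edge_list(pfn, file.path(out_dir, "network.tsv"))
  write_gml(pfn, file.path(out_dir, "network.gml"))
  res$pfn <- pfn

  hierarchy <- run_stage("mca", {
    run_mca(pfn, alpha_grid = config$alpha_grid, dk = config$dk,
            n_rand = config$n_rand, sig_threshold = config$sig_threshold,
            min_size = config$min_size, seed = seeds[[2L]],
            transform = config$transform, epsilon = config$epsilon)
  })
  if (is.null(hierarchy)) return(finish(res))
  htab <- hierarchy_table(hierarchy)
  manifest$stages$mca <- list(n_clusters = nrow(htab),
                              n_significant = sum(!is.na(htab$p_value) &
                                                    htab$p_value <= config$sig_threshold))
  write.table(htab, file.path(out_dir, "hierarchy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res$hierarchy <- hierarchy

  mha <- run_stage("mha", {
    run_mha(pfn, hierarchy, n_s = config$n_s, N_s = config$N_s,
            sig_threshold = config$sig_threshold, seed = seeds[[3L]])
  })
  if (is.null(mha)) return(finish(res))
  manifest$stages$mha <- list(n_scales = length(mha$phi),
                              n_scale_groups = length(mha$scale_groups$groups),
                              n_multiscale_hubs = length(mha$multiscale_hubs))
  if (nrow(mha$table))
    write.table(mha$table, file.path(out_dir, "hubs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  res$mha <- mha

  if (!skip_cta && (!is.null(traits) || !is.null(survival))) {
    cta <- run_stage("cta", {
      run_cta(expr, hierarchy, traits = traits, survival = survival)
    })
    if (is.null(cta)) return(finish(res))
    manifest$stages$cta <- list(n_tests = nrow(cta))
    write.table(cta, file.path(out_dir, "associations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$cta <- cta
  }
  finish(res)
}
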