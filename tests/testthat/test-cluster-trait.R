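test_that("module eigengene captures the shared profile with the sign
           convention and maximal variance", {
  set.seed(2)
  prof <- rnorm(30)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof) +
    matrix(rnorm(90, sd = 1e-6), 3)
  colnames(expr) <- paste0("s", 1:30)
  eg <- module_eigengene(expr, c("g1", "g2", "g3"))
  expect_gt(abs(cor(eg, prof)), 0.999)
  expect_gte(cor(eg, colMeans(expr)), 0)
  # variance-explained matches a full eigendecomposition oracle (5 x 20)
  x <- matrix(rnorm(100), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  eg2 <- module_eigengene(x, paste0("g", 1:5))
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(t(xs)))$values
  expect_equal(attr(eg2, "var_explained"), ev[1] / sum(ev), tolerance = 1e-10)
  # the eigengene's explained variance beats every coordinate projection
  proj_var <- apply(xs, 1, function(row) (sum(row * eg2))^2)
  expect_gte(sum(xs %*% eg2 * (xs %*% eg2)), max(proj_var))
  expect_error(module_eigengene(x, "g1"), "at least 2")
})

test_that("trait association recovers exact and null relationships", {
  set.seed(3)
  eg <- setNames(rnorm(50), paste0("s", 1:50))
  expect_warning(self <- trait_association(eg, eg), "clipped")
  expect_equal(self$r, 1)
  expect_warning(anti <- trait_association(eg, -eg), "clipped")
  expect_equal(anti$r, -1)
  # permuted trait: small correlation, roughly uniform p over repeats
  eg1000 <- setNames(rnorm(1000), paste0("t", 1:1000))
  perm <- function() setNames(sample(unname(eg1000)), names(eg1000))
  ps <- replicate(50, trait_association(eg1000, perm())$p_value)
  expect_lt(max(abs(replicate(20, trait_association(eg1000, perm())$r))), 0.15)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_message(res <- trait_association(eg, rep(1, 50)), "constant")
  expect_true(is.na(res$r))
})

test_that("median-split logrank matches a hand-computed risk-set table and
           degenerates gracefully", {
  # 8 subjects, distinct event times; hand computation of O - E and V
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = c(1, 1, 1, 0, 1, 1, 0, 1))
  eg <- setNames(c(-4, -3, -2, -1, 1, 2, 3, 4), paste0("s", 1:8))
  res <- median_split_logrank(eg, surv)
  # oracle: accumulate O-E for the "high" group over pooled risk sets
  grp_high <- eg > median(eg)
  oe <- 0; v <- 0
  for (t in surv$time[surv$event == 1]) {
    at_risk <- surv$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp_high)
    d <- sum(surv$time == t & surv$event == 1)
    o1 <- sum(surv$time == t & surv$event == 1 & grp_high)
    e1 <- d * n1 / n
    oe <- oe + (o1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$statistic, oe^2 / v, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(oe^2 / v, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1 (duplicate each subject across arms)
  surv2 <- data.frame(sample = paste0("s", 1:8),
                      time = rep(c(1, 2, 3, 4), 2), event = 1)
  eg2 <- setNames(rep(c(-1, 1), each = 4), paste0("s", 1:8))
  res2 <- median_split_logrank(eg2, surv2)
  expect_lt(res2$statistic, 1e-10)
  # no events: warning and p = 1
  surv3 <- data.frame(sample = paste0("s", 1:8), time = 1:8, event = 0)
  expect_warning(res3 <- median_split_logrank(eg, surv3), "no events")
  expect_equal(res3$p_value, 1)
  # group labels are symmetric: relabeling leaves the statistic unchanged
  res4 <- median_split_logrank(-eg, surv)
  expect_equal(res4$statistic, res$statistic, tolerance = 1e-10)
})

test_that("simulated hazard-ratio-3 survival is detected in most seeds", {
  hits <- 0
  for (s in 1:50) {
    eg <- setNames(rnorm(200), paste0("s", 1:200))
    sv <- generate_survival(eg, hazard_ratio = 3, censoring_rate = 0.2,
                            seed = s)
    if (median_split_logrank(eg, sv)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90%
})

test_that("BH adjustment reproduces the step-up worked example and ordering
           guarantees", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(20)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(pmin(1, p * 20) >= bh_fdr(p)))  # Bonferroni dominates BH
})

test_that("fisher exact enrichment equals hypergeometric tail sums", {
  universe <- paste0("g", 1:1000)
  cl <- paste0("g", 1:20)
  gs <- paste0("g", c(1:10, 500:509))
  res <- cluster_signature_enrichment(cl, gs, universe)
  # direct tail sum: P(overlap >= 10) drawing 20 from an urn with 20 set genes
  oracle <- sum(dhyper(10:20, 20, 980, 20))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  # printed 2x2 example (10, 10, 10, 970)
  res2 <- cluster_signature_enrichment(paste0("g", 1:20),
                                       paste0("g", c(1:10, 21:30)),
                                       universe)
  expect_equal(res2$table[1, 1], 10)
  expect_equal(res2$p_value, sum(dhyper(10:20, 20, 980, 20)), tolerance = 1e-12)
  # disjoint cluster and set: odds ratio below 1
  res3 <- cluster_signature_enrichment(paste0("g", 1:50),
                                       paste0("g", 51:150), universe)
  expect_lt(res3$odds_ratio, 1)
  expect_error(cluster_signature_enrichment(cl, character(0), universe),
               "empty")
})

test_that("run_cta produces BH-corrected association tables over hierarchy
           clusters", {
  d <- planted_design(n_samples = 120, module_sizes = rep(15, 2),
                      loading = 0.85, seed = 8)
  gen <- generate_expression(d)
  pfn <- build_pfn(expression_pairs(gen$expr))
  h <- run_mca(pfn, seed = 3, n_rand = 50)
  traits <- data.frame(f1 = gen$factors[, 1], noise = rnorm(120),
                       row.names = rownames(gen$factors))
  sv <- generate_survival(setNames(gen$factors[, 1], rownames(gen$factors)),
                          hazard_ratio = 2.5, seed = 4)
  cta <- run_cta(gen$expr, h, traits = traits, survival = sv)
  expect_true(all(c("cluster_id", "trait", "statistic", "p_value", "fdr")
                  %in% names(cta)))
  # the module-1 factor trait is strongly associated with some cluster
  f1 <- cta[cta$trait == "f1", ]
  expect_lt(min(f1$fdr, na.rm = TRUE), 1e-6)
  expect_true(max(abs(f1$statistic), na.rm = TRUE) > 0.8)
  expect_true(all(cta$fdr >= cta$p_value - 1e-15, na.rm = TRUE))
})
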