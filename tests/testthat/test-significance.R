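test_that("competitive null draws exclude the target trait and honor shapes and seeds", {
  pool <- toy_pool(60, 40, 20, seed = 31)
  target <- pool$variants$trait_label[1]

  for (s in 1:25) {
    nm <- build_competitive_null(pool, p = 8, g = 12,
                                 exclude_traits = target, seed = s)
    expect_equal(dim(nm$Z), c(8L, 12L))
    expect_false(target %in% nm$variants$trait_label)
    # one variant per trait when enough traits are available
    expect_equal(anyDuplicated(nm$variants$trait_label), 0L)
  }

  d1 <- build_competitive_null(pool, 8, 12, seed = 99)
  d2 <- build_competitive_null(pool, 8, 12, seed = 99)
  expect_identical(d1$Z, d2$Z)
  d3 <- build_competitive_null(pool, 8, 12, seed = 100)
  expect_false(identical(rownames(d1$Z), rownames(d3$Z)) &&
                 identical(colnames(d1$Z), colnames(d3$Z)))

  expect_error(build_competitive_null(pool, 8, 12,
                                      exclude_traits = unique(pool$variants$trait_label)),
               class = "archie_bad_argument")
})

test_that("global null draws have the Kronecker covariance", {
  id2 <- correlation_matrix(diag(2), ids = c("a", "b"))
  # identity x identity: iid standard normal entries
  draws <- with(list(), {
    set.seed(5)
    replicate(10000, sample_global_null(id2, id2))
  })
  expect_equal(dim(draws[, , 1]), c(2L, 2L))
  expect_equal(var(as.vector(draws)), 1, tolerance = 0.03)

  # correlated genes: entries within a column correlate at 0.5
  coEE <- correlation_matrix(matrix(c(1, .5, .5, 1), 2), ids = c("g1", "g2"))
  set.seed(6)
  draws2 <- replicate(10000, sample_global_null(coEE, id2))
  expect_equal(cor(draws2[1, 1, ], draws2[2, 1, ]), 0.5, tolerance = 0.03)
  expect_equal(cor(draws2[1, 2, ], draws2[2, 2, ]), 0.5, tolerance = 0.03)
  # independent columns stay independent
  expect_equal(cor(draws2[1, 1, ], draws2[1, 2, ]), 0, tolerance = 0.03)
})

test_that("component p-values are exceedance proportions with the documented conventions", {
  nulls <- archie:::new_null_ensemble(
    matrix(c(seq(0.05, 0.5, length.out = 10),
             seq(0.05, 0.5, length.out = 10)), 10, 2), "global", 1L)

  # observation above all nulls: p = 0, printed as < 1/M
  res <- component_pvalues(c(0.9, 0.9), nulls)
  expect_equal(res$p_values, c(0, 0))
  expect_match(archie:::format_resampled_p(res$p_values[1], res$M), "^< ")

  # observation below all nulls: p = 1
  expect_equal(component_pvalues(c(0.01, 0.01), nulls)$p_values, c(1, 1))

  # exactly 3 of 10 nulls at or above the observation
  obs <- sort(nulls$null_q2[, 1])[8] # ties count as exceedances
  expect_equal(component_pvalues(c(obs, obs), nulls)$p_values[1], 0.3)

  # add-one correction and printed-inequality variant
  expect_equal(component_pvalues(c(obs, obs), nulls, add_one = TRUE)$p_values[1],
               4 / 11)
  expect_equal(component_pvalues(c(obs, obs), nulls,
                                 printed_inequality = TRUE)$p_values[1], 0.7)

  expect_error(component_pvalues(c(.1, .2, .3), nulls),
               class = "archie_bad_argument")
})

test_that("component p-values are monotone in the observed cc-value", {
  withr::local_seed(41)
  nulls <- archie:::new_null_ensemble(matrix(runif(200), 200, 1), "global", 1L)
  obs <- sort(runif(50))
  pv <- sapply(obs, function(o) component_pvalues(o, nulls)$p_values)
  expect_true(all(diff(pv) <= 0))
})

test_that("the number of significant components follows the sequential rule", {
  expect_equal(select_significant(c(0.001, 0.2, 0.3), 0.05), 1L)
  expect_equal(select_significant(c(0.2, 0.01), 0.05), 0L)
  # all components significant: L = K by convention
  expect_equal(select_significant(c(0.001, 0.002), 0.05), 2L)
  # invariant to p-values after the first exceedance
  expect_equal(select_significant(c(0.001, 0.2, 0.001), 0.05),
               select_significant(c(0.001, 0.2, 0.999), 0.05))
})

test_that("null ensembles reuse the observed budgets and are reproducible", {
  pool <- toy_pool(40, 30, 15, seed = 51)
  cfg <- scca_config(c_u = 1.4, c_v = 1.4)
  e1 <- null_ensemble_competitive(pool, 6, 10, K = 2, M = 20, cfg = cfg,
                                  seed = 7)
  e2 <- null_ensemble_competitive(pool, 6, 10, K = 2, M = 20, cfg = cfg,
                                  seed = 7)
  expect_identical(e1$null_q2, e2$null_q2)
  expect_equal(dim(e1$null_q2), c(20L, 2L))
  expect_true(all(e1$null_q2 >= 0 & e1$null_q2 <= 1))
})

test_that("trait-specificity rises with the trait-specific proportion delta", {
  # planted rank-one signal shared by the target trait's variants and
  # concentrated on a sparse subset of genes (trait-specific target set)
  withr::local_seed(61)
  g_ids <- sprintf("s_g%03d", 1:40)
  bvec <- numeric(40); bvec[sample(40, 10)] <- rnorm(10, sd = 1) + 1
  trait_Z <- matrix(rnorm(30 * 40), 30, 40) +
    6 * tcrossprod(abs(rnorm(30)) + .5, bvec / sqrt(sum(bvec^2)))
  trait_pool <- summary_matrix(
    trait_Z, toy_variants(sprintf("s_v%03d", 1:30), trait = "target"),
    toy_genes(g_ids), n_study = 1000L)
  other_pool <- toy_pool(80, 40, 25, seed = 62)
  other_pool$genes$gene_id <- g_ids
  colnames(other_pool$Z) <- g_ids

  # every trait variant carries the shared factor, so the variant budget is
  # set near sqrt(p); the gene side stays sparse to match the target set
  cfg <- scca_config(c_u = 3)
  est1 <- trait_specificity_experiment(trait_pool, other_pool, delta = 1,
                                       p = 10, g = 20, reps = 20, M = 49,
                                       alpha = 0.05, seed = 63, cfg = cfg)
  est0 <- trait_specificity_experiment(trait_pool, other_pool, delta = 0,
                                       p = 10, g = 20, reps = 20, M = 49,
                                       alpha = 0.05, seed = 63, cfg = cfg)
  expect_true(est1 >= 0 && est1 <= 1)
  expect_gte(est1, est0)
  expect_gt(est1, 0.5) # planted signal is detected in most replicates
})

test_that("at delta = 0 the competitive test is approximately calibrated", {
  trait_pool <- toy_pool(30, 40, 10, seed = 71, prefix = "tp")
  other_pool <- toy_pool(90, 40, 30, seed = 72, prefix = "op")
  other_pool$genes$gene_id <- trait_pool$genes$gene_id
  colnames(other_pool$Z) <- trait_pool$genes$gene_id
  alpha <- 0.05; reps <- 40
  est0 <- trait_specificity_experiment(trait_pool, other_pool, delta = 0,
                                       p = 10, g = 20, reps = reps, M = 99,
                                       alpha = alpha, seed = 73)
  expect_lte(est0, alpha + 2 * sqrt(alpha / reps))
})

test_that("significance reports serialize to TSV and JSON", {
  nulls <- archie:::new_null_ensemble(matrix(runif(30), 10, 3), "global", 9L)
  res <- component_pvalues(c(.99, .5, .01), nulls)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_significance(nulls, res, alpha = 0.05, tsv_path = tsv, json_path = js)
  grid <- read.delim(tsv)
  expect_equal(dim(grid), c(10L, 3L))
  rep <- jsonlite::read_json(js)
  expect_equal(length(rep$p_values), 3L)
  expect_equal(rep$M, 10L)
})
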