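test_that("simulated genotypes are binomial dosages with the requested frequencies", {
  g <- simulate_genotypes(500, 12, seed = 1)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(dim(g$dosages), c(500L, 12L))
  expect_true(all(g$mafs >= 0.10 & g$mafs <= 0.40))
  expect_identical(g$dosages, simulate_genotypes(500, 12, seed = 1)$dosages)

  # law of large numbers: empirical frequency tracks the drawn one
  big <- simulate_genotypes(100000, 3, seed = 2)
  expect_equal(unname(colMeans(big$dosages) / 2), unname(big$mafs),
               tolerance = 0.01)

  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)),
               class = "archie_bad_argument")
})

test_that("network presets encode the documented topologies", {
  nets <- lapply(c("global_null", "sparse", "dense", "master_regulator"),
                 function(p) build_network(p, seed = 3))
  names(nets) <- sapply(nets, `[[`, "preset")

  # acyclicity: every parent precedes its child in the build order
  for (nt in nets) {
    order_ <- c(nt$cis, nt$downstream)
    for (child in names(nt$edges)) {
      expect_true(all(match(names(nt$edges[[child]]), order_) <
                        match(child, order_)))
    }
  }

  n_edges <- sapply(nets, function(nt) sum(lengths(nt$edges)))
  expect_gt(n_edges[["dense"]], n_edges[["sparse"]])
  # dense: every downstream gene has >= 4 parents; sparse: <= 2
  expect_true(all(lengths(nets$dense$edges) >= 4))
  expect_true(all(lengths(nets$sparse$edges) <= 2))
  # master regulator: one hub mediates everything
  expect_equal(names(nets$master_regulator$edges)[1], "D1")
  expect_true(all(sapply(nets$master_regulator$edges[-1], names) == "D1"))

  expect_error(build_network("nope"), class = "archie_bad_argument")
  expect_error(build_network("sparse", n_snps = 12),
               class = "archie_bad_argument")
})

test_that("the global-null preset has exactly zero SNP-to-downstream effect", {
  net <- calibrate_effects(build_network("global_null", seed = 4))
  snp_cols <- seq_len(net$n_snps)
  expect_true(all(net$coefficients[net$downstream, snp_cols] == 0))
  expect_equal(unname(net$trans_h2), rep(0, 9))
  # non-exogenous nulls draw 20-30% of variance from upstream genes
  expl <- net$explained
  expect_true(all(expl >= 0.20 & expl <= 0.30))
})

test_that("calibration hits the heritability bands analytically and is scale invariant", {
  for (preset in c("sparse", "dense")) {
    net <- calibrate_effects(build_network(preset, seed = 5))
    expect_gte(mean(net$cis_h2), 0.20); expect_lte(mean(net$cis_h2), 0.22)
    expect_gte(mean(net$trans_h2), 0.10); expect_lte(mean(net$trans_h2), 0.14)
    # every gene has unit total variance by construction
    expect_equal(unname(rowSums(net$coefficients^2)),
                 rep(1, net$n_cis + 9), tolerance = 1e-12)
  }

  # doubling the raw effects changes nothing after calibration
  raw <- build_network("sparse", seed = 5)
  scaled <- raw
  scaled$snp_effects <- lapply(raw$snp_effects, `*`, 2)
  scaled$edges <- lapply(raw$edges, `*`, 2)
  expect_equal(calibrate_effects(raw)$coefficients,
               calibrate_effects(scaled)$coefficients, tolerance = 1e-12)
})

test_that("expression follows the linear SEM exactly in the noiseless limit", {
  net <- calibrate_effects(build_network("sparse", seed = 6))
  net$noise_sd[] <- 0
  g <- simulate_genotypes(200, 40, seed = 7)
  E <- simulate_expression(net, g$dosages, g$mafs, seed = 8)
  # every gene is then an exact linear function of the dosages
  for (gene in c(net$cis, net$downstream)) {
    fit <- lm.fit(cbind(1, g$dosages), E[, gene])
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
  expect_error(simulate_expression(build_network("sparse", seed = 6),
                                   g$dosages, g$mafs),
               class = "archie_bad_argument")
})

test_that("analytic heritabilities match large-sample regression R-squared", {
  net <- calibrate_effects(build_network("dense", seed = 9))
  g <- simulate_genotypes(60000, 40, seed = 10)
  E <- simulate_expression(net, g$dosages, g$mafs, seed = 11)
  cis_r2 <- sapply(seq_along(net$cis), function(j) {
    f <- lm.fit(cbind(1, g$dosages[, net$blocks[[j]]]), E[, net$cis[j]])
    1 - sum(f$residuals^2) / sum((E[, net$cis[j]] - mean(E[, net$cis[j]]))^2)
  })
  expect_equal(cis_r2, unname(net$cis_h2), tolerance = 0.02)
  trans_r2 <- sapply(net$downstream, function(d) {
    f <- lm.fit(cbind(1, g$dosages), E[, d])
    1 - sum(f$residuals^2) / sum((E[, d] - mean(E[, d]))^2)
  })
  expect_equal(unname(trans_r2), unname(net$trans_h2), tolerance = 0.02)
})

test_that("under the global null, SNP-downstream correlations vanish at scale", {
  net <- calibrate_effects(build_network("global_null", seed = 12))
  g <- simulate_genotypes(100000, 40, seed = 13)
  E <- simulate_expression(net, g$dosages, g$mafs, seed = 14)
  expect_lt(max(abs(cor(g$dosages, E[, net$downstream]))), 0.02)
})

test_that("per-pair mapping matches the closed-form OLS statistic", {
  # hand data: slope 1, se sqrt(0.0075), so t = 1/sqrt(0.0075)
  x <- c(0, 1, 1, 2); y <- c(0.1, 0.9, 1.1, 2.1)
  sm <- map_trans_eqtl(cbind(s = x), cbind(g = y), normal_approx = FALSE)
  expect_equal(sm$Z[1, 1], 1 / sqrt(0.0075), tolerance = 1e-10)

  # near-copy of a dosage column is overwhelming at n = 1000
  withr::local_seed(15)
  d <- matrix(rbinom(2000, 2, 0.3), 1000, 2,
              dimnames = list(NULL, c("s1", "s2")))
  e <- cbind(gA = d[, 1] + rnorm(1000, sd = 0.01), gB = rnorm(1000))
  sm2 <- map_trans_eqtl(d, e)
  expect_gt(abs(sm2$Z["s1", "gA"]), 30)
  expect_true(all(sm2$genes$chromosome != sm2$variants$chromosome))

  # independent pairs give uniform p-values
  d0 <- matrix(rbinom(400 * 25, 2, 0.25), 400, 25)
  e0 <- matrix(rnorm(400 * 400), 400, 400)
  p0 <- as.vector(map_trans_eqtl(d0, e0, normal_approx = FALSE)$P)
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)

  expect_error(map_trans_eqtl(cbind(s = rep(1, 10)), cbind(g = rnorm(10))),
               class = "archie_bad_argument")
})

test_that("selection metrics implement the confusion-matrix definitions", {
  expect_equal(selection_metrics(1:2, 1:2, 1:10),
               c(sensitivity = 1, specificity = 1))
  expect_equal(selection_metrics(integer(0), 1:2, 1:10),
               c(sensitivity = 0, specificity = 1))
  expect_equal(selection_metrics(c(2, 3), 1:2, 1:10),
               c(sensitivity = 0.5, specificity = 7 / 8))
  expect_error(selection_metrics(1, integer(0), 1:10),
               class = "archie_bad_argument")
})

test_that("pairwise type-I proportions are monotone in alpha and reproducible", {
  m <- estimate_type1(reps = 60, alpha_grid = c(1e-2, 1e-3, 1e-4),
                      method = "pairwise", n = 400, seed = 16)
  expect_true(all(m$type1 >= 0 & m$type1 <= 1))
  expect_true(all(diff(m$type1) <= 0)) # grid is sorted decreasing in alpha
  m2 <- estimate_type1(reps = 60, alpha_grid = c(1e-2, 1e-3, 1e-4),
                       method = "pairwise", n = 400, seed = 16)
  expect_identical(m$type1, m2$type1)
})
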