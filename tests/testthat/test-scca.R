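test_that("soft_threshold applies the elementwise closed form", {
  x <- c(3, -1, 0.5)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(x, 1), c(2, 0, 0))
  # L1 norm is non-increasing in the threshold
  withr::local_seed(2)
  v <- rnorm(10)
  l1 <- sapply(seq(0, max(abs(v)), length.out = 25),
               function(d) sum(abs(soft_threshold(v, d))))
  expect_true(all(diff(l1) <= 1e-12))
  expect_error(soft_threshold(x, -1), class = "archie_bad_argument")
})

test_that("the L1/L2 projection respects both norms across budgets", {
  withr::local_seed(4)
  for (i in 1:50) {
    p <- sample(3:30, 1)
    a <- rnorm(p)
    c <- runif(1, 1.001, sqrt(p) * 0.999)
    u <- archie:::l1_unit(a, c)
    expect_equal(sum(u^2), 1, tolerance = 1e-9)
    expect_lte(sum(abs(u)), c + 1e-6)
  }
  # support shrinks monotonically as the budget tightens
  a <- rnorm(12)
  grid <- seq(sqrt(12) * 0.99, 1.01, length.out = 12)
  supports <- lapply(grid, function(c) which(archie:::l1_unit(a, c) != 0))
  for (i in seq_len(length(grid) - 1L)) {
    expect_true(all(supports[[i + 1L]] %in% supports[[i]]))
  }
})

test_that("a point-mass matrix yields the corresponding basis component with q2 = 1", {
  W <- matrix(0, 4, 5); W[2, 3] <- 1
  cm <- fit_component(W, scca_config(c_u = 1, c_v = 1))
  expect_equal(unname(cm$u), c(0, 0, 1, 0, 0))
  expect_equal(unname(cm$v), c(0, 1, 0, 0))
  expect_equal(cm$q2, 1)
})

test_that("unpenalized fits recover the leading singular pair", {
  withr::local_seed(6)
  for (i in 1:10) {
    W <- matrix(rnorm(48), 6, 8)
    cm <- fit_component(W, scca_config(c_u = sqrt(8), c_v = sqrt(6),
                                       max_iter = 2000L, tol = 1e-14))
    sv <- svd(W)
    expect_equal(cm$objective, sv$d[1], tolerance = 1e-6)
    expect_equal(cm$q2, 1, tolerance = 1e-6)
    s <- sign(sum(cm$u * sv$v[, 1]))
    expect_equal(unname(cm$u), s * sv$v[, 1], tolerance = 1e-4)
    expect_equal(unname(cm$v), s * sv$u[, 1], tolerance = 1e-4)
  }
})

test_that("rank-one sparse construction recovers the planted supports", {
  # unequal magnitudes so the L1 budget can bind inside the support
  a <- c(0.9, 0.6, 0.3, rep(0, 5)); a <- a / sqrt(sum(a^2))
  b <- c(rep(0, 4), 1.0, 0.7, 0.4, rep(0, 3)); b <- b / sqrt(sum(b^2))
  W <- tcrossprod(a, b) # genes x variants
  cm <- fit_component(W, scca_config(c_u = 1.5, c_v = 1.5))
  expect_equal(unname(cm$selected_variants), which(b != 0))
  expect_equal(unname(cm$selected_genes), which(a != 0))
})

test_that("support recovery succeeds in at least 95% of noisy rank-one runs", {
  ok <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    withr::local_seed(1000 + s)
    g <- 15L; p <- 20L
    av <- numeric(g); av[sample(g, 3)] <- runif(3, 0.5, 1.5)
    bv <- numeric(p); bv[sample(p, 3)] <- runif(3, 0.5, 1.5)
    av <- av / sqrt(sum(av^2)); bv <- bv / sqrt(sum(bv^2))
    signal <- tcrossprod(av, bv) # Frobenius norm 1
    noise <- matrix(rnorm(g * p), g, p)
    noise <- noise / sqrt(sum(noise^2)) / 10 # signal : noise = 10 : 1
    # budgets just inside the planted vectors' L1 norms: the threshold must
    # then clear the noise floor while all planted entries survive
    cm <- fit_component(signal + noise,
                        scca_config(c_u = max(1, 0.95 * sum(abs(bv))),
                                    c_v = max(1, 0.95 * sum(abs(av)))))
    if (identical(unname(cm$selected_variants), which(bv != 0)) &&
        identical(unname(cm$selected_genes), which(av != 0))) ok <- ok + 1L
  }
  expect_gte(ok / n_runs, 0.95)
})

test_that("deflation extracts axes of a diagonal matrix in order", {
  W <- diag(c(3, 2, 1))
  fit <- fit_components(W, 3, scca_config(c_u = 1, c_v = 1))
  for (k in 1:3) {
    expect_equal(unname(fit$components[[k]]$u), as.numeric(1:3 == k))
    expect_equal(unname(fit$components[[k]]$v), as.numeric(1:3 == k))
  }
  # exact-rank matrix: residual vanishes after K unpenalized extractions
  withr::local_seed(13)
  U <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  V <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  W2 <- U %*% diag(c(2, 1)) %*% t(V) # rank 2, 5 x 6
  fit2 <- fit_components(W2, 2, scca_config(c_u = sqrt(6), c_v = sqrt(5),
                                            max_iter = 1000L, tol = 1e-14))
  expect_lt(fit2$deflation_residuals[2], 1e-6)
  # unpenalized cc-values of exact singular pairs equal 1 at every rank
  expect_true(all(abs(fit2$q2 - 1) < 1e-6))
})

test_that("cc_value matches the coordinate closed form and is bounded", {
  withr::local_seed(17)
  W <- matrix(rnorm(9), 3, 3)
  for (i in 1:3) for (j in 1:3) {
    u <- as.numeric(1:3 == i) # variant side
    v <- as.numeric(1:3 == j) # gene side
    expect_equal(cc_value(W, u, v),
                 min(1, W[j, i]^2 /
                       sqrt(crossprod(W[, i]) * crossprod(W[j, ]))),
                 tolerance = 1e-12)
  }
  # v orthogonal to W u gives 0
  W0 <- matrix(0, 2, 2); W0[1, 1] <- 1
  expect_equal(as.numeric(cc_value(W0, c(1, 0), c(0, 1))), 0)

  # Cauchy-Schwarz bound on randomized inputs
  for (i in 1:200) {
    W <- matrix(rnorm(35), 5, 7)
    u <- rnorm(7); u <- u / sqrt(sum(u^2))
    v <- rnorm(5); v <- v / sqrt(sum(v^2))
    q <- cc_value(W, u, v)
    expect_true(q >= 0 && q <= 1)
  }
})

test_that("fits are deterministic and respect the component invariants", {
  withr::local_seed(19)
  W <- matrix(rnorm(60), 6, 10)
  f1 <- fit_components(W, 3)
  f2 <- fit_components(W, 3)
  expect_identical(f1, f2)
  for (cm in f1$components) {
    expect_equal(sum(cm$u^2), 1, tolerance = 1e-6)
    expect_equal(sum(cm$v^2), 1, tolerance = 1e-6)
    expect_lte(sum(abs(cm$u)), cm$c_u + 1e-6)
    expect_lte(sum(abs(cm$v)), cm$c_v + 1e-6)
    expect_true(cm$q2 >= 0 && cm$q2 <= 1)
    # sign convention: largest-magnitude variant loading is positive
    expect_gt(cm$u[which.max(abs(cm$u))], 0)
  }
  expect_error(fit_components(W, 7), class = "archie_bad_argument")
  expect_error(fit_component(matrix(0, 3, 3)), class = "archie_bad_argument")
})

test_that("budgets outside the feasible range are rejected", {
  W <- matrix(rnorm(20), 4, 5)
  expect_error(fit_component(W, scca_config(c_u = 0.5)),
               class = "archie_bad_argument")
  expect_error(fit_component(W, scca_config(c_v = 10)),
               class = "archie_bad_argument")
  expect_equal(default_sparsity(25), 1 + 0.3 * 4)
})
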