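# Causal-network simulation engine.
#
# Genotypes are independent biallelic SNPs (dosages Binomial(2, maf)), in
# blocks of five driving one cis gene each.  Downstream genes form a weighted
# acyclic gene-gene network.  Everything is a linear structural equation
# model, so each gene is a linear combination of the standardized SNP dosages
# and per-gene Gaussian noise terms; variances and heritabilities are
# therefore available in closed form by path counting, and calibration
# rescales effects analytically rather than by trial simulation.
#
# Presets (topologies are frozen; weights are drawn per seed and then
# calibrated):
#   global_null      downstream genes 1-4 exogenous, 5-9 driven only by 1-4;
#                    no SNP -> downstream path exists, so the total SNP effect
#                    on every downstream gene is exactly zero.
#   sparse           each downstream gene has at most 2 parents.
#   dense            each downstream gene has at least 4 parents.
#   master_regulator one hub downstream gene mediates all cis effects.

CIS_H2_RANGE <- c(0.20, 0.22)
TRANS_H2_RANGE <- c(0.10, 0.14)
NULL_UPSTREAM_RANGE <- c(0.20, 0.30)

#' Simulate independent SNP genotypes
#'
#' Per-SNP minor allele frequencies are drawn uniformly on `maf_range`;
#' dosages are iid Binomial(2, maf) across individuals, and SNPs are mutually
#' independent (no LD).
#'
#' @param n number of individuals.
#' @param n_snps number of SNPs.
#' @param maf_range `(low, high)` with `0 < low <= high <= 0.5`.
#' @param seed RNG seed.
#' @return List with `dosages` (n x n_snps integer-valued matrix, columns
#'   `snp1..`) and `mafs`.
#' @export
simulate_genotypes <- function(n, n_snps = 40L, maf_range = c(0.10, 0.40),
                               seed = NULL) {
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L]) {
    archie_abort("maf_range must satisfy 0 < low <= high <= 0.5",
                 "archie_bad_argument")
  }
  with_seed(seed, {
    mafs <- runif(n_snps, maf_range[1L], maf_range[2L])
    X <- matrix(rbinom(n * n_snps, 2L, rep(mafs, each = n)), n, n_snps)
    colnames(X) <- paste0("snp", seq_len(n_snps))
    names(mafs) <- colnames(X)
    list(dosages = X, mafs = mafs)
  })
}

# frozen downstream adjacency per preset; parents reference cis genes C* and
# earlier downstream genes D* only (topological order D1 < ... < D9)
preset_edges <- function(preset, n_cis) {
  cis <- paste0("C", seq_len(n_cis))
  ed <- switch(preset,
    global_null = list(
      D5 = c("D1", "D2"), D6 = c("D2", "D3"), D7 = c("D3", "D4"),
      D8 = c("D1", "D4"), D9 = c("D1", "D3")),
    sparse = list(
      D1 = cis[c(1, 2) %% n_cis + 1], D2 = cis[c(2, 3) %% n_cis + 1],
      D3 = cis[c(4, 5) %% n_cis + 1], D4 = cis[c(6, 7) %% n_cis + 1],
      D5 = c("D1", "D2"), D6 = c("D2", "D3"), D7 = c("D3", "D4"),
      D8 = c("D5", "D6"), D9 = c("D6", "D7")),
    dense = list(
      D1 = cis[(0:3) %% n_cis + 1], D2 = cis[(2:5) %% n_cis + 1],
      D3 = cis[(4:7) %% n_cis + 1], D4 = cis[c(0, 1, 6, 7) %% n_cis + 1],
      D5 = c("D1", "D2", cis[(4:5) %% n_cis + 1]),
      D6 = c("D2", "D3", cis[c(0, 7) %% n_cis + 1]),
      D7 = c("D3", "D4", cis[(2:3) %% n_cis + 1]),
      D8 = c("D5", "D6", "D7", "D1"),
      D9 = c("D6", "D7", "D8", "D2")),
    master_regulator = c(
      list(D1 = cis),
      setNames(rep(list("D1"), 8L), paste0("D", 2:9))),
    archie_abort(sprintf("unknown preset: %s", preset), "archie_bad_argument"))
  lapply(ed, unique)
}

preset_layers <- function(preset) {
  switch(preset,
    master_regulator = list(hub = "D1", downstream = paste0("D", 2:9)),
    list(layer1 = paste0("D", 1:4), layer2 = paste0("D", 5:7),
         layer3 = paste0("D", 8:9)))
}

#' Build a causal network specification
#'
#' Returns the bundled topology for the preset with raw (uncalibrated) effect
#' sizes drawn from the seeded RNG: SNP-to-cis effect vectors (five SNPs per
#' cis gene) and gene-gene edge weights, both standard normal.  Edge
#' *existence* is fixed per preset; only the weights vary with the seed.
#' [calibrate_effects()] must be applied before simulation.
#'
#' @param preset one of `"global_null"`, `"sparse"`, `"dense"`,
#'   `"master_regulator"`.
#' @param seed RNG seed for the raw weights.
#' @param n_snps number of SNPs; must be a multiple of 5 (each block of five
#'   drives one cis gene).
#' @return An object of class `archie_network`.
#' @export
build_network <- function(preset = c("sparse", "dense", "global_null",
                                     "master_regulator"),
                          seed = NULL, n_snps = 40L) {
  if (length(preset) == 1L &&
      !preset %in% c("sparse", "dense", "global_null", "master_regulator")) {
    archie_abort(sprintf("unknown preset: %s", preset), "archie_bad_argument")
  }
  preset <- match.arg(preset)
  if (n_snps %% 5L != 0L || n_snps < 5L) {
    archie_abort("n_snps must be a positive multiple of 5", "archie_bad_argument")
  }
  n_cis <- n_snps %/% 5L
  cis <- paste0("C", seq_len(n_cis))
  downstream <- paste0("D", 1:9)
  edges <- preset_edges(preset, n_cis)
  bad <- setdiff(unlist(edges), c(cis, downstream))
  if (length(bad)) {
    archie_abort(sprintf("preset references missing cis gene %s (n_snps too small)",
                         bad[1L]), "archie_bad_argument")
  }
  exogenous <- setdiff(downstream, names(edges))
  with_seed(seed, {
    snp_effects <- lapply(cis, function(g) rnorm(5L))
    names(snp_effects) <- cis
    edge_weights <- lapply(edges, function(par) setNames(rnorm(length(par)), par))
  })
  structure(
    list(preset = preset, n_snps = as.integer(n_snps), n_cis = n_cis,
         cis = cis, downstream = downstream,
         blocks = setNames(lapply(seq_len(n_cis),
                                  function(j) ((j - 1L) * 5L + 1L):(j * 5L)),
                           cis),
         snp_effects = snp_effects,
         edges = edge_weights, exogenous = exogenous,
         layers = preset_layers(preset),
         targets = list(cis_h2 = CIS_H2_RANGE, trans_h2 = TRANS_H2_RANGE,
                        null_upstream = NULL_UPSTREAM_RANGE),
         calibrated = FALSE),
    class = "archie_network"
  )
}

#' @export
print.archie_network <- function(x, ...) {
  cat(sprintf("archie_network [%s]: %d SNPs -> %d cis genes -> %d downstream genes%s\n",
              x$preset, x$n_snps, x$n_cis, length(x$downstream),
              if (x$calibrated) " (calibrated)" else " (uncalibrated)"))
  if (x$calibrated) {
    cat(sprintf("  mean cis h2 = %.3f, mean downstream trans h2 = %.3f\n",
                mean(x$cis_h2), mean(x$trans_h2)))
  }
  invisible(x)
}

# Propagate coefficients through the SEM for a given downstream explained
# fraction e_d (scalar or named vector).  Basis: n_snps standardized dosages
# followed by one unit-variance noise term per gene.  Returns the full
# coefficient matrix (genes x basis); every gene has unit total variance by
# construction.
propagate_coefficients <- function(net, snp_effects, explained) {
  genes <- c(net$cis, net$downstream)
  nb <- net$n_snps + length(genes)
  basis <- c(paste0("snp", seq_len(net$n_snps)), paste0("eps_", genes))
  C <- matrix(0, length(genes), nb, dimnames = list(genes, basis))
  for (g in net$cis) {
    beta <- snp_effects[[g]]
    C[g, net$blocks[[g]]] <- beta
    C[g, paste0("eps_", g)] <- sqrt(max(0, 1 - sum(beta^2)))
  }
  for (g in net$downstream) {
    if (g %in% net$exogenous) {
      C[g, paste0("eps_", g)] <- 1
      next
    }
    w <- net$edges[[g]]
    combo <- drop(w %*% C[names(w), , drop = FALSE])
    vraw <- sum(combo^2)
    e <- if (length(explained) == 1L) explained else explained[[g]]
    C[g, ] <- combo * sqrt(e / vraw)
    C[g, paste0("eps_", g)] <- sqrt(1 - e)
  }
  C
}

snp_h2 <- function(C, net, genes) {
  rowSums(C[genes, seq_len(net$n_snps), drop = FALSE]^2)
}

#' Calibrate network effects to the target heritabilities
#'
#' Rescales the raw effects analytically.  SNP-to-cis effect vectors are
#' scaled so the cis heritabilities are evenly spaced across the 20-22%
#' target band (their average is exactly 21%).  For the sparse, dense and
#' master-regulator presets, all downstream genes share one explained-
#' variance fraction from their parents; that fraction is solved by
#' root-finding so the analytic average downstream trans heritability (sum of
#' squared SNP-to-gene path products) equals the 12% midpoint of the 10-14%
#' target band.  For the global-null preset the non-exogenous downstream
#' genes get upstream explained fractions evenly spaced across 20-30%, and
#' their trans heritability is exactly zero because no SNP path exists.
#' Residual variances are set so every gene has unit total variance.
#'
#' @param net an uncalibrated [build_network()] result.
#' @return The network with `calibrated = TRUE`, scaled effects, per-gene
#'   noise standard deviations, the full coefficient matrix over
#'   (standardized SNPs + noise terms), and analytic `cis_h2` / `trans_h2`
#'   vectors.
#' @export
calibrate_effects <- function(net) {
  stopifnot(inherits(net, "archie_network"))
  h2c <- if (net$n_cis == 1L) mean(CIS_H2_RANGE) else
    seq(CIS_H2_RANGE[1L], CIS_H2_RANGE[2L], length.out = net$n_cis)
  snp_effects <- lapply(seq_along(net$cis), function(j) {
    raw <- net$snp_effects[[j]]
    raw * sqrt(h2c[j] / sum(raw^2))
  })
  names(snp_effects) <- net$cis

  if (net$preset == "global_null") {
    nonexo <- setdiff(net$downstream, net$exogenous)
    expl <- setNames(seq(NULL_UPSTREAM_RANGE[1L], NULL_UPSTREAM_RANGE[2L],
                         length.out = length(nonexo)), nonexo)
    C <- propagate_coefficients(net, snp_effects, expl)
    explained <- expl
  } else {
    target <- mean(TRANS_H2_RANGE)
    avg_trans <- function(e) {
      C <- propagate_coefficients(net, snp_effects, e)
      mean(snp_h2(C, net, net$downstream))
    }
    e_max <- 0.95
    if (avg_trans(e_max) < target) {
      archie_abort(sprintf("trans heritability target %.2f infeasible for preset '%s': at most %.3f reachable",
                           target, net$preset, avg_trans(e_max)),
                   "archie_bad_argument")
    }
    e_star <- uniroot(function(e) avg_trans(e) - target,
                      lower = 1e-4, upper = e_max, tol = 1e-10)$root
    C <- propagate_coefficients(net, snp_effects, e_star)
    explained <- setNames(rep(e_star, length(setdiff(net$downstream, net$exogenous))),
                          setdiff(net$downstream, net$exogenous))
  }

  # recover the calibrated edge weights: scale factor applied per gene equals
  # sqrt(e / vraw) used during propagation
  edges_cal <- net$edges
  for (g in names(edges_cal)) {
    w <- net$edges[[g]]
    combo <- drop(w %*% C[names(w), , drop = FALSE])
    vraw <- sum(combo^2)
    edges_cal[[g]] <- w * sqrt(explained[[g]] / vraw)
  }

  genes <- c(net$cis, net$downstream)
  net$snp_effects_cal <- snp_effects
  net$edges_cal <- edges_cal
  net$explained <- explained
  net$coefficients <- C
  net$noise_sd <- setNames(C[cbind(genes, paste0("eps_", genes))], genes)
  net$cis_h2 <- snp_h2(C, net, net$cis)
  net$trans_h2 <- snp_h2(C, net, net$downstream)
  net$calibrated <- TRUE
  net
}

#' Analytic gene-gene correlation matrix of a calibrated network
#'
#' Since every gene is a unit-variance linear combination of orthonormal
#' exogenous variables, correlations are inner products of coefficient rows.
#'
#' @param net a calibrated [archie_network].
#' @param genes gene ids (default: the downstream genes).
#' @return A [correlation_matrix()].
#' @export
network_coexpression <- function(net, genes = NULL) {
  stopifnot(inherits(net, "archie_network"), isTRUE(net$calibrated))
  genes <- genes %||% net$downstream
  V <- tcrossprod(net$coefficients[genes, , drop = FALSE])
  V <- (V + t(V)) / 2
  diag(V) <- 1
  correlation_matrix(V, ids = genes)
}

#' Simulate expression from a calibrated network
#'
#' Genes are generated in topological order: each gene is the weighted sum of
#' its parents plus its SNP contribution (cis genes) plus Gaussian noise.
#' Dosages are standardized with the supplied true allele frequencies:
#' `(x - 2m) / sqrt(2 m (1 - m))`.
#'
#' @param net a calibrated [archie_network].
#' @param dosages n x n_snps dosage matrix.
#' @param mafs per-SNP allele frequencies used for standardization.
#' @param seed RNG seed for the noise draws.
#' @return n x (n_cis + 9) expression matrix, columns `C1.. D1..`.
#' @export
simulate_expression <- function(net, dosages, mafs, seed = NULL) {
  stopifnot(inherits(net, "archie_network"))
  if (!isTRUE(net$calibrated)) {
    archie_abort("network must be calibrated before simulation (see calibrate_effects)",
                 "archie_bad_argument")
  }
  if (ncol(dosages) != net$n_snps) {
    archie_abort("dosage column count does not match n_snps", "archie_bad_argument")
  }
  n <- nrow(dosages)
  Xs <- sweep(sweep(dosages, 2L, 2 * mafs, "-"), 2L,
              sqrt(2 * mafs * (1 - mafs)), "/")
  genes <- c(net$cis, net$downstream)
  E <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  with_seed(seed, {
    for (g in net$cis) {
      E[, g] <- Xs[, net$blocks[[g]], drop = FALSE] %*% net$snp_effects_cal[[g]] +
        rnorm(n, 0, net$noise_sd[[g]])
    }
    for (g in net$downstream) {
      base <- if (g %in% net$exogenous) 0 else {
        w <- net$edges_cal[[g]]
        drop(E[, names(w), drop = FALSE] %*% w)
      }
      E[, g] <- base + rnorm(n, 0, net$noise_sd[[g]])
    }
    E
  })
}

#' Per-pair trans-eQTL mapping
#'
#' Simple linear regression of each gene on each variant; the statistic is
#' slope / standard error with a two-sided p-value from the standard normal
#' reference (`normal_approx = TRUE`, the default, appropriate for the
#' n >= 1000 designs used here) or from the t reference.
#'
#' @param dosages n x p dosage matrix (columns named).
#' @param expression n x g expression matrix (columns named).
#' @param gene_subset optional gene names or indices to map (default: all).
#' @param normal_approx use the normal instead of the t reference.
#' @return A [summary_matrix()] with Z and p-value matrices and synthetic
#'   annotation (variants on chromosome 1, genes on chromosome 2, so every
#'   pair is trans by construction); `n_study` is the cohort size.
#' @export
map_trans_eqtl <- function(dosages, expression, gene_subset = NULL,
                           normal_approx = TRUE) {
  dosages <- as.matrix(dosages)
  expression <- as.matrix(expression)
  n <- nrow(dosages)
  if (n < 3L) archie_abort("need at least 3 individuals", "archie_bad_argument")
  if (!is.null(gene_subset)) {
    expression <- expression[, gene_subset, drop = FALSE]
  }
  check_no_constant(dosages, "dosage")
  check_no_constant(expression, "expression")
  R <- stats::cor(dosages, expression) # p x g
  R <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
  Z <- R * sqrt((n - 2) / (1 - R^2))
  P <- if (normal_approx) 2 * pnorm(-abs(Z)) else 2 * pt(-abs(Z), df = n - 2)
  p <- ncol(dosages); g <- ncol(expression)
  vids <- colnames(dosages) %||% paste0("snp", seq_len(p))
  gids <- colnames(expression) %||% paste0("gene", seq_len(g))
  summary_matrix(
    Z,
    variants = data.frame(variant_id = vids, chromosome = "1",
                          position = 1000000L * seq_len(p),
                          maf = pmin(colMeans(dosages) / 2, 0.5),
                          trait_label = NA_character_,
                          stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gids, chromosome = "2",
                       tss = 1000000L * seq_len(g), stringsAsFactors = FALSE),
    P = P, n_study = n
  )
}

# Shared machinery for the ARCHIE arm of the type-I / power harness: a fixed
# calibrated network, one reference co-expression estimate, and one global
# null ensemble reused across replicates (the null generator does not depend
# on the replicate).
archie_harness_setup <- function(net, K, M, cfg, n_ref) {
  genes <- net$downstream
  g <- length(genes); p <- net$n_snps
  ref <- simulate_genotypes(n_ref, p)
  E_ref <- simulate_expression(net, ref$dosages, ref$mafs)
  coexpr_ref <- estimate_coexpression(E_ref[, genes, drop = FALSE])
  # the null generator uses the same estimated co-expression that whitens the
  # observed matrix, and the model LD of independent SNPs (identity)
  ld_model <- correlation_matrix(diag(p), ids = paste0("snp", seq_len(p)))
  b <- resolve_budgets(cfg, p, g)
  ens <- null_ensemble_global(coexpr_ref, ld_model, K, M,
                              cfg = scca_config(b$c_u, b$c_v, b$max_iter, b$tol))
  list(genes = genes, coexpr_ref = coexpr_ref, iE = inverse_sqrt(coexpr_ref),
       ens = ens, budgets = b)
}

archie_rep_pvalues <- function(net, n, setup, K) {
  geno <- simulate_genotypes(n, net$n_snps)
  E <- simulate_expression(net, geno$dosages, geno$mafs)
  sm <- map_trans_eqtl(geno$dosages, E, gene_subset = setup$genes)
  # simulated SNPs are independent, so Sigma_GG is diagonal: no LD whitening
  sigma_ge <- t(z_to_cor(sm$Z, sm$n_study, "t"))
  Wm <- setup$iE %*% sigma_ge
  b <- setup$budgets
  obs <- scca_q2_seq(Wm, K, b$c_u, b$c_v, b$max_iter, b$tol)
  list(pv = component_pvalues(obs, setup$ens)$p_values, sm = sm, Wm = Wm,
       obs_q2 = obs)
}

#' Type-I error of ARCHIE and of pairwise mapping under the global null
#'
#' Runs `reps` independent global-null cohorts.  For `method = "pairwise"`,
#' each replicate's event at level alpha is "any of the p x g per-pair
#' p-values < alpha".  For `method = "archie"`, each replicate's observed
#' cc-values are tested against a global null ensemble (built once, since the
#' null generator is fixed by the preset) and the event is "at least one
#' significant component", i.e. `L >= 1` under the sequential selection rule
#' of [select_significant()].  The network is rebuilt (new weights) per
#' replicate for the pairwise arm; for the ARCHIE arm the topology and
#' calibrated weights are fixed and replicate randomness comes from the
#' cohort, mirroring the use of a fixed null-generating model.
#'
#' @param reps number of replicates.
#' @param alpha_grid levels at which the at-least-one proportions are
#'   reported.
#' @param method `"pairwise"` or `"archie"`.
#' @param M global-null resamples (ARCHIE only); must be at least
#'   `10 / min(alpha_grid)`.
#' @param n cohort size per replicate.
#' @param n_snps SNPs per cohort (multiple of 5).
#' @param K components tested (ARCHIE only).
#' @param n_ref reference cohort size for the co-expression estimate.
#' @param cfg [scca_config()] for the ARCHIE fits.
#' @param seed RNG seed.
#' @return An `archie_metrics` list: `$type1` (named proportions), plus the
#'   settings.
#' @export
estimate_type1 <- function(reps, alpha_grid = c(1e-3, 1e-4),
                           method = c("pairwise", "archie"), M = NULL,
                           n = 1000L, n_snps = 40L, K = 3L, n_ref = 700L,
                           cfg = NULL, seed = NULL) {
  method <- match.arg(method)
  if (reps < 1L) archie_abort("reps must be >= 1", "archie_bad_argument")
  alpha_grid <- sort(as.numeric(alpha_grid), decreasing = TRUE)
  if (method == "archie") {
    M <- M %||% ceiling(10 / min(alpha_grid))
    if (M < 1 / min(alpha_grid)) {
      archie_abort(sprintf("M = %d cannot resolve alpha = %g (need M >= %g)",
                           M, min(alpha_grid), 1 / min(alpha_grid)),
                   "archie_bad_argument")
    }
    if (M < 10 / min(alpha_grid)) {
      warning(sprintf("M = %d gives fewer than 10 null draws per alpha = %g tail; p-values are coarse",
                      M, min(alpha_grid)))
    }
  }
  with_seed(seed, {
    hits <- matrix(FALSE, reps, length(alpha_grid))
    if (method == "pairwise") {
      for (r in seq_len(reps)) {
        net <- calibrate_effects(build_network("global_null", n_snps = n_snps))
        geno <- simulate_genotypes(n, n_snps)
        E <- simulate_expression(net, geno$dosages, geno$mafs)
        sm <- map_trans_eqtl(geno$dosages, E, gene_subset = net$downstream)
        minp <- min(sm$P)
        hits[r, ] <- minp < alpha_grid
      }
    } else {
      net <- calibrate_effects(build_network("global_null", n_snps = n_snps))
      setup <- archie_harness_setup(net, K, M, cfg, n_ref)
      for (r in seq_len(reps)) {
        pv <- archie_rep_pvalues(net, n, setup, K)$pv
        # "at least one significant component" under the sequential rule:
        # components are accepted in rank order, so the event is L >= 1
        hits[r, ] <- vapply(alpha_grid,
                            function(a) select_significant(pv, a) >= 1L,
                            logical(1))
      }
    }
    structure(list(type1 = setNames(colMeans(hits), format(alpha_grid)),
                   reps = reps, alpha = alpha_grid, method = method,
                   n = n, n_snps = n_snps,
                   M = if (method == "archie") M),
              class = "archie_metrics")
  })
}

#' Empirical power to detect network genes, per gene set
#'
#' Per replicate, a gene counts as detected by pairwise mapping when any of
#' its variant-pair p-values is below `alpha_pairwise`, and by ARCHIE when it
#' carries a non-zero loading in a component whose global-null p-value is
#' below `alpha_archie`.  Power is reported per gene set (the layers of the
#' preset network) and method.  The two levels should be calibrated to a
#' common type-I benchmark (see [estimate_type1()]).
#'
#' @param preset `"sparse"`, `"dense"` or `"master_regulator"`.
#' @param reps number of replicates.
#' @param n cohort size.
#' @param alpha_archie level for the ARCHIE component test.
#' @param alpha_pairwise level for the per-pair test.
#' @param K components extracted.
#' @param M global-null resamples (default `ceiling(10 / alpha_archie)`).
#' @param n_ref reference cohort size.
#' @param n_snps SNPs (multiple of 5).
#' @param cfg [scca_config()].
#' @param seed RNG seed.
#' @return An `archie_metrics` list with `$power_by_gene_set` (gene set x
#'   method table), `$power_by_gene`, and the per-replicate detection arrays
#'   (`$detect_archie`, `$detect_pairwise`).
#' @export
estimate_power <- function(preset = c("sparse", "dense", "master_regulator"),
                           reps, n, alpha_archie = 9e-4, alpha_pairwise = 1e-6,
                           K = 3L, M = NULL, n_ref = 700L, n_snps = 40L,
                           cfg = NULL, seed = NULL) {
  preset <- match.arg(preset)
  if (reps < 1L) archie_abort("reps must be >= 1", "archie_bad_argument")
  M <- M %||% ceiling(10 / alpha_archie)
  with_seed(seed, {
    net <- calibrate_effects(build_network(preset, n_snps = n_snps))
    genes <- net$downstream
    setup <- archie_harness_setup(net, K, M, cfg, n_ref)
    det_a <- det_p <- matrix(FALSE, reps, length(genes),
                             dimnames = list(NULL, genes))
    for (r in seq_len(reps)) {
      rep_out <- archie_rep_pvalues(net, n, setup, K)
      det_p[r, ] <- apply(rep_out$sm$P, 2L, min) < alpha_pairwise
      L <- select_significant(rep_out$pv, alpha_archie)
      if (L >= 1L) {
        # refit to recover loadings for the significant ranks
        fit <- fit_components(rep_out$Wm, K,
                              cfg = scca_config(setup$budgets$c_u,
                                                setup$budgets$c_v))
        sel <- unique(unlist(lapply(fit$components[seq_len(L)][
          which(rep_out$pv[seq_len(L)] < alpha_archie)],
          function(cm) cm$selected_genes)))
        det_a[r, sel] <- TRUE
      }
    }
    per_gene <- rbind(archie = colMeans(det_a), pairwise = colMeans(det_p))
    per_set <- vapply(net$layers, function(gs) {
      c(archie = mean(det_a[, gs, drop = FALSE]),
        pairwise = mean(det_p[, gs, drop = FALSE]))
    }, numeric(2))
    structure(list(power_by_gene_set = t(per_set), power_by_gene = per_gene,
                   detect_archie = det_a, detect_pairwise = det_p,
                   layers = net$layers, reps = reps, n = n, preset = preset,
                   alpha_archie = alpha_archie, alpha_pairwise = alpha_pairwise,
                   M = M),
              class = "archie_metrics")
  })
}

#' @export
print.archie_metrics <- function(x, ...) {
  cat("archie_metrics\n")
  if (!is.null(x$type1)) {
    cat(sprintf("  %s type-I over %d reps:\n", x$method, x$reps))
    print(x$type1)
  }
  if (!is.null(x$power_by_gene_set)) {
    cat(sprintf("  power (%s preset, n = %d, %d reps):\n", x$preset, x$n, x$reps))
    print(round(x$power_by_gene_set, 3))
  }
  invisible(x)
}

#' Sensitivity and specificity of a gene selection
#'
#' @param selected selected gene ids (or indices).
#' @param truth truly associated gene ids; must be non-empty and a subset of
#'   `universe`.
#' @param universe all candidate gene ids.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
selection_metrics <- function(selected, truth, universe) {
  if (length(truth) == 0L) archie_abort("truth set is empty", "archie_bad_argument")
  if (!all(truth %in% universe)) {
    archie_abort("truth must be a subset of universe", "archie_bad_argument")
  }
  selected <- intersect(selected, universe)
  tn <- setdiff(universe, union(selected, truth))
  c(sensitivity = length(intersect(selected, truth)) / length(truth),
    specificity = length(tn) / length(setdiff(universe, truth)))
}
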