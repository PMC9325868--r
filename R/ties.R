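# Trans-imputed expression scores (TIES) and the heritability enrichment
# test.
#
# For individual k and target gene j,
#   TIES_jk = sum_i Z_ij x_ik / sqrt(2 m_i (1 - m_i))
# -- the MAF-standardized dosages weighted by the trans-eQTL Z scores.  A
# multi-gene regression of the phenotype on the G TIES columns yields a
# pseudo-r^2 interpreted as the trait variance channelled through the target
# genes; its significance is judged against resampled gene sets (or
# resampled traits).

#' Compute trans-imputed expression scores
#'
#' Exact evaluation of the TIES sum for every individual and target gene.
#' Missing dosages are mean-imputed to `2 * m_i` before the sum (which
#' preserves the score's linearity in the dosage matrix).
#'
#' @param Z p x G matrix of trans-eQTL Z scores (variants x target genes).
#' @param dosages n x p dosage matrix (0/1/2 or imputed dosages; `NA`
#'   allowed).
#' @param mafs length-p vector of minor allele frequencies, strictly inside
#'   (0, 1).
#' @return An object of class `ties_matrix`: `$scores` is n x G.
#' @export
compute_ties <- function(Z, dosages, mafs) {
  Z <- as.matrix(Z)
  dosages <- as.matrix(dosages)
  p <- nrow(Z)
  if (ncol(dosages) != p || length(mafs) != p) {
    archie_abort("dimensions disagree: Z is p x G, dosages n x p, mafs length p",
                 "archie_bad_argument")
  }
  if (any(mafs <= 0 | mafs >= 1)) {
    archie_abort(sprintf("maf must lie strictly in (0, 1); offender index %d",
                         which(mafs <= 0 | mafs >= 1)[1L]),
                 "archie_bad_argument")
  }
  if (anyNA(dosages)) {
    for (i in seq_len(p)) {
      miss <- is.na(dosages[, i])
      if (any(miss)) dosages[miss, i] <- 2 * mafs[i]
    }
  }
  scores <- dosages %*% (Z / sqrt(2 * mafs * (1 - mafs)))
  colnames(scores) <- colnames(Z)
  structure(list(scores = scores,
                 gene_ids = colnames(Z) %||% paste0("gene", seq_len(ncol(Z))),
                 variant_ids = rownames(Z) %||% paste0("variant", seq_len(p))),
            class = "ties_matrix")
}

#' @export
print.ties_matrix <- function(x, ...) {
  cat(sprintf("ties_matrix: %d individuals x %d target genes (from %d variants)\n",
              nrow(x$scores), ncol(x$scores), length(x$variant_ids)))
  invisible(x)
}

# fast pseudo-r2 used inside resampling loops; X without intercept column
pseudo_r2_fast <- function(X, y, family, pseudo = "mcfadden") {
  n <- length(y)
  if (family == "gaussian") {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    if (!fit$converged) {
      archie_abort("logistic fit did not converge (possible separation)",
                   "archie_fit_error")
    }
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
      archie_abort("fitted probabilities at the boundary: quasi-separation in logistic fit",
                   "archie_fit_error")
    }
    ll_full <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    pbar <- mean(y)
    ll_null <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
    if (pseudo == "mcfadden") {
      1 - ll_full / ll_null
    } else { # nagelkerke
      (1 - exp(2 * (ll_null - ll_full) / n)) / (1 - exp(2 * ll_null / n))
    }
  }
}

#' Multi-gene TIES regression
#'
#' Fits `g[E(y)] = beta_0 + sum_j beta_j TIES_j`: ordinary least squares for
#' a continuous phenotype (pseudo-r^2 is the coefficient of determination)
#' or logistic maximum likelihood for a binary one (pseudo-r^2 is McFadden's
#' `1 - logL_full / logL_null` by default; Nagelkerke available).
#'
#' @param ties a [compute_ties()] result (or a plain score matrix).
#' @param phenotype numeric vector; binary 0/1 for `family = "binomial"`.
#' @param family `"gaussian"` or `"binomial"` (default: `"binomial"` when the
#'   phenotype only takes values 0 and 1).
#' @param pseudo_r2 `"mcfadden"` or `"nagelkerke"` (binomial only).
#' @return List with `pseudo_r2`, `coefficients` (intercept first) and
#'   `family`.
#' @export
fit_ties_regression <- function(ties, phenotype,
                                family = NULL,
                                pseudo_r2 = c("mcfadden", "nagelkerke")) {
  pseudo_r2 <- match.arg(pseudo_r2)
  X <- if (inherits(ties, "ties_matrix")) ties$scores else as.matrix(ties)
  y <- as.numeric(phenotype)
  n <- nrow(X); G <- ncol(X)
  if (length(y) != n) archie_abort("phenotype length mismatch", "archie_bad_argument")
  family <- family %||% (if (all(y %in% c(0, 1))) "binomial" else "gaussian")
  if (!family %in% c("gaussian", "binomial")) {
    archie_abort("family must be 'gaussian' or 'binomial'", "archie_bad_argument")
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    archie_abort("binomial family requires a 0/1 phenotype", "archie_bad_argument")
  }
  if (n <= G + 1L) {
    archie_abort("need n > G + 1 observations for the multi-gene regression",
                 "archie_bad_argument")
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    archie_abort(sprintf("constant TIES column: %s",
                         (colnames(X) %||% as.character(seq_len(G)))[which(sds == 0)[1L]]),
                 "archie_bad_argument")
  }
  if (qr(cbind(1, X))$rank < G + 1L) {
    archie_abort("rank-deficient TIES design matrix", "archie_bad_argument")
  }
  design <- cbind(`(Intercept)` = 1, X)
  if (family == "gaussian") {
    fit <- stats::lm.fit(design, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    list(pseudo_r2 = r2, coefficients = fit$coefficients, family = family)
  } else {
    r2 <- pseudo_r2_fast(X, y, "binomial", pseudo_r2)
    fit <- suppressWarnings(stats::glm.fit(design, y, family = stats::binomial()))
    list(pseudo_r2 = r2, coefficients = fit$coefficients, family = family)
  }
}

#' Resampling test for heritability enrichment of the target genes
#'
#' The observed pseudo-r^2 comes from regressing the phenotype on the TIES of
#' the target genes.  The null distribution is built by `B` resamples: with
#' `mode = "random_genes"`, the same number of genes is redrawn from the pool
#' (which must exclude the targets) and the regression repeated; with
#' `mode = "random_trait"`, the target genes are kept and the phenotype is
#' replaced by a draw from `null_phenotypes`.  The p-value is the plain
#' exceedance proportion `#(null >= observed) / B` (add-one correction
#' optional).
#'
#' @param target_Z p x G Z-score matrix for the target genes.
#' @param pool_Z p x G_pool Z-score matrix for the null gene pool (same
#'   variants, target genes excluded).
#' @param dosages n x p dosage matrix for the independent cohort.
#' @param mafs length-p allele frequencies.
#' @param phenotype length-n phenotype vector.
#' @param B number of resamples.
#' @param mode `"random_genes"` or `"random_trait"`.
#' @param null_phenotypes n x (>= 1) matrix of replacement phenotypes
#'   (required for `mode = "random_trait"`); columns are sampled with
#'   replacement.
#' @param family,pseudo_r2 passed to [fit_ties_regression()].
#' @param add_one use the `(1 + count) / (1 + B)` estimator.
#' @param seed RNG seed.
#' @return An object of class `archie_enrichment` with `observed_r2`,
#'   `coefficients`, `null_r2`, `p_value`, `mode`, `seed`.
#' @export
enrichment_test <- function(target_Z, pool_Z, dosages, mafs, phenotype,
                            B = 1000L, mode = c("random_genes", "random_trait"),
                            null_phenotypes = NULL, family = NULL,
                            pseudo_r2 = c("mcfadden", "nagelkerke"),
                            add_one = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  pseudo_r2 <- match.arg(pseudo_r2)
  target_Z <- as.matrix(target_Z); pool_Z <- as.matrix(pool_Z)
  if (B < 1L) archie_abort("B must be >= 1", "archie_bad_argument")
  G <- ncol(target_Z)
  if (mode == "random_genes" && ncol(pool_Z) < G) {
    archie_abort(sprintf("gene pool (%d) smaller than target set (%d)",
                         ncol(pool_Z), G), "archie_bad_argument")
  }
  overlap <- intersect(colnames(target_Z), colnames(pool_Z))
  if (length(overlap)) {
    archie_abort(sprintf("pool must exclude target genes (found %s)",
                         overlap[1L]), "archie_bad_argument")
  }
  if (mode == "random_trait") {
    if (is.null(null_phenotypes) || ncol(as.matrix(null_phenotypes)) < 1L) {
      archie_abort("random_trait mode requires a non-empty null_phenotypes collection",
                   "archie_bad_argument")
    }
    null_phenotypes <- as.matrix(null_phenotypes)
  }
  y <- as.numeric(phenotype)
  family <- family %||% (if (all(y %in% c(0, 1))) "binomial" else "gaussian")

  obs_fit <- fit_ties_regression(compute_ties(target_Z, dosages, mafs), y,
                                 family = family, pseudo_r2 = pseudo_r2)
  # TIES is linear in Z, so all pool scores can be precomputed at once
  pool_scores <- compute_ties(pool_Z, dosages, mafs)$scores
  target_scores <- compute_ties(target_Z, dosages, mafs)$scores
  with_seed(seed, {
    null_r2 <- vapply(seq_len(B), function(b) {
      if (mode == "random_genes") {
        cols <- sample(ncol(pool_scores), G)
        pseudo_r2_fast(pool_scores[, cols, drop = FALSE], y, family, pseudo_r2)
      } else {
        yb <- null_phenotypes[, sample(ncol(null_phenotypes), 1L)]
        pseudo_r2_fast(target_scores, as.numeric(yb), family, pseudo_r2)
      }
    }, numeric(1))
    count <- sum(null_r2 >= obs_fit$pseudo_r2)
    p <- if (add_one) (1 + count) / (1 + B) else count / B
    structure(list(observed_r2 = obs_fit$pseudo_r2,
                   coefficients = obs_fit$coefficients,
                   null_r2 = null_r2, p_value = p, B = B, mode = mode,
                   family = family, add_one = add_one, seed = seed),
              class = "archie_enrichment")
  })
}

#' @export
print.archie_enrichment <- function(x, ...) {
  cat(sprintf("archie_enrichment (%s, %s): observed pseudo-r2 = %.4f, p %s (B = %d)\n",
              x$mode, x$family, x$observed_r2,
              format_resampled_p(x$p_value, x$B), x$B))
  invisible(x)
}

#' Write an enrichment result to JSON (+ optional null-r2 audit TSV)
#'
#' @param x an `archie_enrichment`.
#' @param json_path output JSON path.
#' @param null_tsv optional one-column TSV of the null pseudo-r2 draws.
#' @return Invisibly, the paths written.
#' @export
write_enrichment <- function(x, json_path, null_tsv = NULL) {
  stopifnot(inherits(x, "archie_enrichment"))
  jsonlite::write_json(
    list(observed_r2 = x$observed_r2, p_value = x$p_value,
         p_display = format_resampled_p(x$p_value, x$B),
         B = x$B, mode = x$mode, family = x$family, seed = x$seed),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(null_tsv)) {
    data.table::fwrite(data.table::data.table(null_r2 = x$null_r2), null_tsv,
                       sep = "\t")
  }
  invisible(c(json = json_path, tsv = null_tsv))
}
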