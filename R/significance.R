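# Resampling significance for sparse CCA components.
#
# Two reference distributions are supported.  The competitive null rebuilds
# the summary matrix from variants associated with *other* traits (plus
# freshly sampled genes), so it represents the genome-wide background of
# trans-association that any set of GWAS variants carries; significance
# against it indicates trait-specific structure.  The global null draws
# cross-matrices with the correct within-variant (LD) and within-gene
# (co-expression) correlation but no variant-gene association:
# vec(Sigma_GE;null) ~ N(0, Sigma_EE (x) Sigma_GG).
#
# The per-rank p-value is the exceedance proportion: the fraction of null
# cc-values at that rank that reach or exceed the observed one.  (The
# opposite inequality -- the fraction of nulls the observation exceeds -- is
# available behind `printed_inequality` but is not a p-value: small values
# would then mean *weak* evidence, which is incoherent with the selection
# rule for L below.)

#' Draw a competitive null summary matrix
#'
#' Samples `p` variants from the pool, restricted to traits outside
#' `exclude_traits`; when the pool carries at least `p` distinct eligible
#' traits, one variant is drawn from each of `p` randomly chosen traits
#' (so no single trait dominates the null), otherwise remaining variants are
#' drawn uniformly from the eligible pool.  `g` genes are drawn uniformly
#' without replacement.  Returns the corresponding Z submatrix as a
#' [summary_matrix()].
#'
#' @param pool a [summary_matrix()] whose variant table carries
#'   `trait_label`s.
#' @param p number of variants to draw.
#' @param g number of genes to draw.
#' @param exclude_traits trait labels to exclude (the target trait, and any
#'   trait with substantial genetic correlation to it -- the caller decides).
#' @param seed RNG seed.
#' @return A `p x g` [summary_matrix()].
#' @export
build_competitive_null <- function(pool, p, g, exclude_traits = character(),
                                   seed = NULL) {
  stopifnot(inherits(pool, "summary_matrix"))
  labs <- pool$variants$trait_label
  eligible <- which(!(labs %in% exclude_traits))
  if (length(eligible) < p) {
    archie_abort(sprintf("competitive pool too small after exclusion: %d eligible variants, %d requested",
                         length(eligible), p), "archie_bad_argument")
  }
  if (ncol(pool$Z) < g) {
    archie_abort(sprintf("gene pool too small: %d genes, %d requested",
                         ncol(pool$Z), g), "archie_bad_argument")
  }
  with_seed(seed, {
    el_labs <- labs[eligible]
    traits <- unique(el_labs[!is.na(el_labs)])
    if (length(traits) >= p) {
      chosen_traits <- sample(traits, p)
      vi <- vapply(chosen_traits, function(tr) {
        cand <- eligible[!is.na(el_labs) & el_labs == tr]
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, integer(1))
    } else {
      # fewer traits than requested variants: draw uniformly, one per trait
      # first, then fill the remainder without replacement
      vi <- integer(0)
      for (tr in sample(traits)) {
        cand <- eligible[!is.na(el_labs) & el_labs == tr]
        vi <- c(vi, if (length(cand) == 1L) cand else sample(cand, 1L))
      }
      rest <- setdiff(eligible, vi)
      vi <- c(vi, sample(rest, p - length(vi)))[seq_len(p)]
    }
    gi <- sample(ncol(pool$Z), g)
    pool[vi, gi]
  })
}

#' Draw one global-null cross-matrix
#'
#' One `g x p` matrix whose row-stacked vectorization has covariance
#' `Sigma_EE (x) Sigma_GG`, realized as `A Ztilde B'` with `A = Sigma_EE^{1/2}`,
#' `B = Sigma_GG^{1/2}` and `Ztilde` iid standard normal.
#'
#' @param coexpr [correlation_matrix()] for the genes (Sigma_EE).
#' @param ld [correlation_matrix()] for the variants (Sigma_GG).
#' @param seed RNG seed.
#' @return A `g x p` numeric matrix.
#' @export
sample_global_null <- function(coexpr, ld, seed = NULL) {
  stopifnot(inherits(coexpr, "correlation_matrix"),
            inherits(ld, "correlation_matrix"))
  A <- matrix_sqrt(coexpr)
  B <- matrix_sqrt(ld)
  g <- nrow(A); p <- nrow(B)
  with_seed(seed, A %*% matrix(rnorm(g * p), g, p) %*% t(B))
}

new_null_ensemble <- function(null_q2, kind, seed) {
  null_q2 <- as.matrix(null_q2)
  if (any(null_q2 < 0 | null_q2 > 1)) {
    archie_abort("null cc-values outside [0, 1]", "archie_bad_argument")
  }
  structure(list(M = nrow(null_q2), K = ncol(null_q2), null_q2 = null_q2,
                 kind = kind, seed = seed),
            class = "archie_null_ensemble")
}

#' @export
print.archie_null_ensemble <- function(x, ...) {
  cat(sprintf("archie_null_ensemble (%s): M = %d resamples x K = %d ranks\n",
              x$kind, x$M, x$K))
  invisible(x)
}

#' Build a competitive null ensemble of cc-values
#'
#' Repeats [build_competitive_null()] `M` times; each draw is analyzed with
#' the same sparsity budgets as the observed analysis and its first `K`
#' cc-values recorded.  When genome-wide `ld` / `coexpr` estimates are
#' supplied, the per-draw submatrices are used to whiten each null matrix;
#' otherwise identity matrices are used (appropriate when the pool's
#' variants/genes are approximately uncorrelated, as in the bundled
#' simulations).
#'
#' @inheritParams build_competitive_null
#' @param K number of component ranks to record.
#' @param M number of resamples.
#' @param cfg [scca_config()] -- must carry the same budgets as the observed
#'   analysis.
#' @param ld,coexpr optional genome-wide [correlation_matrix()] objects
#'   covering the pool's variants and genes.
#' @param map Z-to-correlation map used for the null matrices.
#' @return An `archie_null_ensemble`.
#' @export
null_ensemble_competitive <- function(pool, p, g, K, M, cfg = NULL,
                                      exclude_traits = character(),
                                      ld = NULL, coexpr = NULL,
                                      map = "identity", seed = NULL) {
  stopifnot(M >= 1L)
  b <- resolve_budgets(cfg, p, g)
  with_seed(seed, {
    q2 <- matrix(NA_real_, M, K)
    for (m in seq_len(M)) {
      nm <- build_competitive_null(pool, p, g, exclude_traits)
      if (is.null(ld) && is.null(coexpr)) {
        Wm <- t(z_to_cor(nm$Z, nm$n_study, map))
      } else {
        ld_m <- if (is.null(ld)) {
          correlation_matrix(diag(p), ids = nm$variants$variant_id)
        } else subset_correlation(ld, nm$variants$variant_id)
        co_m <- if (is.null(coexpr)) {
          correlation_matrix(diag(g), ids = nm$genes$gene_id)
        } else subset_correlation(coexpr, nm$genes$gene_id)
        Wm <- build_w(nm, ld_m, co_m, map = map)$values
      }
      q2[m, ] <- scca_q2_seq(Wm, K, b$c_u, b$c_v, b$max_iter, b$tol)
    }
    new_null_ensemble(q2, "competitive", seed)
  })
}

#' Build a global null ensemble of cc-values
#'
#' Draws `M` matrices with `vec` covariance `Sigma_EE (x) Sigma_GG` and
#' records the first `K` cc-values of each under the observed sparsity
#' budgets.  Each draw is passed through the same whitening step as the
#' observed analysis (`W = Sigma_EE^{-1/2} Sigma_GE Sigma_GG^{-1/2}`, using
#' the same estimated matrices that generated it), so a null draw reduces to
#' an exactly whitened matrix.  The observed matrix, in contrast, is whitened
#' with *estimated* reference matrices that differ from the truth, so it
#' retains residual correlation structure -- and residual structure lowers
#' cc-values (the q2 normalization penalizes correlated rows/columns).  The
#' null cc-values therefore tend to dominate the observed ones under the
#' global null, making the test conservative.
#'
#' @inheritParams sample_global_null
#' @param K number of component ranks to record.
#' @param M number of draws.
#' @param cfg [scca_config()] with the observed analysis' budgets.
#' @return An `archie_null_ensemble`.
#' @export
null_ensemble_global <- function(coexpr, ld, K, M, cfg = NULL, seed = NULL) {
  stopifnot(M >= 1L)
  A <- matrix_sqrt(coexpr)
  B <- matrix_sqrt(ld)
  # same whitening step the observed matrix goes through
  iA <- inverse_sqrt(coexpr)
  iB <- inverse_sqrt(ld)
  wA <- iA %*% A # identity up to the eigenvalue floor
  wB <- B %*% iB
  g <- nrow(A); p <- nrow(B)
  b <- resolve_budgets(cfg, p, g)
  with_seed(seed, {
    q2 <- matrix(NA_real_, M, K)
    for (m in seq_len(M)) {
      Wn <- wA %*% matrix(rnorm(g * p), g, p) %*% wB
      q2[m, ] <- scca_q2_seq(Wn, K, b$c_u, b$c_v, b$max_iter, b$tol)
    }
    new_null_ensemble(q2, "global", seed)
  })
}

#' Resampling p-values for observed cc-values
#'
#' `p_k` is the proportion of null cc-values at rank `k` that reach or exceed
#' the observed `q2_k`.  A zero is reported as `< 1/M` in printed output; the
#' optional add-one correction `(1 + count) / (1 + M)` guarantees strictly
#' positive p-values but is off by default to match the plain resampling
#' estimator.
#'
#' @param observed_q2 numeric vector of observed cc-values (length K).
#' @param nulls an `archie_null_ensemble` with at least K ranks.
#' @param add_one use the add-one correction.
#' @param printed_inequality if `TRUE`, compute the reversed proportion (the
#'   fraction of nulls the observation exceeds) instead; this is *not* a
#'   p-value and is provided only for comparison.
#' @return An object of class `archie_significance` with `$p_values`, `$M`,
#'   `$K`.
#' @export
component_pvalues <- function(observed_q2, nulls, add_one = FALSE,
                              printed_inequality = FALSE) {
  stopifnot(inherits(nulls, "archie_null_ensemble"))
  K <- length(observed_q2)
  if (nulls$K < K) {
    archie_abort(sprintf("null ensemble has %d ranks, %d observed components",
                         nulls$K, K), "archie_bad_argument")
  }
  M <- nulls$M
  pv <- vapply(seq_len(K), function(k) {
    if (printed_inequality) {
      mean(observed_q2[k] > nulls$null_q2[, k])
    } else if (add_one) {
      (1 + sum(nulls$null_q2[, k] >= observed_q2[k])) / (1 + M)
    } else {
      mean(nulls$null_q2[, k] >= observed_q2[k])
    }
  }, numeric(1))
  structure(list(p_values = pv, M = M, K = K,
                 add_one = add_one, printed_inequality = printed_inequality),
            class = "archie_significance")
}

#' @export
print.archie_significance <- function(x, ...) {
  cat(sprintf("archie_significance: %d components, M = %d resamples\n", x$K, x$M))
  cat("  p-values:", paste(format_resampled_p(x$p_values, x$M), collapse = ", "), "\n")
  invisible(x)
}

#' Number of significant leading components
#'
#' `L = min{k : p_k > alpha} - 1`: components are accepted in rank order
#' until the first non-significant one.  When every p-value is `<= alpha`,
#' all `K` extracted components are significant (`L = K`).
#'
#' @param result an `archie_significance` or a plain p-value vector.
#' @param alpha significance level.
#' @return Integer `L`, `0 <= L <= K`.
#' @export
select_significant <- function(result, alpha) {
  pv <- if (inherits(result, "archie_significance")) result$p_values else result
  idx <- which(pv > alpha)
  if (length(idx) == 0L) length(pv) else idx[1L] - 1L
}

#' Trait-specificity resampling experiment
#'
#' Assembles summary matrices in which a proportion `delta` of the `p`
#' variants come from the target trait's pool and the rest from other traits,
#' runs the full component extraction plus competitive-null test on each, and
#' returns the fraction of replicates with at least one significant
#' component.  At `delta = 0` this estimates the competitive type-I error; at
#' `delta = 1` the power for a fully trait-specific variant set.
#'
#' @param trait_pool [summary_matrix()] of the target trait's variants.
#' @param other_pool [summary_matrix()] of other-trait variants (with
#'   `trait_label`s), sharing `trait_pool`'s gene set.
#' @param delta proportion of trait-specific variants in `[0, 1]`.
#' @param p,g dimensions of each assembled matrix.
#' @param reps number of replicates (>= 1).
#' @param M competitive resamples per replicate.
#' @param alpha significance level.
#' @param K components extracted per matrix.
#' @param cfg [scca_config()] shared by observed and null fits.
#' @param seed RNG seed.
#' @return The fraction of replicates with `L >= 1`, with attribute
#'   `"per_rep"` (logical vector).
#' @export
trait_specificity_experiment <- function(trait_pool, other_pool, delta, p, g,
                                         reps, M = 99L, alpha = 0.05, K = 2L,
                                         cfg = NULL, seed = NULL) {
  stopifnot(inherits(trait_pool, "summary_matrix"),
            inherits(other_pool, "summary_matrix"))
  if (reps < 1L) archie_abort("reps must be >= 1", "archie_bad_argument")
  if (delta < 0 || delta > 1) archie_abort("delta must lie in [0, 1]", "archie_bad_argument")
  gene_ids <- intersect(trait_pool$genes$gene_id, other_pool$genes$gene_id)
  if (length(gene_ids) < g) {
    archie_abort("shared gene set smaller than g", "archie_bad_argument")
  }
  n_trait <- ceiling(delta * p)
  if (nrow(trait_pool$Z) < n_trait) {
    archie_abort("trait pool smaller than delta * p", "archie_bad_argument")
  }
  b <- resolve_budgets(cfg, p, g)
  with_seed(seed, {
    hits <- logical(reps)
    for (r in seq_len(reps)) {
      gsel <- sample(gene_ids, g)
      rows <- NULL
      if (n_trait > 0L) {
        vi <- sample(nrow(trait_pool$Z), n_trait)
        rows <- trait_pool$Z[vi, gsel, drop = FALSE]
      }
      if (n_trait < p) {
        # competitive sampling picks the background variants; their
        # statistics are taken at the same sampled gene set
        bg <- build_competitive_null(other_pool, p - n_trait, 1L)
        rows <- rbind(rows, other_pool$Z[rownames(bg$Z), gsel, drop = FALSE])
      }
      Wobs <- t(rows)
      obs_q2 <- scca_q2_seq(Wobs, K, b$c_u, b$c_v, b$max_iter, b$tol)
      nulls <- null_ensemble_competitive(other_pool, p, g, K, M,
                                         cfg = scca_config(b$c_u, b$c_v,
                                                           b$max_iter, b$tol))
      pv <- component_pvalues(obs_q2, nulls)
      hits[r] <- select_significant(pv, alpha) >= 1L
    }
    structure(mean(hits), per_rep = hits)
  })
}

#' Write a null ensemble and significance report to disk
#'
#' The ensemble is persisted as a TSV grid (resample x rank) and the
#' significance report as JSON.
#'
#' @param nulls an `archie_null_ensemble` (or `NULL` to skip).
#' @param result an `archie_significance` (or `NULL` to skip).
#' @param alpha level used for the reported `L`.
#' @param tsv_path,json_path output paths.
#' @return Invisibly, the paths written.
#' @export
write_significance <- function(nulls = NULL, result = NULL, alpha = 0.05,
                               tsv_path = NULL, json_path = NULL) {
  if (!is.null(nulls) && !is.null(tsv_path)) {
    grid <- data.table::as.data.table(nulls$null_q2)
    data.table::setnames(grid, paste0("rank", seq_len(nulls$K)))
    data.table::fwrite(grid, tsv_path, sep = "\t")
  }
  if (!is.null(result) && !is.null(json_path)) {
    jsonlite::write_json(
      list(p_values = result$p_values,
           p_display = format_resampled_p(result$p_values, result$M),
           alpha = alpha,
           L = select_significant(result, alpha),
           M = result$M,
           seed = if (!is.null(nulls)) nulls$seed),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
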