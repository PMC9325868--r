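# Reference correlation matrices and the adjusted cross-matrix W.
#
# The sparse CCA operates on W = Sigma_EE^{-1/2} Sigma_GE Sigma_GG^{-1/2},
# where Sigma_GG is the LD matrix of the variants (reference genotypes),
# Sigma_EE the (penalized) co-expression matrix of the genes (reference
# expression), and Sigma_GE the cross-correlation implied by the trans-eQTL
# Z scores.  Orientation is fixed package-wide: W has genes in rows and
# variants in columns, so that v' W u is well-formed.

#' Construct a correlation matrix object
#'
#' Validates symmetry (1e-10), a unit diagonal (1e-10) and near positive
#' semi-definiteness (smallest eigenvalue >= -1e-8 before flooring).  The
#' `eigen_floor` is the relative floor applied when the matrix is inverted or
#' square-rooted: eigenvalues below `eigen_floor * lambda_max` are raised to
#' that level, bounding the condition number of the effective matrix by
#' `1 / eigen_floor`.
#'
#' @param values symmetric numeric matrix with unit diagonal.
#' @param ids ordered ids for rows/columns (default: dimnames).
#' @param shrinkage shrinkage weight toward the identity that produced
#'   `values` (recorded for provenance).
#' @param eigen_floor relative eigenvalue floor used by [inverse_sqrt()].
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(values, ids = NULL, shrinkage = 0,
                               eigen_floor = 1e-6) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) archie_abort("matrix not square", "archie_bad_argument")
  if (max(abs(values - t(values))) > 1e-10) {
    archie_abort("matrix not symmetric to 1e-10", "archie_bad_argument")
  }
  if (max(abs(diag(values) - 1)) > 1e-10) {
    archie_abort("diagonal not 1 to 1e-10", "archie_bad_argument")
  }
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    archie_abort(sprintf("matrix not PSD: smallest eigenvalue %.3g", min(ev)),
                 "archie_bad_argument")
  }
  ids <- ids %||% rownames(values) %||% paste0("id", seq_len(n))
  dimnames(values) <- list(ids, ids)
  structure(
    list(values = values, ids = ids, shrinkage = shrinkage,
         eigen_floor = eigen_floor),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d x %d, shrinkage = %.3g, eigen floor = %.1g\n",
              nrow(x$values), ncol(x$values), x$shrinkage, x$eigen_floor))
  invisible(x)
}

#' @export
dim.correlation_matrix <- function(x) dim(x$values)

#' Subset a correlation matrix by id
#'
#' @param C a [correlation_matrix()].
#' @param ids ids (or integer indices) to keep, in the requested order.
#' @return A [correlation_matrix()] over the requested ids.
#' @export
subset_correlation <- function(C, ids) {
  stopifnot(inherits(C, "correlation_matrix"))
  idx <- if (is.character(ids)) match(ids, C$ids) else as.integer(ids)
  if (anyNA(idx)) {
    archie_abort(sprintf("unknown id in subset: %s",
                         ids[which(is.na(idx))[1L]]), "archie_bad_argument")
  }
  correlation_matrix(C$values[idx, idx, drop = FALSE], ids = C$ids[idx],
                     shrinkage = C$shrinkage, eigen_floor = C$eigen_floor)
}

check_no_constant <- function(mat, what) {
  sds <- apply(mat, 2L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(mat)[bad[1L]] %||% as.character(bad[1L])
    archie_abort(sprintf("constant %s column: %s", what, nm), "archie_bad_argument")
  }
  invisible(NULL)
}

#' Estimate an LD matrix from reference dosages
#'
#' Pearson correlation of the dosage columns, linearly shrunk toward the
#' identity: `(1 - lambda) * S + lambda * I`.  The default is the empirical
#' matrix (`shrinkage = 0`), appropriate when the variant count is small
#' relative to the reference sample size.
#'
#' @param dosages numeric matrix, reference samples in rows, variants in
#'   columns (column names are the variant ids).
#' @param shrinkage shrinkage weight lambda in `[0, 1]`.
#' @param eigen_floor relative eigenvalue floor recorded for inversion.
#' @return A [correlation_matrix()].
#' @export
estimate_ld <- function(dosages, shrinkage = 0, eigen_floor = 1e-6) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) {
    archie_abort("need at least 2 reference samples", "archie_bad_argument")
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  check_no_constant(dosages, "variant")
  S <- stats::cor(dosages)
  C <- (1 - shrinkage) * S + shrinkage * diag(ncol(S))
  correlation_matrix(C, ids = colnames(dosages), shrinkage = shrinkage,
                     eigen_floor = eigen_floor)
}

#' Estimate a penalized co-expression matrix from reference expression
#'
#' Column-wise Pearson correlation of the reference expression matrix, shrunk
#' toward the identity.  With `method = "fixed"` the shrinkage weight is
#' `shrinkage` (default 0.1); with `method = "ledoit_wolf"` a data-driven
#' plug-in weight is estimated from the sampling variance of the individual
#' correlations (Schafer-Strimmer style) and recorded in the result.  Because
#' reference panels are usually smaller than the gene count, the raw
#' co-expression matrix is rank-deficient; the shrinkage plus the eigenvalue
#' floor keep its inverse square root well conditioned.
#'
#' @param expression numeric matrix, reference samples in rows, genes in
#'   columns (column names are the gene ids).
#' @param shrinkage fixed shrinkage weight (ignored for `"ledoit_wolf"`).
#' @param method `"fixed"` or `"ledoit_wolf"`.
#' @param quantile_normalize if `TRUE`, each gene is rank transformed to
#'   standard normal quantiles before correlation (ties broken by average
#'   rank), mirroring quantile-normalized reference expression.
#' @param eigen_floor relative eigenvalue floor recorded for inversion.
#' @return A [correlation_matrix()]; the shrinkage actually used is in
#'   `$shrinkage`.
#' @export
estimate_coexpression <- function(expression, shrinkage = 0.1,
                                  method = c("fixed", "ledoit_wolf"),
                                  quantile_normalize = FALSE,
                                  eigen_floor = 1e-6) {
  method <- match.arg(method)
  expression <- as.matrix(expression)
  n <- nrow(expression)
  if (n < 2L) archie_abort("need at least 2 reference samples", "archie_bad_argument")
  check_no_constant(expression, "gene")
  if (quantile_normalize) {
    expression <- apply(expression, 2L, function(x) {
      stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
    })
  }
  S <- stats::cor(expression)
  if (method == "ledoit_wolf") {
    shrinkage <- ledoit_wolf_lambda(expression)
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  C <- (1 - shrinkage) * S + shrinkage * diag(ncol(S))
  correlation_matrix(C, ids = colnames(expression), shrinkage = shrinkage,
                     eigen_floor = eigen_floor)
}

# Plug-in shrinkage intensity toward the identity for a correlation matrix:
# lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2, truncated to [0, 1].
# Var-hat(r_ij) is the empirical variance of the per-sample products of
# standardized residuals (Schafer & Strimmer 2005).
ledoit_wolf_lambda <- function(expression) {
  n <- nrow(expression)
  Xs <- scale(expression) # unit sd, denominator n - 1
  R <- crossprod(Xs) / (n - 1)
  W2 <- crossprod(Xs^2) # sum_k w_kij^2 with w_kij = xs_ki * xs_kj
  wbar <- (n - 1) / n * R
  varR <- n / (n - 1)^3 * (W2 - n * wbar^2)
  off <- upper.tri(R)
  lam <- sum(varR[off]) / sum(R[off]^2)
  min(1, max(0, lam))
}

#' Symmetric inverse square root with an eigenvalue floor
#'
#' Eigendecomposes a symmetric matrix, floors the eigenvalues at
#' `eigen_floor * lambda_max`, and returns `U diag(1/sqrt(lambda)) U'`.  The
#' floor guarantees the effective matrix has condition number at most
#' `1 / eigen_floor`, which is what makes rank-deficient reference
#' co-expression matrices usable.
#'
#' @param C a [correlation_matrix()] or a plain symmetric matrix.
#' @param eigen_floor relative floor; defaults to the value stored in `C`
#'   (or 1e-6 for a plain matrix).
#' @return A symmetric matrix, the floored inverse square root.
#' @export
inverse_sqrt <- function(C, eigen_floor = NULL) {
  V <- if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
  eigen_floor <- eigen_floor %||%
    (if (inherits(C, "correlation_matrix")) C$eigen_floor else 1e-6)
  if (max(abs(V - t(V))) > 1e-8) {
    archie_abort("matrix not symmetric", "archie_bad_argument")
  }
  e <- eigen(V, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) {
    archie_abort("all eigenvalues are non-positive", "archie_bad_argument")
  }
  lam <- pmax(e$values, eigen_floor * lmax)
  out <- e$vectors %*% (t(e$vectors) / sqrt(lam))
  (out + t(out)) / 2
}

# symmetric square root with the same flooring convention
matrix_sqrt <- function(C, eigen_floor = NULL) {
  V <- if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
  eigen_floor <- eigen_floor %||%
    (if (inherits(C, "correlation_matrix")) C$eigen_floor else 1e-6)
  e <- eigen(V, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) archie_abort("all eigenvalues are non-positive", "archie_bad_argument")
  lam <- pmax(e$values, eigen_floor * lmax)
  out <- e$vectors %*% (t(e$vectors) * sqrt(lam))
  (out + t(out)) / 2
}

#' Map Z scores to implied cross-correlations
#'
#' The `"t"` map, `r = Z / sqrt(n - 2 + Z^2)`, inverts the t-to-r transform
#' of simple regression exactly.  The `"linear"` map is `Z / sqrt(n)`
#' (adequate for small |Z|).  `"identity"` passes Z through unchanged --
#' useful in simulation settings where only the relative structure matters
#' (the canonical correlations downstream are scale invariant).
#'
#' @param Z numeric matrix of Z scores.
#' @param n_study eQTL study sample size (unused by `"identity"`).
#' @param map one of `"t"`, `"linear"`, `"identity"`.
#' @return Matrix of the same shape as `Z`.
#' @export
z_to_cor <- function(Z, n_study, map = c("t", "linear", "identity")) {
  map <- match.arg(map)
  if (map == "identity") return(Z)
  if (!is_scalar_number(n_study) || n_study < 3) {
    archie_abort("n_study required (>= 3) for the t/linear Z-to-correlation maps",
                 "archie_bad_argument")
  }
  switch(map,
         t = Z / sqrt(n_study - 2 + Z^2),
         linear = Z / sqrt(n_study))
}

#' Assemble the correlation-adjusted cross-matrix W
#'
#' Forms the cross-correlation matrix from the summary Z scores (via
#' [z_to_cor()]), then whitens both sides:
#' `W = Sigma_EE^{-1/2} Sigma_GE Sigma_GG^{-1/2}`, with genes in rows and
#' variants in columns.  The id orderings of `ld` and `coexpr` must match the
#' summary's variant and gene order exactly.
#'
#' @param summary a [summary_matrix()].
#' @param ld [correlation_matrix()] over the summary's variants (LD).
#' @param coexpr [correlation_matrix()] over the summary's genes
#'   (co-expression).
#' @param map Z-to-correlation map, see [z_to_cor()].
#' @return An object of class `adjusted_matrix`: `$values` is the g x p
#'   matrix W, `$provenance` records ids, shrinkages, floors and the map used.
#' @export
build_w <- function(summary, ld, coexpr, map = c("t", "linear", "identity")) {
  map <- match.arg(map)
  stopifnot(inherits(summary, "summary_matrix"),
            inherits(ld, "correlation_matrix"),
            inherits(coexpr, "correlation_matrix"))
  vids <- summary$variants$variant_id
  gids <- summary$genes$gene_id
  if (!identical(ld$ids, vids)) {
    off <- which(ld$ids != vids | is.na(ld$ids) | is.na(vids))[1L] %||% 1L
    archie_abort(sprintf("LD ids do not match summary variant order (first offender: %s)",
                         ld$ids[off] %||% "<length mismatch>"), "archie_bad_argument")
  }
  if (!identical(coexpr$ids, gids)) {
    off <- which(coexpr$ids != gids | is.na(coexpr$ids) | is.na(gids))[1L] %||% 1L
    archie_abort(sprintf("co-expression ids do not match summary gene order (first offender: %s)",
                         coexpr$ids[off] %||% "<length mismatch>"), "archie_bad_argument")
  }
  sigma_ge <- t(z_to_cor(summary$Z, summary$n_study, map)) # genes x variants
  W <- inverse_sqrt(coexpr) %*% sigma_ge %*% inverse_sqrt(ld)
  dimnames(W) <- list(gids, vids)
  structure(
    list(values = W,
         provenance = list(
           variant_ids = vids, gene_ids = gids,
           shrinkage_ld = ld$shrinkage, shrinkage_coexpr = coexpr$shrinkage,
           eigen_floor_ld = ld$eigen_floor, eigen_floor_coexpr = coexpr$eigen_floor,
           z_map = map, n_study = summary$n_study)),
    class = "adjusted_matrix"
  )
}

#' @export
print.adjusted_matrix <- function(x, ...) {
  cat(sprintf("adjusted_matrix W: %d genes x %d variants (z map: %s)\n",
              nrow(x$values), ncol(x$values), x$provenance$z_map))
  invisible(x)
}

#' @export
dim.adjusted_matrix <- function(x) dim(x$values)

# coerce matrix-like inputs for the sCCA layer
as_w_matrix <- function(W) {
  if (inherits(W, "adjusted_matrix")) W$values else as.matrix(W)
}
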