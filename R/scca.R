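# Sparse canonical correlation core: penalized matrix decomposition of W.
#
# One component solves
#   max v' W u   s.t.  ||u||_2 = ||v||_2 = 1, ||u||_1 <= c_u, ||v||_1 <= c_v
# by alternating soft-thresholded power iterations (the standard penalized
# matrix decomposition scheme): the u-update soft-thresholds W'v with the
# threshold chosen by bisection so the L1 budget binds, then renormalizes;
# symmetrically for v.  Initialization is the leading singular vector pair of
# W, so the fit is deterministic.  Later components come from rank-one
# deflation; every component's cc-value q^2 is computed against the original
# (undeflated) W.

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - delta, 0)` elementwise; realizes the L1 constraint in
#' the sparse CCA updates.
#'
#' @param x numeric vector.
#' @param delta non-negative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(x, delta) {
  if (delta < 0) archie_abort("delta must be non-negative", "archie_bad_argument")
  sign(x) * pmax(abs(x) - delta, 0)
}

#' Sparsity and convergence settings for the sparse CCA
#'
#' The L1 budgets must satisfy `1 <= c_u <= sqrt(p)` and `1 <= c_v <= sqrt(g)`
#' (the feasible range for a unit-L2 vector).  The defaults, applied when a
#' budget is `NULL`, interpolate 30% of the way from the sparsest to the
#' densest feasible budget: `c = 1 + 0.3 * (sqrt(dim) - 1)`.
#'
#' @param c_u L1 budget for the variant loadings (or `NULL` for the default).
#' @param c_v L1 budget for the gene loadings (or `NULL` for the default).
#' @param max_iter maximum alternating iterations.
#' @param tol convergence tolerance on the successive change in the objective
#'   `v' W u`.
#' @return An object of class `scca_config`.
#' @export
scca_config <- function(c_u = NULL, c_v = NULL, max_iter = 200L, tol = 1e-8) {
  stopifnot(max_iter >= 1L, tol > 0)
  structure(list(c_u = c_u, c_v = c_v, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "scca_config")
}

#' Default L1 budget for a loading vector of the given length
#'
#' @param d vector length (number of variants or genes).
#' @return `1 + 0.3 * (sqrt(d) - 1)`.
#' @export
default_sparsity <- function(d) 1 + 0.3 * (sqrt(d) - 1)

# Unit-L2 vector proportional to a soft-thresholded `a` with L1 norm <= c
# (+1e-9).  After normalization the L1 norm of soft(a, delta)/||soft(a,
# delta)||_2 is piecewise smooth in delta with breakpoints at the sorted
# magnitudes, so on the interval with support size k the binding threshold
# solves the quadratic
#   k (k - c^2) d^2 - 2 S (k - c^2) d + (S^2 - c^2 Q) = 0,
# where S and Q are the sum and sum of squares of the top-k magnitudes.  The
# exact root is used; with fully tied magnitudes the reachable L1 values jump
# over c, in which case the sparsest feasible fallback (a single coordinate,
# L1 = 1) is returned.  Returns NULL when `a` is identically zero.
l1_unit <- function(a, c) {
  nrm <- sqrt(sum(a * a))
  if (nrm == 0) return(NULL)
  u <- a / nrm
  if (sum(abs(u)) <= c + 1e-9) return(u)
  ab <- abs(a)
  m <- sort(ab, decreasing = TRUE)
  S <- cumsum(m)
  Q <- cumsum(m * m)
  p <- length(m)
  c2 <- c * c
  delta <- NA_real_
  for (k in seq_len(p)) {
    lo <- if (k < p) m[k + 1L] else 0
    hi <- m[k]
    if (hi <= lo) next # tied magnitudes: empty interval
    kc <- k - c2
    if (kc <= 1e-12) next # support too small: max reachable L1 is sqrt(k) <= c
    disc <- kc * (k * Q[k] - S[k]^2)
    if (disc < 0) next
    rt <- c * sqrt(disc)
    den <- k * kc
    for (cand in c((S[k] * kc - rt) / den, (S[k] * kc + rt) / den)) {
      if (cand >= lo - 1e-12 && cand < hi && S[k] - k * cand > 0) {
        delta <- cand
        break
      }
    }
    if (!is.na(delta)) break
  }
  if (is.na(delta)) {
    i <- which.max(ab)
    out <- numeric(p)
    out[i] <- sign(a[i])
    return(out)
  }
  s <- soft_threshold(a, delta)
  s / sqrt(sum(s * s))
}

# Minimal single-component fit used in resampling loops: no S3 wrapping, no
# validation.  Wm is a plain genes x variants matrix.
scca_fit_core <- function(Wm, c_u, c_v, max_iter = 200L, tol = 1e-8) {
  sv <- svd(Wm, nu = 1L, nv = 1L)
  v <- sv$u[, 1L]
  u <- sv$v[, 1L]
  obj_prev <- -Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    a <- drop(crossprod(Wm, v))
    u_new <- l1_unit(a, c_u)
    if (is.null(u_new)) {
      archie_abort("variant loadings vanished: W' v = 0 (sparsity budget too small or degenerate matrix)",
                   "archie_degenerate")
    }
    u <- u_new
    b <- drop(Wm %*% u)
    v_new <- l1_unit(b, c_v)
    if (is.null(v_new)) {
      archie_abort("gene loadings vanished: W u = 0 (sparsity budget too small or degenerate matrix)",
                   "archie_degenerate")
    }
    v <- v_new
    obj <- sum(v * b)
    if (abs(obj - obj_prev) < tol) { converged <- TRUE; break }
    obj_prev <- obj
  }
  # sign convention: largest-|loading| variant entry positive (ties: lowest
  # index, which is what which.max returns)
  i <- which.max(abs(u))
  if (u[i] < 0) { u <- -u; v <- -v }
  list(u = u, v = v, objective = sum(v * drop(Wm %*% u)),
       iterations = iters, converged = converged)
}

#' Canonical correlation value (cc-value) of a loading pair
#'
#' `q^2 = (v' W u)^2 / sqrt((u' W' W u)(v' W W' v))`, the normalized squared
#' bilinear form; bounded in `[0, 1]` by Cauchy-Schwarz.  When `W u = 0` or
#' `W' v = 0` the value is 0 and the result carries a `degenerate` attribute.
#'
#' @param W an `adjusted_matrix` or plain genes x variants matrix.
#' @param u variant loading vector (length = ncol(W)).
#' @param v gene loading vector (length = nrow(W)).
#' @return The cc-value, a number in `[0, 1]`.
#' @export
cc_value <- function(W, u, v) {
  Wm <- as_w_matrix(W)
  if (all(u == 0) || all(v == 0)) {
    archie_abort("u and v must be non-zero", "archie_bad_argument")
  }
  wu <- drop(Wm %*% u)
  wtv <- drop(crossprod(Wm, v))
  den <- sqrt(sum(wu^2)) * sqrt(sum(wtv^2))
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  num <- sum(v * wu)^2
  min(1, num / den)
}

resolve_budgets <- function(cfg, p, g) {
  cfg <- cfg %||% scca_config()
  c_u <- cfg$c_u %||% default_sparsity(p)
  c_v <- cfg$c_v %||% default_sparsity(g)
  if (c_u < 1 - 1e-12 || c_u > sqrt(p) + 1e-12) {
    archie_abort(sprintf("c_u must lie in [1, sqrt(p)] = [1, %.4g]; got %.4g",
                         sqrt(p), c_u), "archie_bad_argument")
  }
  if (c_v < 1 - 1e-12 || c_v > sqrt(g) + 1e-12) {
    archie_abort(sprintf("c_v must lie in [1, sqrt(g)] = [1, %.4g]; got %.4g",
                         sqrt(g), c_v), "archie_bad_argument")
  }
  list(c_u = c_u, c_v = c_v, max_iter = cfg$max_iter, tol = cfg$tol)
}

#' Fit one sparse CCA component
#'
#' Alternating maximization of `v' W u` under unit-L2 norms and L1 budgets,
#' initialized from the leading singular vectors of W.  The fit is
#' deterministic for a given W and configuration; `seed` only matters for
#' optional random restarts (`restarts > 0`), which keep the best objective.
#'
#' @param W an `adjusted_matrix` from [build_w()] or a plain genes x variants
#'   matrix.
#' @param cfg an [scca_config()] (or `NULL` for defaults).
#' @param seed integer seed for optional restarts.
#' @param restarts number of additional random initializations (default 0).
#' @return An object of class `archie_component` with unit-L2 loading vectors
#'   `u` (variants) and `v` (genes), the cc-value `q2`, the selected index
#'   sets, iteration count and a convergence flag.
#' @export
fit_component <- function(W, cfg = NULL, seed = NULL, restarts = 0L) {
  Wm <- as_w_matrix(W)
  if (all(Wm == 0)) archie_abort("W is identically zero", "archie_bad_argument")
  b <- resolve_budgets(cfg, ncol(Wm), nrow(Wm))
  fit <- scca_fit_core(Wm, b$c_u, b$c_v, b$max_iter, b$tol)
  if (restarts > 0L) {
    fit <- with_seed(seed, {
      best <- fit
      for (r in seq_len(restarts)) {
        v0 <- rnorm(nrow(Wm)); v0 <- v0 / sqrt(sum(v0^2))
        cand <- tryCatch(
          scca_restart_core(Wm, v0, b$c_u, b$c_v, b$max_iter, b$tol),
          archie_degenerate = function(e) NULL)
        if (!is.null(cand) && cand$objective > best$objective) best <- cand
      }
      best
    })
  }
  new_component(fit, Wm, b, rank = 1L)
}

# restart variant of the core with a supplied initial v
scca_restart_core <- function(Wm, v0, c_u, c_v, max_iter, tol) {
  v <- v0
  obj_prev <- -Inf; converged <- FALSE; iters <- 0L; u <- NULL
  for (it in seq_len(max_iter)) {
    iters <- it
    u <- l1_unit(drop(crossprod(Wm, v)), c_u)
    if (is.null(u)) archie_abort("degenerate restart", "archie_degenerate")
    bvec <- drop(Wm %*% u)
    v <- l1_unit(bvec, c_v)
    if (is.null(v)) archie_abort("degenerate restart", "archie_degenerate")
    obj <- sum(v * bvec)
    if (abs(obj - obj_prev) < tol) { converged <- TRUE; break }
    obj_prev <- obj
  }
  i <- which.max(abs(u))
  if (u[i] < 0) { u <- -u; v <- -v }
  list(u = u, v = v, objective = sum(v * drop(Wm %*% u)),
       iterations = iters, converged = converged)
}

new_component <- function(fit, W_orig, budgets, rank) {
  u <- fit$u; v <- fit$v
  names(u) <- colnames(W_orig)
  names(v) <- rownames(W_orig)
  structure(
    list(u = u, v = v,
         q2 = as.numeric(cc_value(W_orig, u, v)),
         rank = as.integer(rank),
         selected_variants = which(u != 0),
         selected_genes = which(v != 0),
         objective = fit$objective,
         iterations = fit$iterations,
         converged = fit$converged,
         c_u = budgets$c_u, c_v = budgets$c_v),
    class = "archie_component"
  )
}

#' @export
print.archie_component <- function(x, ...) {
  cat(sprintf("archie_component (rank %d): q2 = %.4f, %d variants / %d genes selected%s\n",
              x$rank, x$q2, length(x$selected_variants), length(x$selected_genes),
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Extract successive sparse CCA components by deflation
#'
#' After each fit the rank-one contribution `(v' W u) v u'` is subtracted and
#' the next component is fitted to the residual.  Deflation yields only
#' approximately orthogonal loadings (exact orthogonalization would destroy
#' sparsity), and every component's cc-value is computed against the original
#' W.
#'
#' @inheritParams fit_component
#' @param K number of components, `1 <= K <= min(p, g)`.
#' @return An object of class `archie_component_set`: `$components` (list of
#'   [fit_component()] results), `$q2` (vector of cc-values), and
#'   `$deflation_residuals` (Frobenius norm of the working matrix after each
#'   extraction).
#' @export
fit_components <- function(W, K, cfg = NULL, seed = NULL, restarts = 0L) {
  Wm <- as_w_matrix(W)
  K <- as.integer(K)
  if (K < 1L || K > min(dim(Wm))) {
    archie_abort(sprintf("K must lie in [1, min(p, g)] = [1, %d]", min(dim(Wm))),
                 "archie_bad_argument")
  }
  b <- resolve_budgets(cfg, ncol(Wm), nrow(Wm))
  Wk <- Wm
  comps <- vector("list", K)
  resid <- numeric(K)
  for (k in seq_len(K)) {
    fit <- scca_fit_core(Wk, b$c_u, b$c_v, b$max_iter, b$tol)
    comps[[k]] <- new_component(fit, Wm, b, rank = k)
    d <- drop(crossprod(fit$v, Wk %*% fit$u))
    Wk <- Wk - d * tcrossprod(fit$v, fit$u)
    resid[k] <- sqrt(sum(Wk^2))
  }
  structure(
    list(components = comps,
         q2 = vapply(comps, `[[`, numeric(1), "q2"),
         deflation_residuals = resid,
         c_u = b$c_u, c_v = b$c_v),
    class = "archie_component_set"
  )
}

#' @export
print.archie_component_set <- function(x, ...) {
  cat(sprintf("archie_component_set: %d components (c_u = %.3g, c_v = %.3g)\n",
              length(x$components), x$c_u, x$c_v))
  for (cm in x$components) print(cm)
  invisible(x)
}

# fast path for resampling: q2 of the first K deflated components, no S3
scca_q2_seq <- function(Wm, K, c_u, c_v, max_iter = 100L, tol = 1e-7) {
  Wk <- Wm
  q2 <- numeric(K)
  for (k in seq_len(K)) {
    fit <- scca_fit_core(Wk, c_u, c_v, max_iter, tol)
    wu <- drop(Wm %*% fit$u)
    wtv <- drop(crossprod(Wm, fit$v))
    den <- sqrt(sum(wu^2)) * sqrt(sum(wtv^2))
    q2[k] <- if (den == 0) 0 else min(1, sum(fit$v * wu)^2 / den)
    d <- drop(crossprod(fit$v, Wk %*% fit$u))
    Wk <- Wk - d * tcrossprod(fit$v, fit$u)
  }
  q2
}

#' Permutation tuning of the sparsity budgets
#'
#' For every `(c_u, c_v)` pair on the supplied grids, compares the observed
#' leading cc-value with its mean over `T` replicas of W with independently
#' permuted columns (which destroys variant-gene association but keeps the
#' marginal structure), and returns the pair maximizing the gap.
#'
#' @param W an `adjusted_matrix` or plain matrix.
#' @param grid_u,grid_v candidate budgets (defaults: 5-point grids spanning
#'   the feasible range).
#' @param n_perm number of permuted replicas per grid point (default 20).
#' @param seed RNG seed for the permutations.
#' @return List with `c_u`, `c_v`, and the full `gap` matrix.
#' @export
tune_sparsity <- function(W, grid_u = NULL, grid_v = NULL, n_perm = 20L,
                          seed = NULL) {
  Wm <- as_w_matrix(W)
  p <- ncol(Wm); g <- nrow(Wm)
  grid_u <- grid_u %||% seq(1, sqrt(p), length.out = 5L)
  grid_v <- grid_v %||% seq(1, sqrt(g), length.out = 5L)
  with_seed(seed, {
    perms <- replicate(n_perm, apply(Wm, 2L, sample), simplify = FALSE)
    gap <- matrix(NA_real_, length(grid_u), length(grid_v),
                  dimnames = list(signif(grid_u, 4), signif(grid_v, 4)))
    for (i in seq_along(grid_u)) {
      for (j in seq_along(grid_v)) {
        obs <- scca_q2_seq(Wm, 1L, grid_u[i], grid_v[j])
        nul <- vapply(perms, function(Wp) scca_q2_seq(Wp, 1L, grid_u[i], grid_v[j]),
                      numeric(1))
        gap[i, j] <- obs - mean(nul)
      }
    }
    best <- which(gap == max(gap), arr.ind = TRUE)[1L, ]
    list(c_u = grid_u[best[1L]], c_v = grid_v[best[2L]], gap = gap)
  })
}

#' Write a component set to TSV + JSON run summary
#'
#' One TSV row per non-zero loading (`element_type`, `id`, `loading`,
#' `component`), plus a JSON summary with cc-values, iterations, convergence
#' flags and the configuration echo.
#'
#' @param set an `archie_component_set`.
#' @param tsv_path,json_path output files (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_components <- function(set, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(set, "archie_component_set"))
  if (!is.null(tsv_path)) {
    rows <- lapply(set$components, function(cm) {
      data.table::data.table(
        component = cm$rank,
        element_type = c(rep("variant", length(cm$selected_variants)),
                         rep("gene", length(cm$selected_genes))),
        id = c(names(cm$u)[cm$selected_variants] %||% as.character(cm$selected_variants),
               names(cm$v)[cm$selected_genes] %||% as.character(cm$selected_genes)),
        loading = c(cm$u[cm$selected_variants], cm$v[cm$selected_genes]))
    })
    data.table::fwrite(data.table::rbindlist(rows), tsv_path, sep = "\t")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(q2 = set$q2,
           iterations = vapply(set$components, `[[`, integer(1), "iterations"),
           converged = vapply(set$components, `[[`, logical(1), "converged"),
           c_u = set$c_u, c_v = set$c_v),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
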