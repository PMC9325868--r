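# Ingestion and filtering of trans-eQTL summary statistics.
#
# The central container is the summary_matrix: a variants x genes matrix of
# Z scores (optionally paired p-values) with variant and gene annotation
# tables.  All downstream modules consume this object.

#' Construct a summary matrix of trans-eQTL statistics
#'
#' Bundles a variants x genes matrix of Z scores with its annotation tables.
#' `variants` must have columns `variant_id`, `chromosome`, `position` and may
#' carry `maf` (minor allele frequency, in (0, 0.5]) and `trait_label` (the
#' trait each variant is associated with; used to build competitive null
#' pools).  `genes` must have `gene_id`, `chromosome`, `tss`.
#'
#' @param Z numeric matrix, variants in rows, genes in columns.  Row and
#'   column names must match `variants$variant_id` and `genes$gene_id`.
#' @param variants data.frame of variant annotation.
#' @param genes data.frame of gene annotation.
#' @param P optional matrix of two-sided p-values, same shape as `Z`.
#' @param n_study effective sample size of the eQTL study (used by the
#'   Z-to-correlation map in [build_w()]); may be `NA`.
#' @return An object of class `summary_matrix`.
#' @seealso [load_summary()], [filter_trans()], [intersect_expressed()]
#' @export
summary_matrix <- function(Z, variants, genes, P = NULL, n_study = NA_integer_) {
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) archie_abort("Z must be numeric", "archie_bad_argument")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need_v <- c("variant_id", "chromosome", "position")
  need_g <- c("gene_id", "chromosome", "tss")
  if (!all(need_v %in% names(variants))) {
    archie_abort(sprintf("variant table lacks columns: %s",
                         paste(setdiff(need_v, names(variants)), collapse = ", ")),
                 "archie_bad_argument")
  }
  if (!all(need_g %in% names(genes))) {
    archie_abort(sprintf("gene table lacks columns: %s",
                         paste(setdiff(need_g, names(genes)), collapse = ", ")),
                 "archie_bad_argument")
  }
  if (!("maf" %in% names(variants))) variants$maf <- NA_real_
  if (!("trait_label" %in% names(variants))) variants$trait_label <- NA_character_
  if (anyDuplicated(variants$variant_id)) {
    archie_abort("variant ids are not unique", "archie_bad_argument")
  }
  if (anyDuplicated(genes$gene_id)) {
    archie_abort("gene ids are not unique", "archie_bad_argument")
  }
  if (nrow(Z) != nrow(variants) || ncol(Z) != nrow(genes)) {
    archie_abort("Z dimensions do not match annotation tables", "archie_bad_argument")
  }
  rownames(Z) <- variants$variant_id
  colnames(Z) <- genes$gene_id
  ok_maf <- is.na(variants$maf) | (variants$maf > 0 & variants$maf <= 0.5)
  if (!all(ok_maf)) {
    archie_abort(sprintf("maf outside (0, 0.5] for variant %s",
                         variants$variant_id[which(!ok_maf)[1L]]),
                 "archie_bad_argument")
  }
  if (any(variants$position < 1, na.rm = TRUE) || any(genes$tss < 1, na.rm = TRUE)) {
    archie_abort("positions must be 1-based (>= 1)", "archie_bad_argument")
  }
  if (anyNA(Z)) archie_abort("Z contains missing entries", "archie_bad_argument")
  if (!is.null(P)) {
    P <- as.matrix(P)
    if (!identical(dim(P), dim(Z))) {
      archie_abort("P dimensions differ from Z", "archie_bad_argument")
    }
    dimnames(P) <- dimnames(Z)
  }
  structure(
    list(Z = Z, P = P, variants = variants, genes = genes,
         n_study = as.integer(n_study)),
    class = "summary_matrix"
  )
}

#' @export
print.summary_matrix <- function(x, ...) {
  cat(sprintf("summary_matrix: %d variants x %d genes%s\n",
              nrow(x$Z), ncol(x$Z),
              if (is.null(x$P)) "" else " (with p-values)"))
  if (!is.na(x$n_study)) cat(sprintf("  eQTL study n = %d\n", x$n_study))
  ntr <- length(unique(x$variants$trait_label[!is.na(x$variants$trait_label)]))
  if (ntr > 0) cat(sprintf("  variant trait labels: %d traits\n", ntr))
  invisible(x)
}

#' @export
dim.summary_matrix <- function(x) dim(x$Z)

#' Subset a summary matrix
#'
#' Rows (variants) and columns (genes) can be indexed by position, logical
#' mask, or id.  Annotation tables are subset consistently.
#'
#' @param x a [summary_matrix()].
#' @param i,j variant and gene indices or ids.
#' @param ... ignored.
#' @export
`[.summary_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$Z))
  if (missing(j)) j <- seq_len(ncol(x$Z))
  if (is.character(i)) i <- match(i, rownames(x$Z))
  if (is.character(j)) j <- match(j, colnames(x$Z))
  if (anyNA(i) || anyNA(j)) {
    archie_abort("unknown variant or gene id in subset", "archie_bad_argument")
  }
  summary_matrix(
    Z = x$Z[i, j, drop = FALSE],
    variants = x$variants[i, , drop = FALSE],
    genes = x$genes[j, , drop = FALSE],
    P = if (!is.null(x$P)) x$P[i, j, drop = FALSE],
    n_study = x$n_study
  )
}

#' Load trans-eQTL summary statistics from a TSV export
#'
#' Reads a long-format tab-separated file with header columns `SNP`, `SNPChr`,
#' `SNPPos`, `Gene`, `GeneChr`, `GenePos`, `Zscore` and optionally `Pvalue`
#' (one row per variant-gene pair), assembles the variants x genes Z matrix,
#' and attaches annotation.  Row and column order is deterministic: sorted by
#' id.  Variant-gene pairs absent from the file are resolved by
#' `missing_policy`: `"drop_gene"` keeps only genes observed for every variant
#' (the default, mirroring exports that keep the variant set fixed),
#' `"drop_variant"` keeps only fully observed variants, `"error"` fails.
#'
#' When a `Pvalue` column is present each entry is checked against
#' `2 * pnorm(-|Z|)`; discrepancies beyond `zp_tol` raise a warning by default
#' (published tables round p-values), or an error when `zp_check = "error"`.
#'
#' @param path summary statistics TSV.
#' @param variant_meta optional TSV with columns `variant_id`, `chromosome`,
#'   `position`, and optionally `maf`, `trait_label`.  When `NULL`,
#'   chromosome/position are taken from the summary file itself.
#' @param gene_meta optional TSV with columns `gene_id`, `chromosome`, `tss`.
#'   When `NULL`, gene annotation is taken from the summary file (`GenePos`
#'   is interpreted as the transcription start site).
#' @param missing_policy how to handle absent variant-gene pairs.
#' @param zp_check `"warn"` (default), `"error"`, or `"none"`.
#' @param zp_tol tolerance for the Z/p consistency check.
#' @param n_study effective eQTL study sample size to record.
#' @return A [summary_matrix()].
#' @export
load_summary <- function(path, variant_meta = NULL, gene_meta = NULL,
                         missing_policy = c("drop_gene", "drop_variant", "error"),
                         zp_check = c("warn", "error", "none"),
                         zp_tol = 0.01, n_study = NA_integer_) {
  missing_policy <- match.arg(missing_policy)
  zp_check <- match.arg(zp_check)
  if (!file.exists(path)) {
    archie_abort(sprintf("summary file not found: %s", path), "archie_io_error")
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("SNP", "Gene")),
                           data.table = TRUE, showProgress = FALSE)
  need <- c("SNP", "SNPChr", "SNPPos", "Gene", "GeneChr", "GenePos", "Zscore")
  if (!all(need %in% names(tab))) {
    archie_abort(sprintf("summary file lacks required columns: %s",
                         paste(setdiff(need, names(tab)), collapse = ", ")),
                 "archie_io_error")
  }
  z <- suppressWarnings(as.numeric(tab$Zscore))
  bad <- which(!is.finite(z))
  if (length(bad)) {
    # +1 for the header row so the number matches the file line
    archie_abort(sprintf("unparseable Zscore at line %d of %s",
                         bad[1L] + 1L, path), "archie_io_error")
  }
  key <- paste(tab$SNP, tab$Gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    archie_abort(sprintf("duplicated (variant, gene) pair: %s",
                         gsub("\r", " / ", d)), "archie_io_error")
  }

  vids <- sort(unique(tab$SNP))
  gids <- sort(unique(tab$Gene))
  Z <- matrix(NA_real_, length(vids), length(gids), dimnames = list(vids, gids))
  ri <- match(tab$SNP, vids)
  ci <- match(tab$Gene, gids)
  Z[cbind(ri, ci)] <- z
  P <- NULL
  if ("Pvalue" %in% names(tab)) {
    P <- matrix(NA_real_, length(vids), length(gids), dimnames = list(vids, gids))
    P[cbind(ri, ci)] <- suppressWarnings(as.numeric(tab$Pvalue))
  }

  if (anyNA(Z)) {
    if (missing_policy == "error") {
      archie_abort(sprintf("%d variant-gene pairs absent with missing_policy = 'error'",
                           sum(is.na(Z))), "archie_io_error")
    } else if (missing_policy == "drop_gene") {
      keep <- colSums(is.na(Z)) == 0L
      if (!any(keep)) abort_empty("no gene observed for every variant")
      Z <- Z[, keep, drop = FALSE]
      if (!is.null(P)) P <- P[, keep, drop = FALSE]
      gids <- gids[keep]
    } else {
      keep <- rowSums(is.na(Z)) == 0L
      if (!any(keep)) abort_empty("no variant observed for every gene")
      Z <- Z[keep, , drop = FALSE]
      if (!is.null(P)) P <- P[keep, , drop = FALSE]
      vids <- vids[keep]
    }
  }

  vtab <- unique(data.frame(
    variant_id = tab$SNP,
    chromosome = normalize_chrom(tab$SNPChr),
    position = as.integer(tab$SNPPos),
    stringsAsFactors = FALSE
  ))
  vtab <- vtab[match(vids, vtab$variant_id), , drop = FALSE]
  gtab <- unique(data.frame(
    gene_id = tab$Gene,
    chromosome = normalize_chrom(tab$GeneChr),
    tss = as.integer(tab$GenePos),
    stringsAsFactors = FALSE
  ))
  gtab <- gtab[match(gids, gtab$gene_id), , drop = FALSE]

  if (!is.null(variant_meta)) {
    vm <- data.table::fread(variant_meta, sep = "\t", header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
    miss <- setdiff(vids, vm$variant_id)
    if (length(miss)) {
      archie_abort(sprintf("variant_meta lacks %d summary variants (first: %s)",
                           length(miss), miss[1L]), "archie_io_error")
    }
    vm <- vm[match(vids, vm$variant_id), , drop = FALSE]
    vtab$chromosome <- normalize_chrom(vm$chromosome)
    vtab$position <- as.integer(vm$position)
    if ("maf" %in% names(vm)) vtab$maf <- as.numeric(vm$maf)
    if ("trait_label" %in% names(vm)) vtab$trait_label <- as.character(vm$trait_label)
  }
  if (!is.null(gene_meta)) {
    gm <- data.table::fread(gene_meta, sep = "\t", header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
    miss <- setdiff(gids, gm$gene_id)
    if (length(miss)) {
      archie_abort(sprintf("gene_meta lacks %d summary genes (first: %s)",
                           length(miss), miss[1L]), "archie_io_error")
    }
    gm <- gm[match(gids, gm$gene_id), , drop = FALSE]
    gtab$chromosome <- normalize_chrom(gm$chromosome)
    gtab$tss <- as.integer(gm$tss)
  }
  rownames(vtab) <- rownames(gtab) <- NULL

  out <- summary_matrix(Z, vtab, gtab, P = P, n_study = n_study)
  if (!is.null(out$P) && zp_check != "none") {
    expect_p <- 2 * pnorm(-abs(out$Z))
    dev <- abs(out$P - expect_p)
    nbad <- sum(dev > zp_tol, na.rm = TRUE)
    if (nbad > 0) {
      msg <- sprintf("%d p-values deviate from 2*pnorm(-|Z|) by more than %g (max deviation %.3g)",
                     nbad, zp_tol, max(dev, na.rm = TRUE))
      if (zp_check == "error") archie_abort(msg, "archie_zp_mismatch") else warning(msg)
    }
  }
  out
}

#' Write a summary matrix back to the TSV dialect read by [load_summary()]
#'
#' @param x a [summary_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "summary_matrix"))
  p <- nrow(x$Z); g <- ncol(x$Z)
  long <- data.table::data.table(
    SNP = rep(x$variants$variant_id, times = g),
    SNPChr = rep(x$variants$chromosome, times = g),
    SNPPos = rep(x$variants$position, times = g),
    Gene = rep(x$genes$gene_id, each = p),
    GeneChr = rep(x$genes$chromosome, each = p),
    GenePos = rep(x$genes$tss, each = p),
    # %.17g guarantees a bit-exact read-back of the doubles
    Zscore = sprintf("%.17g", as.vector(x$Z))
  )
  if (!is.null(x$P)) long$Pvalue <- sprintf("%.17g", as.vector(x$P))
  data.table::fwrite(long, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Restrict a summary matrix to genes trans to every variant
#'
#' A gene is trans to a variant when they lie on different chromosomes or the
#' variant is at least `window_bp` base pairs from the gene's transcription
#' start site.  Only genes trans to *every* variant in the matrix are kept, so
#' that all retained statistics are genuinely distal for the whole trait
#' variant set.
#'
#' @param summary a [summary_matrix()].
#' @param window_bp distance threshold in base pairs (default 5 Mb).
#' @return The filtered [summary_matrix()].  An empty result raises a classed
#'   `archie_empty` error rather than returning silently.
#' @export
filter_trans <- function(summary, window_bp = 5e6) {
  stopifnot(inherits(summary, "summary_matrix"))
  stop_if_not_scalar(window_bp, "window_bp")
  vchr <- normalize_chrom(summary$variants$chromosome)
  gchr <- normalize_chrom(summary$genes$chromosome)
  vpos <- summary$variants$position
  gtss <- summary$genes$tss
  # p x g logical: pair is trans
  same_chr <- outer(vchr, gchr, "==")
  dist <- abs(outer(vpos, gtss, "-"))
  trans <- !same_chr | dist >= window_bp
  keep <- colSums(trans) == nrow(summary$Z)
  if (!any(keep)) {
    abort_empty(sprintf("no gene is trans (>= %g bp or another chromosome) to every variant",
                        window_bp))
  }
  summary[, which(keep)]
}

#' Intersect summary genes with an expressed-gene list
#'
#' Keeps the genes present in `expressed_gene_ids`, preserving the current
#' column order (used to restrict to genes expressed in the reference tissue).
#'
#' @param summary a [summary_matrix()].
#' @param expressed_gene_ids character vector of gene ids.
#' @return The restricted [summary_matrix()]; empty intersection raises a
#'   classed `archie_empty` error.
#' @export
intersect_expressed <- function(summary, expressed_gene_ids) {
  stopifnot(inherits(summary, "summary_matrix"))
  keep <- summary$genes$gene_id %in% expressed_gene_ids
  if (!any(keep)) abort_empty("no summary gene is in the expressed set")
  summary[, which(keep)]
}
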