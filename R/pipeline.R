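# End-to-end pipeline and bundled fixture generator.
#
# run_pipeline() ties the modules together for one trait:
# load -> trans filter -> expressed-gene intersection -> reference
# correlation matrices -> W -> sparse CCA components -> competitive null ->
# significance report, with every artifact written under output_dir and a
# log sufficient to reconstruct the run (config echo + seeds).

pipeline_defaults <- function() {
  list(
    summary = NULL, variant_meta = NULL, gene_meta = NULL,
    genotype_ref = NULL, expression_ref = NULL, expressed_genes = NULL,
    phenotype = NULL,
    target_trait = NULL,
    K = 3L, M = 100L, alpha = 0.05, window_bp = 5e6,
    c_u = "auto", c_v = "auto",
    shrinkage_ld = 0, shrinkage_coexpr = 0.1, eigen_floor = 1e-6,
    z_map = "t", n_study = NA_integer_,
    null_kind = "competitive",
    seeds = list(null = 1L, fit = 1L),
    output_dir = NULL
  )
}

validate_config <- function(config) {
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    archie_abort(sprintf("unknown config key: %s", unknown[1L]),
                 "archie_config_error")
  }
  cfg <- modifyList(defs, config)
  for (key in c("summary", "output_dir")) {
    if (is.null(cfg[[key]])) {
      archie_abort(sprintf("config key '%s' is required", key),
                   "archie_config_error")
    }
  }
  for (key in c("summary", "variant_meta", "gene_meta", "genotype_ref",
                "expression_ref", "expressed_genes", "phenotype")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      archie_abort(sprintf("config path '%s' does not exist: %s", key, cfg[[key]]),
                   "archie_config_error")
    }
  }
  if (!cfg$null_kind %in% c("competitive", "global")) {
    archie_abort("null_kind must be 'competitive' or 'global'", "archie_config_error")
  }
  cfg
}

read_table_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Run the full aggregative trans-association pipeline
#'
#' @param config named list (or path to a YAML file) with keys: `summary`
#'   (required; TSV read by [load_summary()]), `variant_meta`, `gene_meta`,
#'   `genotype_ref` (TSV, samples x variants, first column sample id),
#'   `expression_ref` (TSV, genes x samples, first column gene id),
#'   `expressed_genes` (one id per line), `target_trait` (restrict analysis
#'   rows to this trait's variants and use the rest as the competitive pool),
#'   `K`, `M`, `alpha`, `window_bp`, `c_u`/`c_v` (numbers or `"auto"`),
#'   `shrinkage_ld`, `shrinkage_coexpr`, `eigen_floor`, `z_map`, `n_study`,
#'   `null_kind` (`"competitive"` or `"global"`), `seeds` (named list with
#'   `null` and `fit`), `output_dir` (required).  Unknown keys are fatal.
#' @return Invisibly, a list with the fitted `components`, `significance`,
#'   `L`, and the paths written (`components.tsv`, `report.json`,
#'   `null_q2.tsv`, `run.log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("run started %s", format(t0)),
                 paste0("config: ", jsonlite::toJSON(
                   cfg[!vapply(cfg, is.null, logical(1))], auto_unbox = TRUE)))
  stage <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%.2fs] %s",
                                       as.numeric(Sys.time() - t0, units = "secs"),
                                       msg))
  }
  on_failure_cleanup <- function() {
    for (f in file.path(cfg$output_dir,
                        c("components.tsv", "report.json", "null_q2.tsv"))) {
      if (file.exists(f)) unlink(f)
    }
  }

  result <- tryCatch({
    sm <- load_summary(cfg$summary, cfg$variant_meta, cfg$gene_meta,
                       n_study = cfg$n_study)
    stage(sprintf("loaded %d variants x %d genes", nrow(sm$Z), ncol(sm$Z)))

    pool <- NULL
    if (!is.null(cfg$target_trait)) {
      in_trait <- which(sm$variants$trait_label %in% cfg$target_trait)
      if (!length(in_trait)) {
        archie_abort(sprintf("no variant labelled with target trait '%s'",
                             cfg$target_trait), "archie_config_error")
      }
      pool <- sm[setdiff(seq_len(nrow(sm$Z)), in_trait), ]
      sm <- sm[in_trait, ]
      stage(sprintf("target trait '%s': %d variants (pool: %d)",
                    cfg$target_trait, nrow(sm$Z), nrow(pool$Z)))
    }

    sm <- filter_trans(sm, cfg$window_bp)
    stage(sprintf("trans filter (>= %g bp): %d genes kept", cfg$window_bp,
                  ncol(sm$Z)))
    if (!is.null(cfg$expressed_genes)) {
      expressed <- readLines(cfg$expressed_genes)
      sm <- intersect_expressed(sm, expressed)
      stage(sprintf("expressed-gene intersection: %d genes kept", ncol(sm$Z)))
    }

    p <- nrow(sm$Z); g <- ncol(sm$Z)
    if (!is.null(cfg$genotype_ref)) {
      dos <- read_table_matrix(cfg$genotype_ref)
      ld_all <- estimate_ld(dos, shrinkage = cfg$shrinkage_ld,
                            eigen_floor = cfg$eigen_floor)
      ld <- subset_correlation(ld_all, sm$variants$variant_id)
    } else {
      ld_all <- NULL
      ld <- correlation_matrix(diag(p), ids = sm$variants$variant_id,
                               eigen_floor = cfg$eigen_floor)
    }
    if (!is.null(cfg$expression_ref)) {
      expr <- t(read_table_matrix(cfg$expression_ref)) # to samples x genes
      co_all <- estimate_coexpression(expr, shrinkage = cfg$shrinkage_coexpr,
                                      eigen_floor = cfg$eigen_floor)
      coexpr <- subset_correlation(co_all, sm$genes$gene_id)
    } else {
      co_all <- NULL
      coexpr <- correlation_matrix(diag(g), ids = sm$genes$gene_id,
                                   eigen_floor = cfg$eigen_floor)
    }
    W <- build_w(sm, ld, coexpr, map = cfg$z_map)
    stage("built adjusted matrix W")

    c_u <- if (identical(cfg$c_u, "auto")) default_sparsity(p) else cfg$c_u
    c_v <- if (identical(cfg$c_v, "auto")) default_sparsity(g) else cfg$c_v
    scfg <- scca_config(c_u, c_v)
    fit <- fit_components(W, cfg$K, cfg = scfg, seed = cfg$seeds$fit)
    stage(sprintf("fitted %d components, q2 = %s", cfg$K,
                  paste(signif(fit$q2, 4), collapse = ", ")))

    nulls <- if (cfg$null_kind == "competitive") {
      if (is.null(pool)) {
        archie_abort("competitive null requires target_trait (to define the pool)",
                     "archie_config_error")
      }
      null_ensemble_competitive(
        pool, p, g, cfg$K, cfg$M, cfg = scfg,
        exclude_traits = cfg$target_trait,
        ld = ld_all, coexpr = co_all,
        map = cfg$z_map, seed = cfg$seeds$null)
    } else {
      null_ensemble_global(coexpr, ld, cfg$K, cfg$M, cfg = scfg,
                           seed = cfg$seeds$null)
    }
    stage(sprintf("%s null ensemble: M = %d", cfg$null_kind, cfg$M))

    sig <- component_pvalues(fit$q2, nulls)
    L <- select_significant(sig, cfg$alpha)
    stage(sprintf("p-values: %s; L = %d at alpha = %g",
                  paste(format_resampled_p(sig$p_values, sig$M), collapse = ", "),
                  L, cfg$alpha))

    paths <- list(
      components = file.path(cfg$output_dir, "components.tsv"),
      report = file.path(cfg$output_dir, "report.json"),
      null_q2 = file.path(cfg$output_dir, "null_q2.tsv"),
      log = file.path(cfg$output_dir, "run.log"))
    write_components(fit, tsv_path = paths$components)
    write_significance(nulls, sig, alpha = cfg$alpha,
                       tsv_path = paths$null_q2, json_path = paths$report)
    list(summary = sm, components = fit, significance = sig, L = L,
         nulls = nulls, paths = paths)
  }, error = function(e) {
    on_failure_cleanup()
    stop(e)
  })

  stage("run complete")
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  invisible(result)
}

#' Generate the bundled synthetic fixture set
#'
#' Writes a self-contained set of synthetic inputs exercising the whole
#' pipeline: a 100-variant x 500-gene summary TSV with a planted rank-one
#' trans signal for the target trait `"trait_target"` (all other variants
#' carry background-only statistics and labels `trait_001..`), variant/gene
#' annotation, reference dosage and expression TSVs, a cohort dosage TSV,
#' and a phenotype generated through the planted trans architecture (so TIES
#' on the planted genes is genuinely associated with it).  All files are
#' plain text.
#'
#' @param seed RNG seed.
#' @param out output directory (created if needed).
#' @param n_variants,n_genes fixture dimensions.
#' @param n_signal_variants,n_signal_genes size of the planted component.
#' @param n_ref reference panel size; `n_cohort` independent cohort size.
#' @return Invisibly, a named list of the file paths plus the planted
#'   variant/gene ids.
#' @export
make_fixtures <- function(seed, out, n_variants = 100L, n_genes = 500L,
                          n_signal_variants = 10L, n_signal_genes = 30L,
                          n_ref = 200L, n_cohort = 400L) {
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out)) {
      archie_abort(sprintf("cannot create output directory: %s", out),
                   "archie_io_error")
    }
  }
  with_seed(seed, {
    n_study <- 30000L
    vids <- sprintf("rs%05d", seq_len(n_variants))
    gids <- sprintf("GENE%04d", seq_len(n_genes))
    # variants spread over chromosomes 1-4, genes over 5-8: all pairs trans
    vtab <- data.frame(
      variant_id = vids,
      chromosome = as.character(rep_len(1:4, n_variants)),
      position = as.integer(1e6 + seq_len(n_variants) * 5e4),
      maf = round(runif(n_variants, 0.10, 0.40), 4),
      trait_label = c(rep("trait_target", n_signal_variants),
                      sprintf("trait_%03d",
                              rep_len(seq_len(45L), n_variants - n_signal_variants))),
      stringsAsFactors = FALSE)
    gtab <- data.frame(
      gene_id = gids,
      chromosome = as.character(rep_len(5:8, n_genes)),
      tss = as.integer(1e6 + seq_len(n_genes) * 7e4),
      stringsAsFactors = FALSE)

    # background Z: iid standard normal; planted rank-one block for the
    # target trait's variants over the signal genes
    Z <- matrix(rnorm(n_variants * n_genes), n_variants, n_genes,
                dimnames = list(vids, gids))
    sig_v <- seq_len(n_signal_variants)
    sig_g <- seq_len(n_signal_genes)
    a <- abs(rnorm(n_signal_variants)) + 0.5
    b <- rnorm(n_signal_genes)
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    strength <- 40
    Z[sig_v, sig_g] <- Z[sig_v, sig_g] + strength * tcrossprod(a, b)
    P <- 2 * pnorm(-abs(Z))

    sm <- summary_matrix(Z, vtab, gtab, P = P, n_study = n_study)
    paths <- list(
      summary = file.path(out, "summary.tsv"),
      variant_meta = file.path(out, "variant_meta.tsv"),
      gene_meta = file.path(out, "gene_meta.tsv"),
      genotype_ref = file.path(out, "genotype_ref.tsv"),
      expression_ref = file.path(out, "expression_ref.tsv"),
      cohort_dosages = file.path(out, "cohort_dosages.tsv"),
      phenotype = file.path(out, "phenotype.tsv"),
      networks = file.path(out, "network_presets.json"))
    write_summary(sm, paths$summary)
    data.table::fwrite(vtab, paths$variant_meta, sep = "\t")
    data.table::fwrite(gtab, paths$gene_meta, sep = "\t")

    # reference dosages: independent SNPs at the annotated MAFs
    ref_dos <- sapply(vtab$maf, function(m) rbinom(n_ref, 2L, m))
    colnames(ref_dos) <- vids
    data.table::fwrite(
      data.table::data.table(sample = sprintf("ref%03d", seq_len(n_ref)), ref_dos),
      paths$genotype_ref, sep = "\t")

    # reference expression: genes x samples, mild random co-expression
    fac <- matrix(rnorm(n_ref * 3L), n_ref, 3L)
    load <- matrix(rnorm(n_genes * 3L, sd = 0.4), n_genes, 3L)
    expr <- t(fac %*% t(load) + matrix(rnorm(n_ref * n_genes), n_ref, n_genes))
    rownames(expr) <- gids
    data.table::fwrite(
      data.table::data.table(gene_id = gids,
                             round(expr, 4)),
      paths$expression_ref, sep = "\t")

    # independent cohort for TIES: dosages + phenotype through the planted
    # trans architecture (sum of planted-gene TIES + noise)
    coh_dos <- sapply(vtab$maf, function(m) rbinom(n_cohort, 2L, m))
    colnames(coh_dos) <- vids
    ties <- compute_ties(Z[, sig_g, drop = FALSE], coh_dos, vtab$maf)
    lin <- rowSums(scale(ties$scores))
    y <- lin + rnorm(n_cohort, sd = sqrt(max(1e-8, var(lin)) * 3))
    data.table::fwrite(
      data.table::data.table(sample = sprintf("id%04d", seq_len(n_cohort)), coh_dos),
      paths$cohort_dosages, sep = "\t")
    data.table::fwrite(
      data.table::data.table(sample = sprintf("id%04d", seq_len(n_cohort)),
                             value = round(y, 5)),
      paths$phenotype, sep = "\t")

    # frozen network presets (topology + calibrated analytic summaries)
    nets <- lapply(c("global_null", "sparse", "dense", "master_regulator"),
                   function(pr) {
                     nt <- calibrate_effects(build_network(pr))
                     list(preset = pr, edges = lapply(nt$edges_cal, as.list),
                          cis_h2 = nt$cis_h2, trans_h2 = nt$trans_h2)
                   })
    jsonlite::write_json(nets, paths$networks, auto_unbox = TRUE, digits = NA)

    invisible(c(paths,
                list(signal_variants = vids[sig_v], signal_genes = gids[sig_g],
                     target_trait = "trait_target")))
  })
}
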