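# shared builders for the test suite; everything is generated in code

toy_variants <- function(ids, chrom = "1", pos = NULL, maf = 0.25,
                         trait = NA_character_) {
  data.frame(variant_id = ids,
             chromosome = rep_len(chrom, length(ids)),
             position = pos %||% (1e6 * seq_along(ids)),
             maf = rep_len(maf, length(ids)),
             trait_label = rep_len(trait, length(ids)),
             stringsAsFactors = FALSE)
}

toy_genes <- function(ids, chrom = "2", tss = NULL) {
  data.frame(gene_id = ids,
             chromosome = rep_len(chrom, length(ids)),
             tss = tss %||% (1e6 * seq_along(ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random summary matrix with iid N(0,1) Z and trait labels cycling over
# `n_traits` traits
toy_pool <- function(p, g, n_traits, seed, prefix = "t") {
  withr::local_seed(seed)
  Z <- matrix(rnorm(p * g), p, g)
  v <- toy_variants(sprintf("%s_v%03d", prefix, seq_len(p)),
                    trait = sprintf("%s_trait%03d", prefix,
                                    rep_len(seq_len(n_traits), p)))
  g_ <- toy_genes(sprintf("%s_g%03d", prefix, seq_len(g)))
  summary_matrix(Z, v, g_, n_study = 1000L)
}

# long-format summary TSV on disk; rows is a data.frame with columns
# SNP, SNPChr, SNPPos, Gene, GeneChr, GenePos, Zscore (and optionally Pvalue)
write_summary_rows <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
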