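test_that("load_summary assembles the matrix by key and applies the missing policy", {
  rows <- data.frame(
    SNP = c("s1", "s1", "s2"), SNPChr = 1, SNPPos = c(100, 100, 200),
    Gene = c("gA", "gB", "gA"), GeneChr = 2, GenePos = c(5e6, 6e6, 5e6),
    Zscore = c(2.0, 0.0, -1.0))
  path <- write_summary_rows(rows)

  # only the fully observed gene column survives drop_gene
  sm <- load_summary(path)
  expect_equal(dim(sm$Z), c(2L, 1L))
  expect_equal(colnames(sm$Z), "gA")
  expect_equal(unname(sm$Z[, "gA"]), c(2, -1))

  # drop_variant keeps the fully observed variant instead
  sv <- load_summary(path, missing_policy = "drop_variant")
  expect_equal(rownames(sv$Z), "s1")
  expect_equal(colnames(sv$Z), c("gA", "gB"))

  expect_error(load_summary(path, missing_policy = "error"),
               class = "archie_io_error")

  # complete file: placement is key-based, independent of row order
  rows2 <- data.frame(
    SNP = c("s2", "s1", "s1", "s2"), SNPChr = 1, SNPPos = c(200, 100, 100, 200),
    Gene = c("gB", "gA", "gB", "gA"), GeneChr = 2, GenePos = c(6e6, 5e6, 6e6, 5e6),
    Zscore = c(4, 1, 2, 3))
  sm2 <- load_summary(write_summary_rows(rows2))
  expect_equal(sm2$Z, matrix(c(1, 3, 2, 4), 2, 2,
                             dimnames = list(c("s1", "s2"), c("gA", "gB"))))
})

test_that("load_summary rejects duplicates and unparseable rows with locations", {
  rows <- data.frame(
    SNP = c("s1", "s1"), SNPChr = 1, SNPPos = 100,
    Gene = c("gA", "gA"), GeneChr = 2, GenePos = 5e6, Zscore = c(1, 2))
  expect_error(load_summary(write_summary_rows(rows)), "duplicated",
               class = "archie_io_error")

  rows$Gene <- c("gA", "gB")
  rows$Zscore <- c("1.0", "oops")
  expect_error(load_summary(write_summary_rows(rows)), "line 3",
               class = "archie_io_error")
})

test_that("Z/p consistency check uses the normal CDF with tolerance 0.01", {
  rows <- data.frame(
    SNP = "s1", SNPChr = 1, SNPPos = 100,
    Gene = "gA", GeneChr = 2, GenePos = 5e6,
    Zscore = 1.96, Pvalue = 0.0500)
  # 2 * pnorm(-1.96) = 0.04999579...: passes at the default tolerance
  expect_silent(sm <- load_summary(write_summary_rows(rows)))
  expect_equal(sm$P[1, 1], 0.05)

  rows$Pvalue <- 0.10
  expect_warning(load_summary(write_summary_rows(rows)), "deviate")
  expect_error(load_summary(write_summary_rows(rows), zp_check = "error"),
               class = "archie_zp_mismatch")
})

test_that("write_summary / load_summary round-trips Z bit-exactly", {
  pool <- toy_pool(7, 5, 3, seed = 42)
  path <- tempfile(fileext = ".tsv")
  write_summary(pool, path)
  back <- load_summary(path, n_study = pool$n_study)
  expect_identical(back$Z[rownames(pool$Z), colnames(pool$Z)], pool$Z)
})

test_that("filter_trans keeps genes trans to every variant", {
  # different chromosome is always trans
  sm <- summary_matrix(matrix(1, 2, 1),
                       toy_variants(c("v1", "v2"), chrom = "1",
                                    pos = c(1e6, 2e6)),
                       toy_genes("g1", chrom = "2", tss = 1.5e6))
  expect_equal(colnames(filter_trans(sm)$Z), "g1")

  # 4,999,999 bp on the same chromosome is below the 5 Mb window
  sm2 <- summary_matrix(matrix(1, 1, 1),
                        toy_variants("v1", chrom = "1", pos = 1),
                        toy_genes("g1", chrom = "1", tss = 5e6))
  expect_error(filter_trans(sm2), class = "archie_empty")
  expect_equal(colnames(filter_trans(sm2, window_bp = 4999999)$Z), "g1")

  # brute-force enumeration over a mixed panel: the chr1 gene at 7.5 Mb is
  # >= 5 Mb from both chr1 variants and trans to the chr2 variant, so it is
  # kept along with the chr3 gene; the chr1 gene at 3 Mb is only 1-2 Mb away
  vt <- toy_variants(c("v1", "v2", "v3"), chrom = c("1", "1", "2"),
                     pos = c(1e6, 2e6, 1e6))
  gt <- toy_genes(c("gA", "gB", "gC"), chrom = c("1", "1", "3"),
                  tss = c(7.5e6, 3e6, 1e6))
  sm3 <- summary_matrix(matrix(0, 3, 3), vt, gt)
  brute <- sapply(seq_len(3), function(j) {
    all(sapply(seq_len(3), function(i) {
      vt$chromosome[i] != gt$chromosome[j] ||
        abs(vt$position[i] - gt$tss[j]) >= 5e6
    }))
  })
  expect_equal(gt$gene_id[brute], c("gA", "gC"))
  expect_equal(colnames(filter_trans(sm3)$Z), c("gA", "gC"))
})

test_that("filter_trans is idempotent and monotone in the window", {
  withr::local_seed(7)
  sm <- summary_matrix(
    matrix(rnorm(8 * 30), 8, 30),
    toy_variants(sprintf("v%02d", 1:8), chrom = rep_len(c("1", "2"), 8),
                 pos = round(runif(8, 1, 5e7))),
    toy_genes(sprintf("g%02d", 1:30), chrom = rep_len(as.character(1:3), 30),
              tss = round(runif(30, 1, 5e7))))
  once <- filter_trans(sm)
  expect_identical(filter_trans(once)$Z, once$Z)
  # window = 0 keeps everything except exact-position overlaps
  expect_equal(ncol(filter_trans(sm, window_bp = 0)$Z), 30L)
  sizes <- sapply(c(0, 1e6, 5e6, 2e7), function(w) {
    tryCatch(ncol(filter_trans(sm, window_bp = w)$Z),
             archie_empty = function(e) 0L)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("intersect_expressed intersects and preserves order", {
  pool <- toy_pool(3, 4, 2, seed = 5)
  ids <- pool$genes$gene_id
  kept <- intersect_expressed(pool, c(ids[3], ids[2], "unrelated"))
  expect_equal(colnames(kept$Z), ids[2:3]) # original column order
  expect_identical(intersect_expressed(pool, c(ids, "extra"))$Z, pool$Z)
  expect_error(intersect_expressed(pool, "none"), class = "archie_empty")
})

test_that("summary_matrix validates annotation invariants", {
  expect_error(summary_matrix(matrix(0, 2, 1),
                              toy_variants(c("a", "a")), toy_genes("g")),
               "unique", class = "archie_bad_argument")
  expect_error(summary_matrix(matrix(0, 1, 1),
                              toy_variants("a", maf = 0.7), toy_genes("g")),
               "maf", class = "archie_bad_argument")
  expect_error(summary_matrix(matrix(NA_real_, 1, 1),
                              toy_variants("a"), toy_genes("g")),
               "missing", class = "archie_bad_argument")
})
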