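test_that("read_gwas parses a well-formed file and accounts for every row", {
  path <- write_gwas_file(make_gwas_df())
  g <- read_gwas(path)
  expect_s3_class(g, "gwas_sumstats")
  expect_equal(nrow(g), 3L)
  expect_equal(attr(g, "n_input"), 3L)
  expect_equal(attr(g, "n_skipped"), 0L)
  expect_equal(g$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(g$beta, c(0.10, -0.05, 0.02))
})

test_that("rows violating invariants are skipped and counted", {
  df <- make_gwas_df(se = c(0.02, 0, 0.02))  # se = 0 invalid
  path <- write_gwas_file(df)
  expect_message(g <- read_gwas(path), "skipped 1 of 3")
  expect_equal(nrow(g), 2L)
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_equal(attr(g, "n_input"), nrow(g) + attr(g, "n_skipped"))

  # p-value outside (0, 1] and identical alleles also fail
  df2 <- make_gwas_df(pvalue = c(0.5, 0, 1.5))
  expect_message(g2 <- read_gwas(write_gwas_file(df2)), "skipped 2 of 3")
  df3 <- make_gwas_df(effect_allele = c("A", "A", "C"),
                      other_allele = c("A", "G", "T"))
  expect_message(g3 <- read_gwas(write_gwas_file(df3)), "skipped 1 of 3")
  expect_equal(nrow(g3) + attr(g3, "n_skipped"), attr(g3, "n_input"))
})

test_that("odds-ratio columns are natural-log converted at read time", {
  path <- write_lines_tmp(c(
    "SNP\tA1\tA2\tOR\tSE\tP",
    "rs1\tA\tG\t1.105\t0.02\t0.001",
    "rs2\tT\tC\t0.9\t0.03\t0.5"
  ))
  g <- read_gwas(path, gwas_dialect("generic", beta = NULL, or = "OR",
                                    chrom = NULL, pos = NULL, eaf = NULL,
                                    n = NULL))
  expect_equal(g$beta, c(log(1.105), log(0.9)))
  expect_equal(g$beta[1], 0.09985, tolerance = 1e-4)
})

test_that("missing required columns and empty files raise named errors", {
  path <- write_lines_tmp(c("SNP\tA1\tA2\tBETA\tP", "rs1\tA\tG\t0.1\t0.5"))
  expect_error(read_gwas(path), "'SE'")
  empty <- write_lines_tmp(character())
  expect_error(read_gwas(empty), "empty input")
  header_only <- write_lines_tmp("SNP\tA1\tA2\tBETA\tSE\tP")
  expect_error(read_gwas(header_only), "no data rows")
  expect_error(read_gwas(tempfile()), "not found")
})

test_that("the megastroke dialect reads METAL-style files", {
  path <- write_lines_tmp(c(
    "MarkerName\tAllele1\tAllele2\tFreq1\tEffect\tStdErr\tP-value",
    "rs12122341\ta\tg\t0.25\t0.041\t0.012\t3.2e-4",
    "rs9651613\tt\tc\t0.4\t-0.02\t0.01\t0.045"
  ))
  g <- read_gwas(path, "megastroke")
  expect_equal(g$snp_id, c("rs12122341", "rs9651613"))
  expect_equal(g$effect_allele, c("A", "T"))  # alleles upper-cased
  expect_true(all(is.na(g$chrom)))
})

test_that("duplicate rsIDs keep the first occurrence with a warning", {
  df <- make_gwas_df(snp_id = c("rs1", "rs1", "rs2"),
                     beta = c(0.1, 0.9, 0.2))
  expect_warning(g <- read_gwas(write_gwas_file(df)), "duplicate")
  expect_equal(nrow(g), 2L)
  expect_equal(g$beta[g$snp_id == "rs1"], 0.1)
})

test_that("read_qtl groups records by probe and flags trans pairs", {
  df <- make_qtl_df(
    snp_id = rep(sprintf("rs%d", 1:5), 2),
    probe_id = rep(c("P1", "P2"), each = 5),
    effect_allele = rep("A", 10), other_allele = rep("G", 10),
    beta = seq(0.1, 1, by = 0.1), se = rep(0.05, 10)
  )
  q <- read_qtl(write_qtl_file(df))
  expect_equal(nrow(q), 10L)
  expect_equal(sort(unique(q$probe_id)), c("P1", "P2"))
  expect_equal(unname(table(q$probe_id)["P1"]), 5L)

  df$snp_chrom[1] <- "2"  # probe on chrom 1, SNP on chrom 2
  q2 <- read_qtl(write_qtl_file(df))
  expect_equal(nrow(q2), 10L)   # retained
  expect_true(q2$trans[q2$snp_id == "rs1" & q2$probe_id == "P1"])
  expect_equal(sum(q2$trans), 1L)
})

test_that("duplicate (snp, probe) rows keep the first occurrence", {
  df <- make_qtl_df(snp_id = c("rs1", "rs1", "rs2"),
                    probe_id = c("P1", "P1", "P1"),
                    beta = c(0.2, 0.8, 0.3))
  expect_warning(q <- read_qtl(write_qtl_file(df)), "duplicate")
  expect_equal(nrow(q), 2L)
  expect_equal(q$beta[q$snp_id == "rs1"], 0.2)
})

test_that("gzip-compressed inputs are read transparently", {
  df <- make_gwas_df()
  path <- tempfile(fileext = ".tsv.gz")
  write_sumstats(df, path, "gwas")
  g <- read_gwas(path)
  expect_equal(g$beta, df$beta)
  expect_equal(g$snp_id, df$snp_id)
})

test_that("result reports are sorted, scientific, and round-trip", {
  res <- structure(data.frame(
    probe_id = c("P1", "P2"), gene_symbol = c("G1", "G2"),
    top_snp = c("rs1", "rs2"), b_xy = c(0.31234, -0.21111),
    se_xy = c(0.05, 0.04), T_smr = c(20.1234, 24.5678),
    p_smr = c(9.0e-6, 4.0e-6), n_cis_snps = c(10L, 12L),
    stringsAsFactors = FALSE
  ), class = c("smr_result", "data.frame"))
  path <- tempfile(fileext = ".tsv")
  write_smr_results(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "^SNP\tP-value\tGene")
  expect_match(lines[2], "^rs2")  # smallest p first
  back <- read_smr_results(path)
  expect_equal(back$p_smr, c(4.0e-6, 9.0e-6))
  expect_equal(signif(back$b_xy, 3), signif(c(-0.21111, 0.31234), 3))
  expect_equal(signif(back$T_smr, 3), signif(c(24.5678, 20.1234), 3))

  # empty results give a header-only file
  empty <- res[0, , drop = FALSE]
  path2 <- tempfile(fileext = ".tsv")
  write_smr_results(empty, path2)
  expect_length(readLines(path2), 1L)
  expect_equal(nrow(read_smr_results(path2)), 0L)
})

test_that("per-source mQTL eligibility filters apply window, p and FDR rules", {
  df <- make_qtl_df(
    snp_id = sprintf("rs%d", 1:4),
    probe_id = rep("cg1", 4), probe_pos = 1e6,
    snp_pos = 1e6 + c(2e3, 1e4, 1e5, 6e5),
    effect_allele = rep("A", 4), other_allele = rep("G", 4),
    beta = c(0.5, 0.5, 0.01, 0.5), se = rep(0.04, 4)
  )
  df$fdr <- c(0.01, 0.5, 0.01, 0.01)
  expect_equal(filter_mqtl_records(df, "rosmap")$snp_id, "rs1")   # <= 5 kb
  h <- filter_mqtl_records(df, "hannon")  # <= 500 kb and p < 1e-10
  expect_true(all(abs(h$snp_pos - h$probe_pos) <= 5e5 & h$pvalue < 1e-10))
  expect_equal(h$snp_id, c("rs1", "rs2"))
  j <- filter_mqtl_records(df, "jaffe")   # <= 20 kb and fdr < 0.1
  expect_equal(j$snp_id, "rs1")
  c1 <- filter_mqtl_records(df, "custom", window_bp = 2e5)
  expect_equal(nrow(c1), 3L)
})
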