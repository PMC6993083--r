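test_that("estimate_bxy is the exact Wald ratio", {
  expect_equal(estimate_bxy(0.06, 0.2), 0.3)
  expect_equal(estimate_bxy(0, 0.2), 0)
  expect_equal(estimate_bxy(-0.06, -0.2), 0.3)  # signs cancel
  expect_error(estimate_bxy(0.06, 0), "b_zx = 0")
})

test_that("smr_statistic evaluates the chi-square(1) approximation", {
  expect_equal(smr_statistic(0, 5), 0)
  expect_equal(smr_statistic(2, 2), 2)           # z^2/2 when equal
  expect_equal(smr_statistic(4, 10), 1600 / 116) # direct evaluation
  expect_equal(smr_statistic(4, 10), 13.7931, tolerance = 1e-5)
  expect_error(smr_statistic(0, 0), "degenerate")
})

test_that("smr_pvalue is the upper-tail chi-square(1) probability", {
  expect_equal(smr_pvalue(0), 1)
  # independent oracle: chi1 upper tail == two-sided normal tail at sqrt(T)
  expect_equal(smr_pvalue(3.841), 2 * pnorm(-sqrt(3.841)))
  expect_equal(smr_pvalue(3.841), 0.0500, tolerance = 1e-3)
  expect_equal(smr_pvalue(13.7931), 2.04e-4, tolerance = 2e-3)
  expect_error(smr_pvalue(-1), "finite and >= 0")
})

test_that("delta_se_bxy implements the first-order delta method", {
  expect_equal(delta_se_bxy(0.06, 0.02, 0.2, 0.02),
               0.3 * sqrt((1 / 3)^2 + 0.1^2))
  expect_equal(delta_se_bxy(0.06, 0.02, 0.2, 0.02), 0.10440,
               tolerance = 1e-4)
  expect_equal(delta_se_bxy(0, 0.02, 0.2, 0.05), 0.1)  # b_zy = 0 limit
  # scale invariance of the relative error
  se1 <- delta_se_bxy(0.06, 0.02, 0.2, 0.02) / abs(0.06 / 0.2)
  se2 <- delta_se_bxy(0.12, 0.04, 0.4, 0.04) / abs(0.12 / 0.4)
  expect_equal(se1, se2)
  expect_error(delta_se_bxy(0.1, 0.02, 0, 0.02), "b_zx = 0")
})

test_that("select_instrument picks the smallest QTL p inside the window", {
  tr <- make_qtl_df(snp_id = c("rsA", "rsB", "rsC"),
                    probe_pos = 5e6,
                    snp_pos = 5e6 + c(1e4, -2e4, 3e4))
  triples <- data.frame(
    snp_id = tr$snp_id, probe_id = "P1", probe_pos = 5e6,
    snp_pos = tr$snp_pos, p_zx = c(1e-9, 1e-10, 1e-7),
    z_zx = c(6, 6.5, 5.5), stringsAsFactors = FALSE
  )
  pick <- select_instrument(triples, 5e6)
  expect_equal(pick$snp_id, "rsB")
  expect_equal(attr(pick, "n_cis"), 3L)

  # a candidate 1.5 Mb away is outside the 1 Mb cis window
  far <- triples
  far$snp_pos[2] <- 5e6 + 1.5e6
  expect_equal(select_instrument(far, 5e6)$snp_id, "rsA")
  expect_equal(attr(select_instrument(far, 5e6), "n_cis"), 2L)

  # nothing passes the default genome-wide instrument threshold
  weak <- triples
  weak$p_zx <- c(1e-4, 1e-5, 1e-6)
  expect_null(select_instrument(weak, 5e6))

  # deterministic tie-breaks: p, then |z_zx|, then rsID
  tie <- triples
  tie$p_zx <- rep(1e-10, 3)
  tie$z_zx <- c(6, 7, 7)
  expect_equal(select_instrument(tie, 5e6)$snp_id, "rsB")
  tie$z_zx <- rep(7, 3)
  expect_equal(select_instrument(tie, 5e6)$snp_id, "rsA")
})

test_that("apply_threshold resolves bonferroni and fixed policies", {
  res <- structure(data.frame(
    probe_id = sprintf("P%03d", 1:500), gene_symbol = "G", top_snp = "rs1",
    b_xy = 0.1, se_xy = 0.02, T_smr = 10,
    p_smr = seq(1e-6, 0.5, length.out = 500), n_cis_snps = 5L,
    stringsAsFactors = FALSE
  ), class = c("smr_result", "data.frame"))
  sig <- apply_threshold(res, "bonferroni")
  expect_equal(attr(sig, "alpha"), 0.05 / 500)
  expect_true(all(sig$p_smr < 1e-4))

  two <- res[1:2, ]; two$p_smr <- c(4.17e-6, 2e-5)
  sig2 <- apply_threshold(two, "fixed:1e-5")
  expect_equal(nrow(sig2), 1L)
  expect_equal(sig2$p_smr, 4.17e-6)

  expect_equal(nrow(apply_threshold(res[0, ], "bonferroni")), 0L)
  expect_error(resolve_alpha("fdr", 10), "unknown alpha_policy")
  expect_error(resolve_alpha("fixed:2", 10), "in \\(0, 1\\]")
})

test_that("smr_statistic is symmetric and bounded by min(z^2) (property)", {
  set.seed(11)
  a <- rnorm(10000, sd = 5)
  b <- rnorm(10000, sd = 5)
  keep <- !(a == 0 & b == 0)
  a <- a[keep]; b <- b[keep]
  T1 <- smr_statistic(a, b)
  expect_equal(T1, smr_statistic(b, a))
  expect_true(all(T1 <= pmin(a^2, b^2) + 1e-12))
  # the bound is approached as the other |z| grows
  T_big <- smr_statistic(3, 1e6)
  expect_equal(T_big, 9, tolerance = 1e-6)
})

test_that("smr_pvalue is strictly decreasing in T (property)", {
  Ts <- sort(c(0, 10^seq(-3, 2, length.out = 60)))
  ps <- smr_pvalue(Ts)
  expect_true(all(diff(ps) < 0))
})

test_that("run_smr screens probes end to end, deterministically", {
  cfg <- sim_config(n_probes = 5, n_snps = 8, seed = 7)
  eq <- simulate_qtl_stats(cfg)
  gw <- simulate_gwas_stats(cfg, eq$truth)
  r1 <- run_smr(gw, eq$records)
  r2 <- run_smr(gw, eq$records)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_s3_class(r1, "smr_result")
  expect_true(all(diff(r1$p_smr) >= 0))  # sorted ascending
  expect_true(all(r1$T_smr >= 0))
  expect_equal(r1$p_smr, smr_pvalue(r1$T_smr))
  # the selected instruments are the planted ones under a strong effect
  expect_true(all(r1$top_snp %in% eq$truth$probes$instrument_snp))
  # Wald ratio identity holds for each reported probe
  h <- harmonize_datasets(gw, eq$records)
  for (i in seq_len(nrow(r1))) {
    row <- h[h$snp_id == r1$top_snp[i] & h$probe_id == r1$probe_id[i], ]
    expect_equal(r1$b_xy[i], row$b_zy / row$b_zx)
    expect_true(r1$T_smr[i] <= min(row$z_zy^2, row$z_zx^2) + 1e-12)
  }
})

test_that("run_smr warns and returns empty on no overlap or no instrument", {
  gwas <- make_gwas_df(snp_id = c("rsX", "rsY"))
  qtl <- make_qtl_df(snp_id = c("rsA", "rsB"),
                     effect_allele = c("A", "A"),
                     other_allele = c("G", "G"), beta = c(0.1, 0.2))
  w <- capture_warnings(r <- run_smr(gwas, qtl))
  expect_true(any(grepl("no overlapping|empty", w)))
  expect_equal(nrow(r), 0L)
  expect_error(run_smr(gwas[0, ], qtl), "non-empty")
})
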