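test_that("generator counts, schema and validation", {
  cfg <- sim_config(n_probes = 3, n_snps = 20, seed = 5)
  sim <- simulate_qtl_stats(cfg)
  expect_equal(nrow(sim$records), 60L)
  expect_equal(nrow(sim$truth$probes), 3L)
  expect_s3_class(sim$records, "qtl_sumstats")
  expect_true(all(sim$records$se > 0))
  expect_true(all(sim$records$pvalue > 0 & sim$records$pvalue <= 1))
  # one instrument per probe, effect planted on it only
  per_probe <- tapply(sim$truth$snps$true_b_zx != 0,
                      sim$truth$snps$probe_id, sum)
  expect_true(all(per_probe == 1))
  # invalid configurations are rejected
  expect_error(sim_config(n_probes = 0), "n_probes")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_qtl = 5), "sample sizes")
  expect_error(sim_config(swap_frac = 2), "swap_frac")
})

test_that("instrument z matches the closed-form expectation (oracle)", {
  # E|z| = b_zx * sqrt(2 n maf (1-maf)); 200 probes act as 200 replicates
  cfg <- sim_config(n_probes = 200, n_snps = 2, maf_range = c(0.3, 0.3),
                    n_qtl = 1000, true_b_zx = 0.5, seed = 99)
  sim <- simulate_qtl_stats(cfg)
  inst <- merge(sim$truth$probes[c("probe_id", "instrument_snp")],
                sim$records, by.x = c("probe_id", "instrument_snp"),
                by.y = c("probe_id", "snp_id"))
  z <- abs(inst$beta / inst$se)
  expected <- 0.5 * sqrt(2 * 1000 * 0.3 * 0.7)  # = 10.247
  expect_equal(expected, 10.247, tolerance = 1e-4)
  mc_se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - expected), 3 * mc_se)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 4, n_snps = 5, seed = 17, swap_frac = 0.2,
                    ambiguous_frac = 0.2)
  a <- simulate_qtl_stats(cfg)
  b <- simulate_qtl_stats(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$probes, b$truth$probes)
  ga <- simulate_gwas_stats(cfg, a$truth)
  gb <- simulate_gwas_stats(cfg, a$truth)
  expect_identical(ga, gb)
  ma <- simulate_mqtl_stats(cfg)
  mb <- simulate_mqtl_stats(cfg)
  expect_identical(ma$records, mb$records)
  # different seed changes data, not schema
  c2 <- simulate_qtl_stats(sim_config(n_probes = 4, n_snps = 5, seed = 18))
  expect_identical(names(c2$records), names(a$records))
  expect_false(identical(c2$records$beta, a$records$beta))
})

test_that("generated p-values are consistent with z to 1e-10 relative", {
  cfg <- sim_config(n_probes = 10, n_snps = 10, seed = 3)
  sim <- simulate_qtl_stats(cfg)
  z <- sim$records$beta / sim$records$se
  expect_equal(sim$records$pvalue, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  gw <- simulate_gwas_stats(cfg, sim$truth)
  expect_equal(gw$pvalue, 2 * pnorm(-abs(gw$beta / gw$se)), tolerance = 1e-10)
})

test_that("GWAS scenarios encode the causal model and its null", {
  cfg_null <- sim_config(n_probes = 40, n_snps = 10, scenario = "null",
                         seed = 23)
  eq <- simulate_qtl_stats(cfg_null)
  gw <- simulate_gwas_stats(cfg_null, eq$truth)
  non_inst <- gw$snp_id[eq$truth$snps$true_b_zx == 0]
  z <- with(gw[gw$snp_id %in% non_inst, ], beta / se)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))

  # causal: instrument's expected trait effect is b_xy * b_zx = 0.15
  cfg <- sim_config(n_probes = 300, n_snps = 2, scenario = "causal",
                    true_b_xy = 0.3, true_b_zx = 0.5, seed = 24)
  eq2 <- simulate_qtl_stats(cfg)
  gw2 <- simulate_gwas_stats(cfg, eq2$truth)
  inst_ids <- eq2$truth$probes$instrument_snp
  b_zy <- gw2$beta[match(inst_ids, gw2$snp_id)]
  se_zy <- gw2$se[match(inst_ids, gw2$snp_id)]
  mc_se <- sd(b_zy) / sqrt(length(b_zy))
  expect_lt(abs(mean(b_zy) - 0.15), 3 * mc_se + 1e-12)
  expect_true(all(abs(se_zy - 1 / sqrt(2 * cfg$n_gwas *
    eq2$truth$snps$maf[match(inst_ids, eq2$truth$snps$snp_id)] *
    (1 - eq2$truth$snps$maf[match(inst_ids, eq2$truth$snps$snp_id)]))) < 1e-12))

  # population-level Wald identity: regression of observed b_zy on observed
  # b_zx across instruments recovers the causal slope
  b_zx <- eq2$records$beta[match(inst_ids, eq2$records$snp_id)]
  fit <- lm(b_zy ~ 0 + b_zx)
  expect_lt(abs(coef(fit)[[1]] - 0.3), 3 * summary(fit)$coefficients[1, 2])

  # pleiotropy: instrument trait effects independent of molecular effects
  cfg_p <- sim_config(n_probes = 300, n_snps = 2,
                      scenario = "independent_pleiotropy", seed = 25)
  eq3 <- simulate_qtl_stats(cfg_p)
  gw3 <- simulate_gwas_stats(cfg_p, eq3$truth)
  b_zy3 <- gw3$beta[match(eq3$truth$probes$instrument_snp, gw3$snp_id)]
  expect_lt(abs(mean(b_zy3)), 3 * sd(b_zy3) / sqrt(length(b_zy3)))
  expect_gt(sd(b_zy3), 0.05)  # real pleiotropic spread, not the null
})

test_that("mQTL presets honor per-source windows and thresholds", {
  cfg <- sim_config(n_probes = 6, n_snps = 8, seed = 41)
  ros <- simulate_mqtl_stats(cfg, preset = "rosmap")
  expect_true(all(abs(ros$records$snp_pos - ros$records$probe_pos) <= 5e3))
  expect_true(all(grepl("^cg", ros$records$probe_id)))

  han <- simulate_mqtl_stats(cfg, preset = "hannon")
  expect_true(all(han$records$pvalue < 1e-10))
  expect_true(all(abs(han$records$snp_pos - han$records$probe_pos) <= 5e5))

  jaf <- simulate_mqtl_stats(cfg, preset = "jaffe")
  expect_true(all(jaf$records$fdr < 0.1))
  expect_true(all(abs(jaf$records$snp_pos - jaf$records$probe_pos) <= 2e4))
})

test_that("fixtures round-trip through the flat-file I/O path", {
  cfg <- sim_config(n_probes = 3, n_snps = 5, seed = 55)
  dir <- tempfile()
  fx <- simulate_dataset(cfg, dir, n_cohorts = 1)
  expect_true(all(file.exists(c(fx$paths$eqtl, fx$paths$gwas,
                                fx$paths$mqtl, fx$paths$truth))))
  g <- read_gwas(fx$paths$gwas)
  q <- read_qtl(fx$paths$eqtl)
  expect_equal(nrow(g), 15L)
  expect_equal(nrow(q), 15L)
  expect_equal(sort(g$snp_id), sort(q$snp_id))
  # values survive the write/read cycle
  mem <- simulate_qtl_stats(cfg)
  expect_equal(q$beta[match(mem$records$snp_id, q$snp_id)],
               mem$records$beta, tolerance = 1e-12)
})
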