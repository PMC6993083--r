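#' Configuration for the synthetic summary-statistics generator
#'
#' The generator emulates the two-sample summary-data setting directly:
#' observed effect sizes are drawn around their true values with the
#' analytic standard error `1/sqrt(2 n maf (1-maf))` of a per-allele
#' regression estimate, with no individual-level genotypes and no LD between
#' SNPs (the analysis uses single top-SNP instruments and never models LD).
#'
#' Defaults mirror the study design the pipeline targets: a large stroke
#' GWAS (`n_gwas = 446696`, i.e. 40,585 cases + 406,111 controls), a brain
#' eQTL meta-analysis with effective `n_qtl = 1194` and a brain mQTL
#' meta-analysis with effective `n_mqtl = 1160`; a 1 Mb cis window; a strong
#' instrument (`true_b_zx = 0.5`, expected `|z_zx|` around 10-11 at the
#' default MAF range) and a causal effect `true_b_xy = 0.3`.
#'
#' @param n_snps SNPs per probe region.
#' @param n_probes number of probes.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param n_gwas,n_qtl,n_mqtl sample sizes (all >= 10).
#' @param true_b_zx per-allele effect of the instrument SNP on its probe's
#'   molecular phenotype; all other SNPs have zero effect.
#' @param true_b_xy causal effect of the molecular phenotype on the trait.
#' @param scenario `"causal"` (each SNP's trait effect is
#'   `true_b_xy * b_zx`), `"null"` (no trait effects), or
#'   `"independent_pleiotropy"` (the instrument receives a trait effect
#'   drawn independently of its molecular effect).
#' @param seed RNG seed; identical seeds give identical output.
#' @param probe_window_bp half-width of the region SNPs are placed in.
#' @param swap_frac fraction of GWAS records emitted with swapped allele
#'   order and negated beta (exercises harmonization).
#' @param ambiguous_frac fraction of SNPs given strand-ambiguous (A/T, C/G)
#'   allele pairs.
#' @param snp_id_start,probe_prefix,gene_prefix identifier layout, letting
#'   independently generated datasets coexist without ID collisions.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20, n_probes = 10,
                       maf_range = c(0.05, 0.5),
                       n_gwas = 446696, n_qtl = 1194, n_mqtl = 1160,
                       true_b_zx = 0.5, true_b_xy = 0.3,
                       scenario = c("causal", "null", "independent_pleiotropy"),
                       seed = 1, probe_window_bp = 1e6,
                       swap_frac = 0, ambiguous_frac = 0,
                       snp_id_start = 100000,
                       probe_prefix = "PROBE", gene_prefix = "GENE") {
  scenario <- match.arg(scenario)
  if (!is_scalar_number(n_probes) || n_probes < 1) {
    stop_config("sim_config: n_probes must be >= 1")
  }
  if (!is_scalar_number(n_snps) || n_snps < 1) {
    stop_config("sim_config: n_snps must be >= 1")
  }
  if (any(c(n_gwas, n_qtl, n_mqtl) < 10)) {
    stop_config("sim_config: sample sizes must be >= 10")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_config("sim_config: maf_range must be an interval within (0, 0.5]")
  }
  if (swap_frac < 0 || swap_frac > 1 || ambiguous_frac < 0 || ambiguous_frac > 1) {
    stop_config("sim_config: swap_frac and ambiguous_frac must be in [0, 1]")
  }
  structure(list(
    n_snps = as.integer(n_snps), n_probes = as.integer(n_probes),
    maf_range = as.numeric(maf_range),
    n_gwas = n_gwas, n_qtl = n_qtl, n_mqtl = n_mqtl,
    true_b_zx = true_b_zx, true_b_xy = true_b_xy,
    scenario = scenario, seed = as.integer(seed),
    probe_window_bp = probe_window_bp,
    swap_frac = swap_frac, ambiguous_frac = ambiguous_frac,
    snp_id_start = as.integer(snp_id_start),
    probe_prefix = probe_prefix, gene_prefix = gene_prefix
  ), class = "sim_config")
}

NONAMBIG_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                           "G", "A", "C", "A", "G", "T", "C", "T"),
                         ncol = 2, byrow = TRUE)
AMBIG_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)

sample_allele_pairs <- function(n, ambiguous_frac) {
  amb <- stats::runif(n) < ambiguous_frac
  idx_n <- sample.int(nrow(NONAMBIG_PAIRS), n, replace = TRUE)
  idx_a <- sample.int(nrow(AMBIG_PAIRS), n, replace = TRUE)
  a1 <- ifelse(amb, AMBIG_PAIRS[idx_a, 1], NONAMBIG_PAIRS[idx_n, 1])
  a2 <- ifelse(amb, AMBIG_PAIRS[idx_a, 2], NONAMBIG_PAIRS[idx_n, 2])
  cbind(a1, a2)
}

# Analytic standard error of a per-allele summary-statistic estimate for a
# standardized phenotype.
analytic_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

two_sided_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

# Shared worker: lay out probes and SNPs, plant one instrument per probe,
# draw observed QTL effects. Used by both the expression and methylation
# generators.
simulate_qtl_core <- function(config, n_sample, window_bp,
                              probe_ids, gene_ids, snp_id_start) {
  P <- length(probe_ids)
  K <- config$n_snps
  probe_chrom <- as.character(((seq_len(P) - 1L) %% 22L) + 1L)
  probe_pos <- 2e6 + ((seq_len(P) - 1L) %/% 22L) * (2 * window_bp + 2e6)
  probe_idx <- rep(seq_len(P), each = K)
  snp_num <- snp_id_start + seq_len(P * K) - 1L
  snp_id <- paste0("rs", snp_num)
  snp_pos <- round(probe_pos[probe_idx] +
                     stats::runif(P * K, -window_bp, window_bp))
  maf <- stats::runif(P * K, config$maf_range[1], config$maf_range[2])
  alleles <- sample_allele_pairs(P * K, config$ambiguous_frac)
  inst_offset <- sample.int(K, P, replace = TRUE)
  inst_row <- (seq_len(P) - 1L) * K + inst_offset
  true_b_zx <- numeric(P * K)
  true_b_zx[inst_row] <- config$true_b_zx
  se <- analytic_se(n_sample, maf)
  beta <- stats::rnorm(P * K, mean = true_b_zx, sd = se)
  z <- beta / se
  records <- data.frame(
    snp_id = snp_id,
    probe_id = probe_ids[probe_idx],
    gene_symbol = gene_ids[probe_idx],
    probe_chrom = probe_chrom[probe_idx],
    probe_pos = probe_pos[probe_idx],
    snp_chrom = probe_chrom[probe_idx],
    snp_pos = snp_pos,
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    eaf = maf,
    beta = beta,
    se = se,
    pvalue = two_sided_p(z),
    fdr = NA_real_,
    trans = FALSE,
    stringsAsFactors = FALSE
  )
  effective_b_xy <- switch(config$scenario,
    causal = config$true_b_xy, null = 0, independent_pleiotropy = NA_real_)
  truth <- list(
    probes = data.frame(
      probe_id = probe_ids,
      gene_symbol = gene_ids,
      probe_chrom = probe_chrom,
      probe_pos = probe_pos,
      instrument_snp = snp_id[inst_row],
      true_b_zx = config$true_b_zx,
      true_b_xy = effective_b_xy,
      scenario = config$scenario,
      stringsAsFactors = FALSE
    ),
    snps = data.frame(
      snp_id = snp_id,
      probe_id = probe_ids[probe_idx],
      snp_chrom = probe_chrom[probe_idx],
      snp_pos = snp_pos,
      maf = maf,
      effect_allele = alleles[, 1],
      other_allele = alleles[, 2],
      true_b_zx = true_b_zx,
      stringsAsFactors = FALSE
    ),
    config = config
  )
  class(truth) <- "sim_truth"
  class(records) <- c("qtl_sumstats", "data.frame")
  list(records = records, truth = truth)
}

#' Simulate expression-QTL summary statistics with known truth
#'
#' Per probe, one randomly placed SNP carries the instrument effect
#' `true_b_zx` on the probe's expression level; all other SNPs are null.
#' Observed betas are drawn around truth with the analytic standard error at
#' the QTL sample size; z and p follow from beta/se and the two-sided normal
#' tail. SNP positions fall within `probe_window_bp` of the probe.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return a list with `records` (a `qtl_sumstats` frame,
#'   `n_probes * n_snps` rows) and `truth` (a `sim_truth`: per-probe
#'   instrument identity and effects, per-SNP true `b_zx`).
#' @export
simulate_qtl_stats <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    P <- config$n_probes
    simulate_qtl_core(
      config, config$n_qtl, config$probe_window_bp,
      probe_ids = sprintf("%s%04d", config$probe_prefix, seq_len(P)),
      gene_ids = sprintf("%s%04d", config$gene_prefix, seq_len(P)),
      snp_id_start = config$snp_id_start
    )
  })
}

#' Simulate GWAS summary statistics over a simulated SNP panel
#'
#' The trait side of the two-sample design, on the same SNP panel as a
#' [simulate_qtl_stats()] run. True per-SNP trait effects follow the
#' scenario: under `"causal"` each SNP contributes `true_b_xy * b_zx`
#' (so non-instrument SNPs are null); under `"null"` all effects are zero;
#' under `"independent_pleiotropy"` each instrument SNP receives a trait
#' effect drawn `N(0, (true_b_xy * true_b_zx)^2)`, independent of its
#' molecular effect — the violation of the mediation model the SMR test
#' cannot distinguish from causality. Observed effects are drawn with the
#' analytic standard error at the GWAS sample size. A fraction `swap_frac`
#' of records is emitted with swapped alleles and negated beta.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [simulate_qtl_stats()] (same panel).
#' @param seed RNG seed (default `config$seed + 1` so the two samples are
#'   independent but jointly reproducible).
#' @return a `gwas_sumstats` frame, one row per panel SNP.
#' @export
simulate_gwas_stats <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "sim_truth") || is.null(truth$snps) ||
      nrow(truth$snps) == 0L) {
    stop("simulate_gwas_stats: `truth` must come from simulate_qtl_stats() on a matching SNP panel")
  }
  panel <- truth$snps
  with_seed(seed, {
    n <- nrow(panel)
    true_b_zy <- switch(config$scenario,
      causal = config$true_b_xy * panel$true_b_zx,
      null = numeric(n),
      independent_pleiotropy = {
        b <- numeric(n)
        inst <- panel$true_b_zx != 0
        b[inst] <- stats::rnorm(sum(inst), 0,
                                abs(config$true_b_xy * config$true_b_zx))
        b
      })
    se <- analytic_se(config$n_gwas, panel$maf)
    beta <- stats::rnorm(n, true_b_zy, se)
    swap <- stats::runif(n) < config$swap_frac
    out <- data.frame(
      snp_id = panel$snp_id,
      chrom = panel$snp_chrom,
      pos = panel$snp_pos,
      effect_allele = ifelse(swap, panel$other_allele, panel$effect_allele),
      other_allele = ifelse(swap, panel$effect_allele, panel$other_allele),
      eaf = ifelse(swap, 1 - panel$maf, panel$maf),
      beta = ifelse(swap, -beta, beta),
      se = se,
      pvalue = two_sided_p(beta / se),
      n = config$n_gwas,
      stringsAsFactors = FALSE
    )
    class(out) <- c("gwas_sumstats", "data.frame")
    out
  })
}

#' Simulate methylation-QTL summary statistics
#'
#' As [simulate_qtl_stats()] but with methylation-style probe identifiers
#' (`cg...`), the mQTL sample size, and per-source eligibility presets
#' honoring the distribution rules of the emulated sources: `"rosmap"`
#' (SNPs within 5 kb of the probe), `"hannon"` (within 500 kb, records kept
#' only if p < 1e-10), `"jaffe"` (within 20 kb, records kept only if
#' BH-adjusted FDR < 0.1, with the FDR emitted as a column).
#'
#' When `planted_snps` (rsIDs from `snp_panel`, a `sim_truth$snps` frame)
#' are given, each planted SNP becomes the instrument of one methylation
#' probe placed within the source window, and `config$n_probes` background
#' probes with fresh SNPs are added — the fixture for cross-reference
#' testing with a known `(n_query, n_with_any_hit)` answer.
#'
#' @param config a [sim_config()].
#' @param preset mQTL source preset.
#' @param snp_panel optional `sim_truth$snps`-shaped frame supplying planted
#'   SNPs' positions, frequencies and alleles.
#' @param planted_snps rsIDs within `snp_panel` to plant methylation effects
#'   on.
#' @param seed RNG seed (default `config$seed + 2`).
#' @return a list with `records` (a `qtl_sumstats` frame, post-filter) and
#'   `truth`.
#' @export
simulate_mqtl_stats <- function(config,
                                preset = c("rosmap", "hannon", "jaffe"),
                                snp_panel = NULL, planted_snps = NULL,
                                seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  preset <- match.arg(preset)
  rules <- mqtl_presets()[[preset]]
  window <- rules$window_bp
  with_seed(seed, {
    mqtl_id_start <- config$snp_id_start + 500000L
    if (is.null(planted_snps)) {
      sim <- simulate_qtl_core(
        config, config$n_mqtl, window,
        probe_ids = sprintf("cg%08d", seq_len(config$n_probes)),
        gene_ids = rep(NA_character_, config$n_probes),
        snp_id_start = mqtl_id_start
      )
    } else {
      if (is.null(snp_panel) || !all(planted_snps %in% snp_panel$snp_id)) {
        stop("simulate_mqtl_stats: planted_snps must be rsIDs present in snp_panel")
      }
      sim <- simulate_planted_mqtl(config, window, snp_panel, planted_snps,
                                   mqtl_id_start)
    }
    records <- sim$records
    if (!is.null(rules$fdr_max)) {
      # simulated stand-in for the source's published FDR column
      records$fdr <- stats::p.adjust(records$pvalue, method = "BH")
    }
    if (!is.null(rules$p_max)) {
      records <- records[records$pvalue < rules$p_max, , drop = FALSE]
    }
    if (!is.null(rules$fdr_max)) {
      records <- records[records$fdr < rules$fdr_max, , drop = FALSE]
    }
    rownames(records) <- NULL
    class(records) <- c("qtl_sumstats", "data.frame")
    attr(records, "mqtl_preset") <- preset
    list(records = records, truth = sim$truth)
  })
}

# Build the planted-mQTL layout: one probe per planted SNP (that SNP is the
# instrument, surrounded by fresh null SNPs), plus background probes whose
# instruments are fresh SNPs unrelated to the query set.
simulate_planted_mqtl <- function(config, window, snp_panel, planted_snps,
                                  id_start) {
  planted <- snp_panel[match(planted_snps, snp_panel$snp_id), , drop = FALSE]
  n_planted <- nrow(planted)
  n_bg <- config$n_probes
  P <- n_planted + n_bg
  K <- config$n_snps
  probe_ids <- sprintf("cg%08d", seq_len(P))
  probe_chrom <- character(P)
  probe_pos <- numeric(P)
  # planted probes sit beside their SNP, inside the source window
  off <- round(stats::runif(n_planted, -window / 2, window / 2))
  probe_chrom[seq_len(n_planted)] <- planted$snp_chrom
  probe_pos[seq_len(n_planted)] <- planted$snp_pos + off
  if (n_bg > 0) {
    bg <- seq_len(n_bg) + n_planted
    probe_chrom[bg] <- as.character(((seq_len(n_bg) - 1L) %% 22L) + 1L)
    probe_pos[bg] <- 8e8 + ((seq_len(n_bg) - 1L) %/% 22L) * (2 * window + 2e6)
  }
  rows <- vector("list", P)
  truth_rows <- vector("list", P)
  next_id <- id_start
  for (j in seq_len(P)) {
    is_planted <- j <= n_planted
    n_null <- K - 1L
    null_ids <- paste0("rs", next_id + seq_len(n_null) - 1L)
    next_id <- next_id + n_null
    if (is_planted) {
      inst_id <- planted$snp_id[j]
      inst_pos <- planted$snp_pos[j]
      inst_maf <- planted$maf[j]
      inst_a1 <- planted$effect_allele[j]
      inst_a2 <- planted$other_allele[j]
    } else {
      inst_id <- paste0("rs", next_id)
      next_id <- next_id + 1L
      inst_pos <- round(probe_pos[j] + stats::runif(1, -window, window))
      inst_maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      pr <- sample_allele_pairs(1L, config$ambiguous_frac)
      inst_a1 <- pr[1, 1]; inst_a2 <- pr[1, 2]
    }
    null_pos <- round(probe_pos[j] + stats::runif(n_null, -window, window))
    null_maf <- stats::runif(n_null, config$maf_range[1], config$maf_range[2])
    null_al <- sample_allele_pairs(n_null, config$ambiguous_frac)
    snp_id <- c(inst_id, null_ids)
    snp_pos <- c(inst_pos, null_pos)
    maf <- c(inst_maf, null_maf)
    a1 <- c(inst_a1, null_al[, 1])
    a2 <- c(inst_a2, null_al[, 2])
    true_b <- c(config$true_b_zx, numeric(n_null))
    se <- analytic_se(config$n_mqtl, maf)
    beta <- stats::rnorm(K, true_b, se)
    rows[[j]] <- data.frame(
      snp_id = snp_id, probe_id = probe_ids[j], gene_symbol = NA_character_,
      probe_chrom = probe_chrom[j], probe_pos = probe_pos[j],
      snp_chrom = probe_chrom[j], snp_pos = snp_pos,
      effect_allele = a1, other_allele = a2, eaf = maf,
      beta = beta, se = se, pvalue = two_sided_p(beta / se),
      fdr = NA_real_, trans = FALSE, stringsAsFactors = FALSE
    )
    truth_rows[[j]] <- data.frame(
      probe_id = probe_ids[j], gene_symbol = NA_character_,
      probe_chrom = probe_chrom[j], probe_pos = probe_pos[j],
      instrument_snp = inst_id, true_b_zx = config$true_b_zx,
      true_b_xy = NA_real_, scenario = config$scenario,
      planted = is_planted, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  class(records) <- c("qtl_sumstats", "data.frame")
  truth <- list(probes = do.call(rbind, truth_rows), snps = NULL,
                config = config)
  class(truth) <- "sim_truth"
  list(records = records, truth = truth)
}

#' Write simulated summary statistics in the generic flat-file dialect
#'
#' Emits exactly the layout the `"generic"` presets of [gwas_dialect()] and
#' [qtl_dialect()] read, so fixtures exercise the full I/O path.
#'
#' @param records a `gwas_sumstats` or `qtl_sumstats` frame.
#' @param path output path (gzip if it ends in `.gz`).
#' @param kind `"gwas"` or `"qtl"`; inferred from the class when omitted.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path, kind = NULL) {
  kind <- kind %||%
    (if (inherits(records, "gwas_sumstats")) "gwas" else "qtl")
  out <- if (kind == "gwas") {
    data.frame(SNP = records$snp_id, CHR = records$chrom, BP = records$pos,
               A1 = records$effect_allele, A2 = records$other_allele,
               FREQ = records$eaf, BETA = records$beta, SE = records$se,
               P = records$pvalue, N = records$n, stringsAsFactors = FALSE)
  } else {
    data.frame(SNP = records$snp_id, SNP_CHR = records$snp_chrom,
               SNP_BP = records$snp_pos,
               A1 = records$effect_allele, A2 = records$other_allele,
               FREQ = records$eaf, PROBE = records$probe_id,
               PROBE_CHR = records$probe_chrom, PROBE_BP = records$probe_pos,
               GENE = records$gene_symbol, BETA = records$beta,
               SE = records$se, P = records$pvalue, FDR = records$fdr,
               stringsAsFactors = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study fixture to a directory
#'
#' Generates linked GWAS + eQTL + mQTL summary statistics under one seed and
#' writes them (plus the generative truth tables) as flat files readable by
#' the pipeline. With `n_cohorts > 1`, several GWAS files are drawn over the
#' same SNP panel with independent noise — synthetic "cohorts" sharing the
#' same underlying architecture.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_cohorts number of GWAS files to draw.
#' @param mqtl_preset source preset for the methylation data.
#' @param planted_mqtl_snps optional rsIDs from the eQTL panel to plant
#'   methylation effects on (see [simulate_mqtl_stats()]).
#' @return invisibly, a list of written paths plus the truth object.
#' @export
simulate_dataset <- function(config, dir, n_cohorts = 1,
                             mqtl_preset = "rosmap",
                             planted_mqtl_snps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eqtl <- simulate_qtl_stats(config)
  paths <- list()
  paths$eqtl <- file.path(dir, "eqtl.tsv")
  write_sumstats(eqtl$records, paths$eqtl, "qtl")
  labels <- if (n_cohorts == 1) "gwas" else sprintf("gwas_cohort%d", seq_len(n_cohorts))
  paths$gwas <- character(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    g <- simulate_gwas_stats(config, eqtl$truth, seed = config$seed + i)
    paths$gwas[i] <- file.path(dir, paste0(labels[i], ".tsv"))
    write_sumstats(g, paths$gwas[i], "gwas")
  }
  mqtl <- simulate_mqtl_stats(config, preset = mqtl_preset,
                              snp_panel = eqtl$truth$snps,
                              planted_snps = planted_mqtl_snps)
  paths$mqtl <- file.path(dir, "mqtl.tsv")
  write_sumstats(mqtl$records, paths$mqtl, "qtl")
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(eqtl$truth$probes, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth_snps <- file.path(dir, "truth_snps.tsv")
  utils::write.table(eqtl$truth$snps, paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, truth = eqtl$truth,
                 mqtl_truth = mqtl$truth))
}
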