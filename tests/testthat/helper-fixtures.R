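# In-code fixtures shared across test files. All randomness is seeded at the
# call site; helpers themselves are deterministic.

make_gwas_df <- function(snp_id = c("rs1", "rs2", "rs3"),
                         effect_allele = rep_len(c("A", "A", "T"), length(snp_id)),
                         other_allele = rep_len(c("G", "C", "C"), length(snp_id)),
                         beta = rep_len(c(0.10, -0.05, 0.02), length(snp_id)),
                         se = rep(0.02, length(snp_id)),
                         eaf = rep(0.3, length(snp_id)),
                         pvalue = NULL) {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  structure(data.frame(
    snp_id = snp_id, chrom = "1", pos = seq_along(snp_id) * 1000,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue,
    n = 1000, stringsAsFactors = FALSE
  ), class = c("gwas_sumstats", "data.frame"))
}

make_qtl_df <- function(snp_id = c("rs1", "rs2", "rs3"),
                        probe_id = rep("P1", length(snp_id)),
                        effect_allele = rep_len(c("A", "A", "T"), length(snp_id)),
                        other_allele = rep_len(c("G", "C", "C"), length(snp_id)),
                        beta = rep_len(c(0.20, 0.15, -0.10), length(snp_id)),
                        se = rep(0.03, length(snp_id)),
                        probe_pos = 50000,
                        snp_pos = NULL,
                        gene_symbol = "GENEX",
                        eaf = rep(0.3, length(snp_id)),
                        pvalue = NULL) {
  if (is.null(snp_pos)) snp_pos <- probe_pos + seq_along(snp_id) * 100
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  structure(data.frame(
    snp_id = snp_id, probe_id = probe_id, gene_symbol = gene_symbol,
    probe_chrom = "1", probe_pos = probe_pos, snp_chrom = "1",
    snp_pos = snp_pos, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pvalue = pvalue, fdr = NA_real_, trans = FALSE,
    stringsAsFactors = FALSE
  ), class = c("qtl_sumstats", "data.frame"))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small GWAS file in the generic dialect, with optional extra raw lines.
write_gwas_file <- function(df = make_gwas_df(), path = tempfile(fileext = ".tsv")) {
  smrlink::write_sumstats(df, path, "gwas")
  path
}

write_qtl_file <- function(df = make_qtl_df(), path = tempfile(fileext = ".tsv")) {
  smrlink::write_sumstats(df, path, "qtl")
  path
}

# Swap every QTL record's alleles and negate its beta (and mirror eaf):
# the same dataset under the opposite allele coding.
swap_qtl_coding <- function(qtl) {
  out <- qtl
  out$effect_allele <- qtl$other_allele
  out$other_allele <- qtl$effect_allele
  out$beta <- -qtl$beta
  out$eaf <- 1 - qtl$eaf
  out
}
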