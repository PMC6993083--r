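#' Column dialect for GWAS summary-statistic files
#'
#' Summary-statistic flat files differ in column naming across consortia, so
#' the mapping from file columns to canonical fields is configuration, not
#' hard-coded. A dialect maps each canonical field to the column name used in
#' the file. Either `beta` or `or` (odds ratio, converted to the log scale at
#' read time) must be mapped.
#'
#' Presets:
#' \describe{
#'   \item{`generic`}{`SNP / CHR / BP / A1 / A2 / FREQ / BETA / SE / P / N`;
#'     the layout [write_sumstats()] emits.}
#'   \item{`megastroke`}{METAL-style meta-analysis output:
#'     `MarkerName / Allele1 / Allele2 / Freq1 / Effect / StdErr / P-value`
#'     (no chromosome/position columns; matching is rsID-keyed).}
#' }
#'
#' @param preset name of a built-in layout.
#' @param ... canonical-field overrides, e.g. `beta = "b"`, `or = "OR"`.
#'   Set a field to `NULL` to mark it absent. Canonical fields: `snp`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `or`,
#'   `se`, `pvalue`, `n`.
#' @return an object of class `smr_dialect`.
#' @export
#' @examples
#' gwas_dialect("megastroke")
#' gwas_dialect("generic", beta = NULL, or = "OR")
gwas_dialect <- function(preset = c("generic", "megastroke"), ...) {
  preset <- match.arg(preset)
  map <- switch(preset,
    generic = list(
      snp = "SNP", chrom = "CHR", pos = "BP",
      effect_allele = "A1", other_allele = "A2", eaf = "FREQ",
      beta = "BETA", or = NULL, se = "SE", pvalue = "P", n = "N"
    ),
    megastroke = list(
      snp = "MarkerName", chrom = NULL, pos = NULL,
      effect_allele = "Allele1", other_allele = "Allele2", eaf = "Freq1",
      beta = "Effect", or = NULL, se = "StdErr", pvalue = "P-value", n = NULL
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(map))
  if (length(bad)) {
    stop_config("unknown dialect field(s): %s", paste(bad, collapse = ", "))
  }
  for (nm in names(dots)) map[nm] <- list(dots[[nm]])
  structure(list(kind = "gwas", preset = preset, map = map),
            class = "smr_dialect")
}

#' Column dialect for QTL summary-statistic files
#'
#' As [gwas_dialect()], for per-SNP-per-probe expression or methylation QTL
#' tables. Additional canonical fields: `probe`, `probe_chrom`, `probe_pos`,
#' `gene`, `snp_chrom`, `snp_pos`, `fdr` (a published FDR column, used by
#' per-source methylation filters; never recomputed from the file).
#'
#' Presets:
#' \describe{
#'   \item{`generic`}{the layout [write_sumstats()] emits.}
#'   \item{`smr_flat`}{the flat query layout distributed alongside brain
#'     eQTL/mQTL meta-analyses: `SNP / Chr / BP / A1 / A2 / Freq / Probe /
#'     Probe_Chr / Probe_bp / Gene / b / SE / p`.}
#' }
#'
#' @inheritParams gwas_dialect
#' @return an object of class `smr_dialect`.
#' @export
qtl_dialect <- function(preset = c("generic", "smr_flat"), ...) {
  preset <- match.arg(preset)
  map <- switch(preset,
    generic = list(
      snp = "SNP", snp_chrom = "SNP_CHR", snp_pos = "SNP_BP",
      effect_allele = "A1", other_allele = "A2", eaf = "FREQ",
      probe = "PROBE", probe_chrom = "PROBE_CHR", probe_pos = "PROBE_BP",
      gene = "GENE", beta = "BETA", or = NULL, se = "SE", pvalue = "P",
      fdr = "FDR"
    ),
    smr_flat = list(
      snp = "SNP", snp_chrom = "Chr", snp_pos = "BP",
      effect_allele = "A1", other_allele = "A2", eaf = "Freq",
      probe = "Probe", probe_chrom = "Probe_Chr", probe_pos = "Probe_bp",
      gene = "Gene", beta = "b", or = NULL, se = "SE", pvalue = "p",
      fdr = NULL
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(map))
  if (length(bad)) {
    stop_config("unknown dialect field(s): %s", paste(bad, collapse = ", "))
  }
  for (nm in names(dots)) map[nm] <- list(dots[[nm]])
  structure(list(kind = "qtl", preset = preset, map = map),
            class = "smr_dialect")
}

#' @export
print.smr_dialect <- function(x, ...) {
  cat(sprintf("<%s dialect, preset '%s'>\n", x$kind, x$preset))
  for (nm in names(x$map)) {
    cat(sprintf("  %-14s -> %s\n", nm, x$map[[nm]] %||% "<absent>"))
  }
  invisible(x)
}

# Resolve a dialect argument that may be a preset name or a dialect object.
as_dialect <- function(dialect, kind) {
  if (inherits(dialect, "smr_dialect")) {
    if (dialect$kind != kind) {
      stop_config("expected a %s dialect, got a %s dialect", kind, dialect$kind)
    }
    return(dialect)
  }
  if (is.character(dialect) && length(dialect) == 1L) {
    return(if (kind == "gwas") gwas_dialect(dialect) else qtl_dialect(dialect))
  }
  stop_config("`dialect` must be a preset name or an smr_dialect object")
}
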