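#' @section File handling:
#' All readers accept plain or gzip-compressed whitespace/tab-delimited text
#' with a header row; compression is detected from the file contents, not the
#' extension.
#' @name sumstats-io
NULL

# Read a whitespace/tab-delimited table through a gzfile() connection, which
# transparently handles both gzip-compressed and plain text.
read_flat_table <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = TRUE, sep = "", quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop_config("empty input file: %s", path)
      }
      stop(e)
    }
  )
  if (nrow(df) == 0L) stop_config("input file has a header but no data rows: %s", path)
  df
}

# Pull mapped columns out of a raw table. Required canonical fields missing
# from the dialect or the header raise a configuration error naming the
# column; optional fields absent from either become NA.
extract_columns <- function(raw, dialect, required, optional, path) {
  get_col <- function(field, needed) {
    colname <- dialect$map[[field]]
    if (is.null(colname)) {
      if (needed) {
        stop_config("dialect maps no column for required field '%s'", field)
      }
      return(NULL)
    }
    if (!colname %in% names(raw)) {
      if (needed) {
        stop_config("required column '%s' (field '%s') not found in %s",
                    colname, field, path)
      }
      return(NULL)
    }
    raw[[colname]]
  }
  out <- list()
  for (f in required) out[[f]] <- get_col(f, TRUE)
  for (f in optional) {
    v <- get_col(f, FALSE)
    out[[f]] <- v %||% rep(NA, nrow(raw))
  }
  out
}

# Effect size on the log scale: a beta column is taken as-is, an odds-ratio
# column is natural-log transformed so downstream code sees one scale.
resolve_effect <- function(raw, dialect, path) {
  beta_col <- dialect$map[["beta"]]
  or_col <- dialect$map[["or"]]
  if (!is.null(beta_col) && beta_col %in% names(raw)) {
    return(as.numeric(raw[[beta_col]]))
  }
  if (!is.null(or_col) && or_col %in% names(raw)) {
    return(log(as.numeric(raw[[or_col]])))
  }
  stop_config("no effect-size column: dialect maps beta='%s', or='%s'; file %s has: %s",
              beta_col %||% "<absent>", or_col %||% "<absent>", path,
              paste(names(raw), collapse = ", "))
}

#' Read GWAS summary statistics
#'
#' Parses one SNP-trait association per row. Rows violating basic invariants
#' (`se > 0`, p-value in (0, 1], finite effect size, effect allele distinct
#' from the other allele) are counted and skipped, and the count is reported.
#' Odds-ratio columns are converted to log odds at read time. Duplicate rsIDs
#' keep the first occurrence with a warning.
#'
#' @param path flat file (optionally gzipped), whitespace/tab-delimited with
#'   a header.
#' @param dialect a [gwas_dialect()] object or preset name.
#' @return a `data.frame` of class `gwas_sumstats` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`; attributes `n_input` and `n_skipped` record the row
#'   accounting (`n_input = nrow + n_skipped` always, before deduplication).
#' @seealso [read_qtl()], [gwas_dialect()]
#' @export
read_gwas <- function(path, dialect = gwas_dialect()) {
  dialect <- as_dialect(dialect, "gwas")
  raw <- read_flat_table(path)
  cols <- extract_columns(
    raw, dialect,
    required = c("snp", "effect_allele", "other_allele", "se", "pvalue"),
    optional = c("chrom", "pos", "eaf", "n"),
    path = path
  )
  df <- data.frame(
    snp_id = as.character(cols$snp),
    chrom = as.character(cols$chrom),
    pos = as.numeric(cols$pos),
    effect_allele = toupper(as.character(cols$effect_allele)),
    other_allele = toupper(as.character(cols$other_allele)),
    eaf = as.numeric(cols$eaf),
    beta = resolve_effect(raw, dialect, path),
    se = as.numeric(cols$se),
    pvalue = as.numeric(cols$pvalue),
    n = as.numeric(cols$n),
    stringsAsFactors = FALSE
  )
  ok <- record_ok(df)
  n_input <- nrow(df)
  n_skipped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (n_skipped > 0L) {
    message(sprintf("read_gwas: skipped %d of %d rows failing invariants",
                    n_skipped, n_input))
  }
  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    warning(sprintf("read_gwas: %d duplicate rsID row(s) in %s; keeping first occurrence",
                    sum(dup), path), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, n_input = n_input, n_skipped = n_skipped,
            class = c("gwas_sumstats", "data.frame"))
}

# Shared row invariants: se > 0, p in (0,1], finite z = beta/se, distinct
# alleles. NA in any required numeric fails the row.
record_ok <- function(df) {
  se_ok <- is.finite(df$se) & df$se > 0
  p_ok <- is.finite(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1
  b_ok <- is.finite(df$beta)
  z_ok <- se_ok & b_ok & is.finite(df$beta / df$se)
  a_ok <- !is.na(df$effect_allele) & !is.na(df$other_allele) &
    df$effect_allele != df$other_allele
  se_ok & p_ok & b_ok & z_ok & a_ok
}

#' Read QTL (eQTL or mQTL) summary statistics
#'
#' Parses one SNP-by-probe molecular association per row. The same row
#' invariants as [read_gwas()] apply; additionally `probe_id` and the probe
#' position are required. Records whose SNP lies on a different chromosome
#' than the probe are retained but flagged `trans = TRUE`. Duplicate
#' (snp, probe) pairs keep the first occurrence with a warning.
#'
#' @inheritParams read_gwas
#' @param dialect a [qtl_dialect()] object or preset name.
#' @return a `data.frame` of class `qtl_sumstats` with columns `snp_id`,
#'   `probe_id`, `gene_symbol`, `probe_chrom`, `probe_pos`, `snp_chrom`,
#'   `snp_pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `fdr`, `trans`; attributes `n_input`, `n_skipped`.
#' @export
read_qtl <- function(path, dialect = qtl_dialect()) {
  dialect <- as_dialect(dialect, "qtl")
  raw <- read_flat_table(path)
  cols <- extract_columns(
    raw, dialect,
    required = c("snp", "probe", "probe_pos",
                 "effect_allele", "other_allele", "se", "pvalue"),
    optional = c("gene", "probe_chrom", "snp_chrom", "snp_pos", "eaf", "fdr"),
    path = path
  )
  df <- data.frame(
    snp_id = as.character(cols$snp),
    probe_id = as.character(cols$probe),
    gene_symbol = as.character(cols$gene),
    probe_chrom = as.character(cols$probe_chrom),
    probe_pos = as.numeric(cols$probe_pos),
    snp_chrom = as.character(cols$snp_chrom),
    snp_pos = as.numeric(cols$snp_pos),
    effect_allele = toupper(as.character(cols$effect_allele)),
    other_allele = toupper(as.character(cols$other_allele)),
    eaf = as.numeric(cols$eaf),
    beta = resolve_effect(raw, dialect, path),
    se = as.numeric(cols$se),
    pvalue = as.numeric(cols$pvalue),
    fdr = as.numeric(cols$fdr),
    stringsAsFactors = FALSE
  )
  ok <- record_ok(df) & !is.na(df$probe_id) & is.finite(df$probe_pos)
  n_input <- nrow(df)
  n_skipped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (n_skipped > 0L) {
    message(sprintf("read_qtl: skipped %d of %d rows failing invariants",
                    n_skipped, n_input))
  }
  df$trans <- !is.na(df$probe_chrom) & !is.na(df$snp_chrom) &
    df$probe_chrom != df$snp_chrom
  dup <- duplicated(df[c("snp_id", "probe_id")])
  if (any(dup)) {
    warning(sprintf("read_qtl: %d duplicate (snp, probe) row(s) in %s; keeping first occurrence",
                    sum(dup), path), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, n_input = n_input, n_skipped = n_skipped,
            class = c("qtl_sumstats", "data.frame"))
}

#' Per-source methylation-QTL eligibility filters
#'
#' Brain mQTL meta-analyses distribute only records passing source-specific
#' eligibility rules; when mixing sources these are applied as record-level
#' pre-filters, tagged by source:
#' \describe{
#'   \item{`rosmap`}{SNP within 5 kb of the methylation probe.}
#'   \item{`hannon`}{SNP within 500 kb and mQTL p-value < 1e-10.}
#'   \item{`jaffe`}{SNP within 20 kb and published FDR < 0.1 (the `fdr`
#'     column is an input, never recomputed).}
#' }
#'
#' @param qtl a `qtl_sumstats` data frame with `snp_pos` and `probe_pos`.
#' @param source one of `"rosmap"`, `"hannon"`, `"jaffe"`, or `"custom"`.
#' @param window_bp,p_max,fdr_max overrides for `source = "custom"`.
#' @return the filtered `qtl_sumstats`, with a `source` attribute.
#' @export
filter_mqtl_records <- function(qtl,
                                source = c("rosmap", "hannon", "jaffe", "custom"),
                                window_bp = NULL, p_max = NULL, fdr_max = NULL) {
  source <- match.arg(source)
  preset <- mqtl_presets()[[source]] %||%
    list(window_bp = window_bp, p_max = p_max, fdr_max = fdr_max)
  window_bp <- window_bp %||% preset$window_bp
  p_max <- p_max %||% preset$p_max
  fdr_max <- fdr_max %||% preset$fdr_max
  keep <- rep(TRUE, nrow(qtl))
  if (!is.null(window_bp)) {
    keep <- keep & is.finite(qtl$snp_pos) & !qtl$trans &
      abs(qtl$snp_pos - qtl$probe_pos) <= window_bp
  }
  if (!is.null(p_max)) keep <- keep & qtl$pvalue < p_max
  if (!is.null(fdr_max)) keep <- keep & !is.na(qtl$fdr) & qtl$fdr < fdr_max
  out <- qtl[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- source
  attr(out, "n_input") <- attr(qtl, "n_input")
  attr(out, "n_skipped") <- attr(qtl, "n_skipped")
  class(out) <- class(qtl)
  out
}

#' @rdname filter_mqtl_records
#' @return `mqtl_presets()`: the named list of per-source eligibility rules.
#' @export
mqtl_presets <- function() {
  list(
    rosmap = list(window_bp = 5e3, p_max = NULL, fdr_max = NULL),
    hannon = list(window_bp = 5e5, p_max = 1e-10, fdr_max = NULL),
    jaffe = list(window_bp = 2e4, p_max = NULL, fdr_max = 0.1),
    custom = NULL
  )
}

#' Write an SMR result report
#'
#' Tab-delimited report shaped like a per-trait association table: one row
#' per probe, ordered by ascending SMR p-value, with the p-value printed in
#' scientific notation at 4 significant digits.
#'
#' @param results an `smr_result` data frame (see [run_smr()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smr_results <- function(results, path) {
  results <- results[order(results$p_smr, results$probe_id), , drop = FALSE]
  gene <- ifelse(is.na(results$gene_symbol) | results$gene_symbol == "",
                 results$probe_id, results$gene_symbol)
  out <- data.frame(
    SNP = results$top_snp,
    `P-value` = format_pval(results$p_smr),
    Gene = gene,
    b_xy = format_num(results$b_xy),
    se_xy = format_num(results$se_xy),
    T_SMR = format_num(results$T_smr),
    probe_id = results$probe_id,
    n_cis_snps = results$n_cis_snps,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  con <- file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a report written by [write_smr_results()]
#'
#' @param path report file path.
#' @return a data frame with numeric `p_smr`, `b_xy`, `se_xy`, `T_smr`.
#' @export
read_smr_results <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  data.frame(
    probe_id = raw$probe_id,
    gene_symbol = raw$Gene,
    top_snp = raw$SNP,
    b_xy = as.numeric(raw$b_xy),
    se_xy = as.numeric(raw$se_xy),
    T_smr = as.numeric(raw$T_SMR),
    p_smr = as.numeric(raw$`P-value`),
    n_cis_snps = as.integer(raw$n_cis_snps),
    stringsAsFactors = FALSE
  )
}
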