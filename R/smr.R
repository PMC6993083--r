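#' SMR analysis configuration
#'
#' @param window_bp cis-window half-width in base pairs around each probe
#'   within which SNPs are candidate instruments (default 1 Mb, the window
#'   at which brain eQTL meta-analyses distribute records).
#' @param p_qtl_max maximum QTL p-value for a SNP to qualify as an
#'   instrument (default 5e-8, genome-wide significance — the two-sample MR
#'   convention for instrument validity).
#' @param alpha_policy multiple-testing policy for [apply_threshold()]:
#'   `"bonferroni"` (0.05 / number of probes tested) or `"fixed:x"` for an
#'   explicit cutoff, e.g. `"fixed:1e-5"`.
#' @return a list of class `smr_config`.
#' @export
smr_config <- function(window_bp = 1e6, p_qtl_max = 5e-8,
                       alpha_policy = "bonferroni") {
  stopifnot(is_scalar_number(window_bp), window_bp > 0,
            is_scalar_number(p_qtl_max), p_qtl_max > 0, p_qtl_max <= 1)
  resolve_alpha(alpha_policy, 1L)  # fail fast on malformed policy
  structure(list(window_bp = window_bp, p_qtl_max = p_qtl_max,
                 alpha_policy = alpha_policy),
            class = "smr_config")
}

#' Wald-ratio estimate of the effect of a molecular phenotype on a trait
#'
#' The two-step least-squares estimate `b_xy = b_zy / b_zx`: the SNP-trait
#' effect divided by the SNP-molecular-phenotype effect, both on the same
#' aligned allele. Free of confounding from non-genetic factors under the
#' instrumental-variable assumptions.
#'
#' @param b_zy SNP effect on the trait.
#' @param b_zx SNP effect on the molecular phenotype (must be nonzero).
#' @return `b_zy / b_zx`, vectorized.
#' @export
estimate_bxy <- function(b_zy, b_zx) {
  if (any(b_zx == 0)) {
    stop("estimate_bxy: b_zx = 0 — the instrument carries no effect on the molecular phenotype")
  }
  b_zy / b_zx
}

#' Approximate chi-square(1) SMR test statistic
#'
#' `T_SMR = z_zy^2 * z_zx^2 / (z_zy^2 + z_zx^2)`, where `z_zy` is the GWAS
#' z-statistic and `z_zx` the QTL z-statistic of the instrument SNP. This is
#' the two-sample approximation to `b_xy^2 / var(b_xy)`; it is symmetric in
#' its arguments, bounded above by `min(z_zy^2, z_zx^2)`, and zero when
#' either z is zero.
#'
#' @param z_zy GWAS z-statistic(s).
#' @param z_zx QTL z-statistic(s).
#' @return the statistic, vectorized.
#' @export
smr_statistic <- function(z_zy, z_zx) {
  if (any(z_zy == 0 & z_zx == 0)) {
    stop("smr_statistic: degenerate input, both z statistics are zero")
  }
  a2 <- z_zy^2
  b2 <- z_zx^2
  ifelse(a2 == 0 | b2 == 0, 0, a2 * b2 / (a2 + b2))
}

#' Upper-tail chi-square(1) p-value for the SMR statistic
#'
#' @param T_smr nonnegative statistic(s) from [smr_statistic()].
#' @return upper-tail probability of a chi-square distribution with one
#'   degree of freedom, vectorized.
#' @export
smr_pvalue <- function(T_smr) {
  if (any(!is.finite(T_smr)) || any(T_smr < 0)) {
    stop("smr_pvalue: T_smr must be finite and >= 0")
  }
  stats::pchisq(T_smr, df = 1, lower.tail = FALSE)
}

#' First-order delta-method standard error of the Wald ratio
#'
#' `se_xy = |b_xy| * sqrt((se_zy/b_zy)^2 + (se_zx/b_zx)^2)`, reducing to
#' `se_zy / |b_zx|` when `b_zy = 0`. Diagnostic only: the reported test
#' statistic is the [smr_statistic()] approximation, which coincides with
#' `b_xy^2 / se_xy^2` under this first-order variance.
#'
#' @param b_zy,se_zy SNP-trait effect and its standard error.
#' @param b_zx,se_zx SNP-molecular effect (nonzero) and its standard error.
#' @return the delta-method standard error, vectorized.
#' @export
delta_se_bxy <- function(b_zy, se_zy, b_zx, se_zx) {
  if (any(b_zx == 0)) stop("delta_se_bxy: b_zx = 0")
  ifelse(b_zy == 0,
         se_zy / abs(b_zx),
         abs(b_zy / b_zx) * sqrt((se_zy / b_zy)^2 + (se_zx / b_zx)^2))
}

#' Select the instrument SNP for one probe
#'
#' Among harmonized triples for a single probe, candidates are the SNPs
#' within `window_bp` of the probe position whose QTL p-value passes
#' `p_qtl_max`. The instrument is the candidate with the smallest QTL
#' p-value; ties break by largest `|z_zx|`, then lexicographically smallest
#' rsID, so selection is deterministic.
#'
#' @param triples a `harmonized_triples` frame, all rows sharing one probe.
#' @param probe_pos the probe position (1-based).
#' @param window_bp cis-window half-width.
#' @param p_qtl_max instrument QTL p-value threshold.
#' @return a one-row data frame (the chosen triple) with an `n_cis`
#'   attribute counting in-window candidates, or `NULL` if none survives.
#' @export
select_instrument <- function(triples, probe_pos, window_bp = 1e6,
                              p_qtl_max = 5e-8) {
  in_window <- is.finite(triples$snp_pos) &
    abs(triples$snp_pos - probe_pos) <= window_bp
  cand <- triples[in_window & triples$p_zx <= p_qtl_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(cand$p_zx, -abs(cand$z_zx), cand$snp_id)
  out <- cand[ord[1L], , drop = FALSE]
  attr(out, "n_cis") <- sum(in_window)
  out
}

#' Run the SMR test across all probes
#'
#' The single-dataset engine: harmonizes the GWAS against the QTL dataset,
#' selects the top cis-QTL SNP per probe as its instrument, and computes the
#' Wald-ratio estimate, delta-method standard error, SMR statistic and
#' chi-square(1) p-value for every probe with a surviving instrument.
#' Deterministic given inputs and configuration.
#'
#' @param gwas a `gwas_sumstats` frame, or pre-built `harmonized_triples`
#'   (in which case `qtl` is ignored).
#' @param qtl a `qtl_sumstats` frame.
#' @param config an [smr_config()].
#' @param policy a [harmonize_policy()].
#' @return a data frame of class `smr_result`, sorted by ascending `p_smr`,
#'   with columns `probe_id`, `gene_symbol`, `top_snp`, `b_xy`, `se_xy`,
#'   `T_smr`, `p_smr`, `n_cis_snps`; attributes `tally` (harmonization
#'   rejection tally) and `n_probes_tested`.
#' @export
run_smr <- function(gwas, qtl = NULL, config = smr_config(),
                    policy = harmonize_policy()) {
  if (inherits(gwas, "harmonized_triples")) {
    triples <- gwas
  } else {
    if (is.null(qtl) || nrow(gwas) == 0L || nrow(qtl) == 0L) {
      stop("run_smr: both GWAS and QTL inputs are required and must be non-empty")
    }
    triples <- harmonize_datasets(gwas, qtl, policy)
  }
  if (nrow(triples) == 0L) {
    warning("run_smr: empty harmonized intersection, no probes tested",
            call. = FALSE)
    return(empty_smr_result(attr(triples, "tally")))
  }
  rows <- vector("list", length(unique(triples$probe_id)))
  i <- 0L
  for (chunk in split(triples, triples$probe_id)) {
    inst <- select_instrument(chunk, chunk$probe_pos[1L],
                              window_bp = config$window_bp,
                              p_qtl_max = config$p_qtl_max)
    if (is.null(inst)) next
    i <- i + 1L
    b_xy <- estimate_bxy(inst$b_zy, inst$b_zx)
    T_smr <- smr_statistic(inst$z_zy, inst$z_zx)
    rows[[i]] <- data.frame(
      probe_id = inst$probe_id,
      gene_symbol = inst$gene_symbol,
      top_snp = inst$snp_id,
      b_xy = b_xy,
      se_xy = delta_se_bxy(inst$b_zy, inst$se_zy, inst$b_zx, inst$se_zx),
      T_smr = T_smr,
      p_smr = smr_pvalue(T_smr),
      n_cis_snps = attr(inst, "n_cis"),
      stringsAsFactors = FALSE
    )
  }
  if (i == 0L) {
    warning("run_smr: no probe has a qualifying instrument", call. = FALSE)
    return(empty_smr_result(attr(triples, "tally")))
  }
  out <- do.call(rbind, rows[seq_len(i)])
  out <- out[order(out$p_smr, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, tally = attr(triples, "tally"), n_probes_tested = nrow(out),
            class = c("smr_result", "data.frame"))
}

empty_smr_result <- function(tally = NULL) {
  out <- data.frame(
    probe_id = character(), gene_symbol = character(), top_snp = character(),
    b_xy = numeric(), se_xy = numeric(), T_smr = numeric(), p_smr = numeric(),
    n_cis_snps = integer(), stringsAsFactors = FALSE
  )
  structure(out, tally = tally, n_probes_tested = 0L,
            class = c("smr_result", "data.frame"))
}

#' Resolve a significance policy to a numeric cutoff
#'
#' @param alpha_policy `"bonferroni"` or `"fixed:x"`.
#' @param n_tests number of probes tested (used by `"bonferroni"`).
#' @return the numeric p-value cutoff.
#' @export
resolve_alpha <- function(alpha_policy, n_tests) {
  if (identical(alpha_policy, "bonferroni")) {
    if (n_tests < 1L) return(0.05)
    return(0.05 / n_tests)
  }
  if (is.character(alpha_policy) && grepl("^fixed:", alpha_policy)) {
    x <- suppressWarnings(as.numeric(sub("^fixed:", "", alpha_policy)))
    if (!is.finite(x) || x <= 0 || x > 1) {
      stop_config("alpha_policy 'fixed:x' needs x in (0, 1]; got '%s'", alpha_policy)
    }
    return(x)
  }
  stop_config("unknown alpha_policy '%s' (use 'bonferroni' or 'fixed:x')",
              as.character(alpha_policy))
}

#' Threshold SMR results for significance
#'
#' @param results an `smr_result` frame covering the complete analysis.
#' @param alpha_policy see [resolve_alpha()]; `"bonferroni"` divides 0.05 by
#'   the number of probes in `results`.
#' @return the significant subset (class `smr_result`), with attributes
#'   `alpha` (resolved cutoff) and `alpha_policy`.
#' @export
apply_threshold <- function(results, alpha_policy = "bonferroni") {
  alpha <- resolve_alpha(alpha_policy, nrow(results))
  out <- results[results$p_smr < alpha, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, alpha_policy = alpha_policy,
            n_probes_tested = nrow(results),
            class = c("smr_result", "data.frame"))
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR results: %d probe(s)", nrow(x)))
  if (!is.null(attr(x, "alpha"))) {
    cat(sprintf(" significant at p < %.3g [%s]", attr(x, "alpha"),
                attr(x, "alpha_policy")))
  }
  cat("\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}
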