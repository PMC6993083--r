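#' Overlap of significant genes between two analyses
#'
#' Intersects the gene symbols of two thresholded SMR result sets,
#' case-normalized (upper case). Commutative and idempotent.
#'
#' @param results_a,results_b thresholded `smr_result` frames (see
#'   [apply_threshold()]) or character vectors of gene symbols.
#' @return a sorted character vector of shared gene symbols.
#' @export
overlap_genes <- function(results_a, results_b) {
  genes <- function(x) {
    g <- if (is.character(x)) x else x$gene_symbol
    sort(unique(toupper(g[!is.na(g) & g != ""])))
  }
  intersect(genes(results_a), genes(results_b))
}

#' De-duplicated significant SNPs with per-analysis provenance
#'
#' A SNP may reach significance through several genes within one analysis
#' (one variant regulating two neighboring genes) and across analyses; it is
#' counted once, with every contributing analysis recorded.
#'
#' @param all_significant a named list of thresholded `smr_result` frames,
#'   one per analysis label.
#' @return a data frame with `snp_id`, `n_analyses`, `analyses`
#'   (comma-joined labels) and `genes` (comma-joined gene symbols the SNP
#'   instruments anywhere), sorted by `snp_id`.
#' @export
unique_snps <- function(all_significant) {
  if (length(all_significant) == 0L) {
    return(data.frame(snp_id = character(), n_analyses = integer(),
                      analyses = character(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(all_significant)) || any(names(all_significant) == "")) {
    names(all_significant) <- paste0("analysis", seq_along(all_significant))
  }
  long <- do.call(rbind, lapply(names(all_significant), function(lab) {
    res <- all_significant[[lab]]
    if (nrow(res) == 0L) return(NULL)
    data.frame(snp_id = res$top_snp, analysis = lab,
               gene = ifelse(is.na(res$gene_symbol) | res$gene_symbol == "",
                             res$probe_id, res$gene_symbol),
               stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    return(unique_snps(list()))
  }
  by_snp <- split(long, long$snp_id)
  out <- do.call(rbind, lapply(by_snp, function(d) {
    data.frame(
      snp_id = d$snp_id[1L],
      n_analyses = length(unique(d$analysis)),
      analyses = paste(sort(unique(d$analysis)), collapse = ","),
      genes = paste(sort(unique(toupper(d$gene))), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference trait-associated SNPs against methylation-QTL evidence
#'
#' For each query SNP (typically the de-duplicated significant SNPs from the
#' expression analyses), collects the methylation probes for which it shows
#' significant mQTL evidence. Two modes:
#' \describe{
#'   \item{`"smr"`}{(default) the SNP must be the instrument of a
#'     methylation probe passing the SMR significance threshold — the same
#'     test machinery with the methylation probe as the molecular
#'     phenotype.}
#'   \item{`"lookup"`}{nominal mQTL association: the SNP's record-level
#'     mQTL p-value (from `mqtl_records`) must pass the threshold, resolved
#'     over the number of distinct methylation probes.}
#' }
#' Every query SNP appears in the output, with zero probes if it has no
#' methylation evidence.
#'
#' @param snps character vector of query rsIDs (or a [unique_snps()] frame).
#' @param mqtl_results an `smr_result` frame from [run_smr()] on the mQTL
#'   dataset (mode `"smr"`).
#' @param alpha_policy see [resolve_alpha()].
#' @param mode `"smr"` or `"lookup"`.
#' @param mqtl_records a `qtl_sumstats` frame of methylation records,
#'   required for mode `"lookup"`.
#' @return a data frame of class `crossref_result` with `snp_id`,
#'   `n_methylation_probes`, `best_mqtl_p` (NA when no probe), `probes`
#'   (semicolon-joined `probe_id=p` pairs); attribute `summary` is the
#'   named vector `c(n_query, n_with_any_hit)`.
#' @export
cross_reference_mqtl <- function(snps, mqtl_results = NULL,
                                 alpha_policy = "bonferroni",
                                 mode = c("smr", "lookup"),
                                 mqtl_records = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(snps)) snps <- snps$snp_id
  snps <- unique(as.character(snps))
  if (mode == "smr") {
    if (is.null(mqtl_results)) {
      stop("cross_reference_mqtl: mode 'smr' needs mqtl_results from run_smr()")
    }
    sig <- apply_threshold(mqtl_results, alpha_policy)
    hits <- data.frame(snp_id = sig$top_snp, probe_id = sig$probe_id,
                       p = sig$p_smr, stringsAsFactors = FALSE)
  } else {
    if (is.null(mqtl_records)) {
      stop("cross_reference_mqtl: mode 'lookup' needs mqtl_records")
    }
    alpha <- resolve_alpha(alpha_policy, length(unique(mqtl_records$probe_id)))
    keep <- mqtl_records$pvalue < alpha
    hits <- data.frame(snp_id = mqtl_records$snp_id[keep],
                       probe_id = mqtl_records$probe_id[keep],
                       p = mqtl_records$pvalue[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(snps, function(s) {
    h <- hits[hits$snp_id == s, , drop = FALSE]
    h <- h[order(h$p, h$probe_id), , drop = FALSE]
    data.frame(
      snp_id = s,
      n_methylation_probes = nrow(h),
      best_mqtl_p = if (nrow(h)) h$p[1L] else NA_real_,
      probes = paste(sprintf("%s=%s", h$probe_id, format_pval(h$p)),
                     collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), n_methylation_probes = integer(),
                      best_mqtl_p = numeric(), probes = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  n_query <- length(snps)
  n_hit <- sum(out$n_methylation_probes > 0L)
  message(sprintf("%d of %d query SNPs significant in mQTL", n_hit, n_query))
  structure(out, summary = c(n_query = n_query, n_with_any_hit = n_hit),
            mode = mode, class = c("crossref_result", "data.frame"))
}

#' Write a methylation cross-reference report
#'
#' @param xref a `crossref_result` from [cross_reference_mqtl()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_crossref_results <- function(xref, path) {
  out <- data.frame(
    snp_id = xref$snp_id,
    n_methylation_probes = xref$n_methylation_probes,
    best_mqtl_p = ifelse(is.na(xref$best_mqtl_p), "NA",
                         format_pval(xref$best_mqtl_p)),
    probes = xref$probes,
    stringsAsFactors = FALSE
  )
  con <- file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- attr(xref, "summary")
  writeLines(sprintf("# %d of %d query SNPs significant in mQTL",
                     s[["n_with_any_hit"]], s[["n_query"]]), con)
  invisible(path)
}
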