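#' Allele-harmonization policy
#'
#' Controls how allele-orientation conflicts between the GWAS and QTL
#' datasets are resolved when building harmonized triples.
#'
#' Strand-ambiguous pairs (A/T and C/G) cannot be oriented from alleles
#' alone; the conservative two-sample MR default is to drop them. With
#' `freq_rescue = TRUE` an ambiguous SNP is kept when both datasets carry an
#' effect-allele frequency, both frequencies are away from 0.5 by more than
#' `eaf_margin`, and the frequencies are concordant after orientation.
#'
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @param freq_rescue attempt frequency-based rescue of ambiguous SNPs.
#' @param eaf_margin minimum |eaf - 0.5| on both sides for a rescue.
#' @return an object of class `harmonize_policy`.
#' @export
harmonize_policy <- function(drop_ambiguous = TRUE, freq_rescue = FALSE,
                             eaf_margin = 0.08) {
  stopifnot(is.logical(drop_ambiguous), is.logical(freq_rescue),
            is_scalar_number(eaf_margin), eaf_margin >= 0, eaf_margin < 0.5)
  structure(list(drop_ambiguous = drop_ambiguous, freq_rescue = freq_rescue,
                 eaf_margin = eaf_margin),
            class = "harmonize_policy")
}

VALID_ALLELES <- c("A", "C", "G", "T")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Vectorized allele comparison between GWAS (ga1/ga2) and QTL (qa1/qa2)
# effect/other alleles. Status: "ok", "flipped", "ambiguous", "mismatch",
# "indel" (any allele not a single A/C/G/T base).
classify_alleles <- function(ga1, ga2, qa1, qa2) {
  status <- rep("mismatch", length(ga1))
  snv <- ga1 %in% VALID_ALLELES & ga2 %in% VALID_ALLELES &
    qa1 %in% VALID_ALLELES & qa2 %in% VALID_ALLELES
  status[!snv] <- "indel"
  same <- snv & ga1 == qa1 & ga2 == qa2
  swap <- snv & ga1 == qa2 & ga2 == qa1
  status[same] <- "ok"
  status[swap] <- "flipped"
  amb <- (same | swap) & is_ambiguous_pair(ga1, ga2)
  status[amb] <- "ambiguous"
  list(status = status, swapped = swap)
}

# Frequency-based rescue test for ambiguous SNPs: both eafs informative
# (|eaf-0.5| > margin) and concordant after orienting the QTL eaf to the
# GWAS effect allele (swap => 1 - eaf).
ambiguous_rescuable <- function(eaf_g, eaf_q, swapped, margin) {
  eaf_q_oriented <- ifelse(swapped, 1 - eaf_q, eaf_q)
  is.finite(eaf_g) & is.finite(eaf_q_oriented) &
    abs(eaf_g - 0.5) > margin & abs(eaf_q_oriented - 0.5) > margin &
    sign(eaf_g - 0.5) == sign(eaf_q_oriented - 0.5)
}

#' Align the effect alleles of one GWAS and one QTL record
#'
#' Produces a harmonized triple in which the trait and molecular effect
#' sizes refer to the same allele. If the allele pair is swapped between the
#' datasets the QTL beta is negated and `flipped = TRUE`; strand-ambiguous
#' pairs are dropped (or frequency-rescued) per the policy; any other
#' mismatch, and any indel/multi-allelic record, is rejected with a reason.
#'
#' @param g one GWAS record (single row of a `gwas_sumstats` frame, or a
#'   list with the same fields).
#' @param q one QTL record.
#' @param policy a [harmonize_policy()].
#' @return a list with `triple` (one-row data frame, or `NULL` on rejection)
#'   and `reason` (`"ok"`, `"flipped"`, `"ambiguous_rescued"`,
#'   `"ambiguous"`, `"allele_mismatch"`, or `"indel_or_multiallelic"`).
#' @export
align_alleles <- function(g, q, policy = harmonize_policy()) {
  g <- as.list(g)
  q <- as.list(q)
  if (!identical(as.character(g$snp_id), as.character(q$snp_id))) {
    stop("align_alleles: snp_id mismatch ('", g$snp_id, "' vs '", q$snp_id,
         "') — records must be pre-matched by rsID")
  }
  cls <- classify_alleles(g$effect_allele, g$other_allele,
                          q$effect_allele, q$other_allele)
  status <- cls$status
  swapped <- cls$swapped
  if (status == "ambiguous") {
    if (policy$freq_rescue &&
        ambiguous_rescuable(g$eaf %||% NA_real_, q$eaf %||% NA_real_,
                            swapped, policy$eaf_margin)) {
      status <- "ambiguous_rescued"
    } else if (policy$drop_ambiguous) {
      return(list(triple = NULL, reason = "ambiguous"))
    } else {
      status <- if (swapped) "flipped" else "ok"
    }
  }
  if (status == "indel") {
    return(list(triple = NULL, reason = "indel_or_multiallelic"))
  }
  if (status == "mismatch") {
    return(list(triple = NULL, reason = "allele_mismatch"))
  }
  b_zx <- if (swapped) -q$beta else q$beta
  triple <- data.frame(
    snp_id = as.character(g$snp_id),
    probe_id = as.character(q$probe_id),
    gene_symbol = as.character(q$gene_symbol %||% NA_character_),
    probe_chrom = as.character(q$probe_chrom %||% NA_character_),
    probe_pos = as.numeric(q$probe_pos),
    snp_pos = as.numeric(q$snp_pos %||% NA_real_),
    b_zy = g$beta, se_zy = g$se, z_zy = g$beta / g$se, p_zy = g$pvalue,
    b_zx = b_zx, se_zx = q$se, z_zx = b_zx / q$se, p_zx = q$pvalue,
    flipped = swapped,
    ambiguous = status == "ambiguous_rescued",
    stringsAsFactors = FALSE
  )
  reason <- if (status == "ambiguous_rescued") "ambiguous_rescued"
            else if (swapped) "flipped" else "ok"
  list(triple = triple, reason = reason)
}

#' Intersect GWAS and QTL datasets into harmonized triples
#'
#' Matches records by rsID (the named summary-statistic sources are
#' rsID-keyed; positions are not used as a matching key), aligns effect
#' alleles for every (SNP, probe) candidate pair, and tallies rejections by
#' reason. An empty intersection is a valid, warned outcome.
#'
#' @param gwas a `gwas_sumstats` data frame ([read_gwas()]).
#' @param qtl a `qtl_sumstats` data frame ([read_qtl()]).
#' @param policy a [harmonize_policy()].
#' @return a data frame of class `harmonized_triples`, one row per surviving
#'   (SNP, probe) pair, with `z_zy = b_zy/se_zy` and `z_zx = b_zx/se_zx` on
#'   the aligned allele. Attribute `tally`: named integer vector counting
#'   `ok`, `flipped`, `ambiguous_rescued`, `ambiguous`, `allele_mismatch`,
#'   `indel_or_multiallelic`; the retained rows plus rejects always equal
#'   the number of candidate pairs.
#' @export
harmonize_datasets <- function(gwas, qtl, policy = harmonize_policy()) {
  tally <- c(ok = 0L, flipped = 0L, ambiguous_rescued = 0L,
             ambiguous = 0L, allele_mismatch = 0L,
             indel_or_multiallelic = 0L)
  g <- as.data.frame(gwas)[c("snp_id", "effect_allele", "other_allele",
                             "eaf", "beta", "se", "pvalue")]
  names(g) <- c("snp_id", "g_a1", "g_a2", "g_eaf", "b_zy", "se_zy", "p_zy")
  q <- as.data.frame(qtl)
  m <- merge(q, g, by = "snp_id", sort = FALSE)
  if (nrow(m) == 0L) {
    warning("harmonize_datasets: no overlapping SNPs between GWAS and QTL datasets",
            call. = FALSE)
    return(empty_triples(tally))
  }
  cls <- classify_alleles(m$g_a1, m$g_a2, m$effect_allele, m$other_allele)
  status <- cls$status
  swapped <- cls$swapped
  amb <- status == "ambiguous"
  if (any(amb)) {
    if (policy$freq_rescue) {
      resc <- amb & ambiguous_rescuable(m$g_eaf, m$eaf, swapped, policy$eaf_margin)
      status[resc] <- "ambiguous_rescued"
    } else if (!policy$drop_ambiguous) {
      status[amb] <- ifelse(swapped[amb], "flipped", "ok")
    }
  }
  keep <- status %in% c("ok", "flipped", "ambiguous_rescued")
  tally_key <- status
  tally_key[status == "indel"] <- "indel_or_multiallelic"
  tally_key[status == "mismatch"] <- "allele_mismatch"
  counts <- table(factor(tally_key, levels = names(tally)))
  tally[names(counts)] <- as.integer(counts)
  kept <- m[keep, , drop = FALSE]
  b_zx <- ifelse(swapped[keep], -kept$beta, kept$beta)
  out <- data.frame(
    snp_id = kept$snp_id,
    probe_id = kept$probe_id,
    gene_symbol = kept$gene_symbol,
    probe_chrom = kept$probe_chrom,
    probe_pos = kept$probe_pos,
    snp_pos = kept$snp_pos,
    b_zy = kept$b_zy, se_zy = kept$se_zy,
    z_zy = kept$b_zy / kept$se_zy, p_zy = kept$p_zy,
    b_zx = b_zx, se_zx = kept$se,
    z_zx = b_zx / kept$se, p_zx = kept$pvalue,
    flipped = swapped[keep],
    ambiguous = status[keep] == "ambiguous_rescued",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$probe_id, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("harmonize_datasets: all candidate pairs rejected during allele alignment",
            call. = FALSE)
  }
  structure(out, tally = tally, class = c("harmonized_triples", "data.frame"))
}

empty_triples <- function(tally) {
  out <- data.frame(
    snp_id = character(), probe_id = character(), gene_symbol = character(),
    probe_chrom = character(), probe_pos = numeric(), snp_pos = numeric(),
    b_zy = numeric(), se_zy = numeric(), z_zy = numeric(), p_zy = numeric(),
    b_zx = numeric(), se_zx = numeric(), z_zx = numeric(), p_zx = numeric(),
    flipped = logical(), ambiguous = logical(),
    stringsAsFactors = FALSE
  )
  structure(out, tally = tally, class = c("harmonized_triples", "data.frame"))
}
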