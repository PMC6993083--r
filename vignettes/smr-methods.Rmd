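---
title: "Methods: summary-data Mendelian randomization in smrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data Mendelian randomization in smrlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

For a SNP `z`, a molecular phenotype `x` (gene expression or CpG
methylation) and a trait `y`, the instrumental-variable estimate of the
effect of `x` on `y` is the Wald ratio `b_xy = b_zy / b_zx`, where `b_zy`
and `b_zx` are per-allele least-squares estimates from a GWAS and a QTL
study respectively. In the two-sample summary-data setting neither `x` and
`y` nor the two samples are observed jointly; the test statistic is

```
T_SMR = z_zy^2 * z_zx^2 / (z_zy^2 + z_zx^2),    z = b / se,
```

referred to a chi-square distribution with one degree of freedom. The
identity `1/T_SMR = 1/z_zy^2 + 1/z_zx^2` makes explicit that the statistic
is dominated by the weaker of the two associations and is bounded above by
`min(z_zy^2, z_zx^2)` — a probe cannot test more significant than either
its GWAS or its QTL evidence alone.

A significant `T_SMR` is evidence that the same causal variant drives both
the molecular phenotype and the trait. It is *consistent with* causality
(`z → x → y`) but cannot be distinguished from vertical pleiotropy of the
instrument SNP using a single instrument; the generator's
`independent_pleiotropy` scenario exists precisely to produce datasets
where the SMR test fires without the mediation model being true. No
heterogeneity (multi-SNP) test is implemented — single top-SNP instruments
only.

### Assumptions

1. The instrument is strongly associated with `x` (enforced by the
   `p_qtl_max` threshold; weak instruments bias `b_xy` toward zero and
   inflate its variance).
2. The GWAS and QTL samples are non-overlapping and drawn from comparable
   populations, so `z_zy` and `z_zx` are independent.
3. Effect alleles are correctly aligned between datasets — the job of the
   harmonization stage.

## The variance of b_xy

The source formulation labels a displayed equation "the variance of
`b_xy`" but prints the test statistic there; no explicit variance formula
is given. We therefore report the first-order delta-method standard error

```
se_xy = |b_xy| * sqrt((se_zy/b_zy)^2 + (se_zx/b_zx)^2)
```

(with the `b_zy = 0` limit `se_zy/|b_zx|`), flagged as the implementer's
choice. Algebraically, `b_xy^2 / se_xy^2` with this variance *equals* the
`T_SMR` expression above, so the "two forms agree within 5%" acceptance
check is an internal-consistency check of two code paths rather than a
comparison of genuinely different approximations; `se_xy` is reported as a
diagnostic only and `T_SMR` is the test.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_bp` | 1,000,000 | bp | brain eQTL meta-analyses distribute only SNPs within 1 Mb of each probe |
| `p_qtl_max` | 5e-8 | p-value | genome-wide significance; the conventional validity bar for a cis instrument |
| `alpha_policy` | `bonferroni` | — | 0.05 / probes tested; the source tables imply fixed per-table cutoffs (~1e-5, ~1e-4) but never state them, so `fixed:x` is available to mimic them |
| mQTL source filters | 5 kb / 500 kb + p<1e-10 / 20 kb + FDR<0.1 | — | the distribution rules of the ROSMAP-, Hannon- and Jaffe-style sources; applied as record-level pre-filters, published FDR treated as input |

Instrument ties (identical QTL p) break by larger `|z_zx|`, then
lexicographically smaller rsID — fixed so results are deterministic and
order-stable.

## Harmonization policy

Matching is by rsID, not position (the targeted source files are
rsID-keyed; the METAL-style GWAS layout has no position columns). Swapped
allele pairs negate the QTL beta; because `T_SMR` depends on z only through
`z^2`, the full pipeline is invariant to re-coding every QTL record to the
opposite allele — an acceptance criterion checked byte-for-byte on the
written reports. Strand-ambiguous (A/T, C/G) SNPs are dropped by default,
the conservative two-sample norm since the source text is silent;
`freq_rescue = TRUE` keeps them when both effect-allele frequencies are
informative (`|eaf - 0.5| > 0.08`) and concordant after orientation. Indels
and multi-allelic records are rejected with a tallied reason; duplicates
keep the first occurrence with a warning. Retained + rejected = candidate
pairs, always.

## The synthetic-data generator

Summary statistics are simulated directly — observed `beta ~ N(truth, se)`
with the analytic per-allele standard error `se = 1/sqrt(2 n maf (1-maf))`
of a standardized-phenotype regression — rather than via individual-level
genotypes. This matches the two-sample summary-data setting exactly and is
orders of magnitude faster. Defaults are the stated world of the targeted
study: GWAS n = 446,696 (40,585 cases + 406,111 controls of the European
ischemic-stroke analysis), eQTL effective n = 1,194, mQTL effective
n = 1,160, 1 Mb cis regions. The instrument effect `true_b_zx = 0.5` gives
an expected instrument `|z_zx|` of about 10–11 over the default MAF range
(0.05–0.5 uniform, a generic common-variant spectrum chosen once), i.e. a
strong instrument (F ≈ z² > 100); `true_b_xy = 0.3` is the causal effect
used by the recovery criterion. Under `independent_pleiotropy` the
instrument's trait effect is drawn `N(0, (true_b_xy·true_b_zx)^2)` —
matched in scale to the causal scenario so the two are comparable in power,
independent of `b_zx` by construction.

Deliberately **not** emulated: linkage disequilibrium (the analysis uses
single top-SNP instruments and never models LD), population structure,
case/control liability-scale effects (the GWAS `n` enters only through the
standard error), and sample overlap. A green calibration or recovery test
therefore establishes correctness of the estimator and test under the
stated model — it does not establish robustness to LD-induced winner's
curse, allele-frequency mismatch between cohorts, or pleiotropy, and the
null-calibration result says nothing about real GWAS with correlated SNPs.

Degenerate inputs: both z-statistics zero is an error (the statistic is
0/0); one zero gives `T = 0`, `p = 1`. Generated p-values are floored at
1e-300 to avoid underflow to an invalid 0. The generator is deterministic
under its seed, restores the caller's RNG state, and writes exactly the
flat-file dialect the readers parse, so fixtures exercise the full I/O
path.

## Open design points, decided

- **mQTL "significance" for the cross-reference** is ambiguous in the
  source ("significant in mQTL dataset"): re-running the SMR machinery with
  the methylation probe as `x` (default, mode `"smr"`), or a nominal lookup
  of the record-level mQTL p-value (mode `"lookup"`). Both are provided;
  neither is asserted to reproduce the source's 31-of-38 count, which is
  not desk-scale reproducible. In the pipeline's `"smr"` mode the first
  configured GWAS supplies the trait side for the methylation screen — a
  documented simplification; run [cross_reference_mqtl()] directly for
  per-GWAS control.
- **Report shape**: per-label reports mirror the source's per-trait tables
  (`SNP / P-value / Gene`) plus `b_xy`, `se_xy`, `T_SMR`, `probe_id`,
  `n_cis_snps`; p-values in scientific notation at 4 significant digits;
  probes without a gene symbol are reported by probe id.
- **Chromosome/position are optional on the GWAS side** since the
  METAL-style layout lacks them and matching is rsID-keyed; cis windows use
  QTL-side SNP positions.
- Acceptance simulations run as one vectorized generator call (one probe
  region per replicate: 2,000 for calibration, 500 for recovery), keeping
  the whole suite in seconds while using exactly the stated replicate
  counts.

## Known limitations

Single-instrument tests cannot separate causality from pleiotropy or
linkage; no LD reference, no conditional analysis, no multi-SNP SMR or
heterogeneity test; no binary QTL storage formats or VCF input; no
genome-build liftover or LD-proxy substitution — records that fail rsID or
allele matching are dropped, not rescued. The published FDR of
Jaffe-style mQTL sources is consumed, never recomputed.
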