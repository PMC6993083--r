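#' Assemble a pipeline run configuration
#'
#' @param gwas the GWAS inputs: a named character vector/list of paths
#'   (names are labels), or a list of `list(path=, label=, trait=)` entries.
#'   The optional `trait` groups labels for gene-overlap reports (two labels
#'   are compared when they share a trait); without traits, all label pairs
#'   are compared.
#' @param eqtl path to the eQTL summary-statistic file.
#' @param mqtl optional path to the mQTL summary-statistic file.
#' @param gwas_dialect,qtl_dialect dialect objects or preset names.
#' @param window_bp,p_qtl_max,alpha_policy see [smr_config()].
#' @param mqtl_mode `"smr"` or `"lookup"`, see [cross_reference_mqtl()].
#' @param mqtl_source optional per-source eligibility filter applied to the
#'   mQTL records at read time (see [filter_mqtl_records()]).
#' @param out_dir run directory for reports and the log.
#' @param seed seed recorded for simulation subcommands (the analysis path
#'   itself is fully deterministic).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(gwas, eqtl, mqtl = NULL,
                       gwas_dialect = "generic", qtl_dialect = "generic",
                       window_bp = 1e6, p_qtl_max = 5e-8,
                       alpha_policy = "bonferroni",
                       mqtl_mode = c("smr", "lookup"), mqtl_source = NULL,
                       out_dir = "smr_run", seed = 1) {
  mqtl_mode <- match.arg(mqtl_mode)
  if (is.list(gwas) && length(gwas) && is.list(gwas[[1]])) {
    labels <- vapply(gwas, function(x) x$label, character(1))
    paths <- vapply(gwas, function(x) x$path, character(1))
    traits <- vapply(gwas, function(x) x$trait %||% NA_character_, character(1))
  } else {
    paths <- unlist(gwas, use.names = TRUE)
    labels <- names(paths) %||% basename(paths)
    if (is.null(names(paths)) || any(labels == "")) {
      stop_config("run_config: every GWAS input needs a label")
    }
    traits <- rep(NA_character_, length(paths))
  }
  if (anyDuplicated(labels)) stop_config("run_config: GWAS labels must be unique")
  if (anyDuplicated(paths)) stop_config("run_config: GWAS paths must be distinct")
  structure(list(
    gwas = data.frame(label = labels, path = unname(paths), trait = traits,
                      stringsAsFactors = FALSE),
    eqtl = eqtl, mqtl = mqtl,
    gwas_dialect = gwas_dialect, qtl_dialect = qtl_dialect,
    smr = smr_config(window_bp, p_qtl_max, alpha_policy),
    mqtl_mode = mqtl_mode, mqtl_source = mqtl_source,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file carries the same fields as [run_config()]; `gwas` is a mapping
#' of label to path, or a sequence of `{path, label, trait}` entries.
#'
#' @param path configuration file, `.yaml`/`.yml` or `.json`.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(
    gwas = raw$gwas,
    eqtl = raw$eqtl,
    mqtl = raw$mqtl,
    gwas_dialect = raw$gwas_dialect %||% "generic",
    qtl_dialect = raw$qtl_dialect %||% "generic",
    window_bp = raw$window_bp %||% 1e6,
    p_qtl_max = raw$p_qtl_max %||% 5e-8,
    alpha_policy = raw$alpha_policy %||% "bonferroni",
    mqtl_mode = raw$mqtl_mode %||% "smr",
    mqtl_source = raw$mqtl_source,
    out_dir = raw$out_dir %||% "smr_run",
    seed = raw$seed %||% 1
  )
}

#' Run the full integration pipeline
#'
#' The staged workflow: read each GWAS, harmonize it against the eQTL
#' dataset, run the SMR screen, threshold, and write a per-label report;
#' write a gene-overlap report for each label pair sharing a trait; if an
#' mQTL dataset is configured, cross-reference the de-duplicated significant
#' SNPs against methylation evidence. A line-oriented JSON run log records
#' row counts, harmonization tallies, resolved thresholds and the package
#' version. All inputs are checked before anything is written; a failure in
#' one GWAS label is isolated, logged, and does not abort the others.
#'
#' @param config a [run_config()] or path to a YAML/JSON config file.
#' @return invisibly, a list: `results` and `significant` (per label),
#'   `overlap` (per label pair), `xref`, `report_paths`, `log_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  inputs <- c(config$gwas$path, config$eqtl, config$mqtl)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop_config("unreadable input(s), aborting before any writes: %s",
                paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  log_event <- function(...) {
    writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, null = "null",
                                digits = NA), log_con)
  }
  log_event(event = "start", version = as.character(utils::packageVersion("smrlink")),
            n_gwas_inputs = nrow(config$gwas),
            window_bp = config$smr$window_bp,
            p_qtl_max = config$smr$p_qtl_max,
            alpha_policy = config$smr$alpha_policy)

  eqtl <- read_qtl(config$eqtl, config$qtl_dialect)
  log_event(event = "read_qtl", path = config$eqtl, n_rows = nrow(eqtl),
            n_skipped = attr(eqtl, "n_skipped"),
            n_probes = length(unique(eqtl$probe_id)))

  results <- list(); significant <- list(); report_paths <- character()
  for (i in seq_len(nrow(config$gwas))) {
    label <- config$gwas$label[i]
    res <- tryCatch({
      gwas <- read_gwas(config$gwas$path[i], config$gwas_dialect)
      r <- run_smr(gwas, eqtl, config$smr)
      sig <- apply_threshold(r, config$smr$alpha_policy)
      path_all <- file.path(config$out_dir, paste0(label, "_smr.tsv"))
      path_sig <- file.path(config$out_dir, paste0(label, "_significant.tsv"))
      write_smr_results(r, path_all)
      write_smr_results(sig, path_sig)
      log_event(event = "smr", label = label, n_gwas_rows = nrow(gwas),
                n_gwas_skipped = attr(gwas, "n_skipped"),
                tally = as.list(attr(r, "tally")),
                n_probes_tested = attr(r, "n_probes_tested"),
                resolved_alpha = attr(sig, "alpha"),
                n_significant = nrow(sig))
      list(results = r, significant = sig, paths = c(path_all, path_sig))
    }, error = function(e) {
      log_event(event = "error", label = label, message = conditionMessage(e))
      warning(sprintf("label '%s' failed: %s", label, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    results[[label]] <- res$results
    significant[[label]] <- res$significant
    report_paths <- c(report_paths, res$paths)
  }

  overlap <- list()
  labs <- names(significant)
  if (length(labs) >= 2) {
    traits <- config$gwas$trait[match(labs, config$gwas$label)]
    for (a in seq_along(labs)) {
      for (b in seq_along(labs)) {
        if (a >= b) next
        if (!is.na(traits[a]) && !is.na(traits[b]) &&
            traits[a] != traits[b]) next
        genes <- overlap_genes(significant[[labs[a]]], significant[[labs[b]]])
        key <- paste(labs[a], labs[b], sep = "__")
        overlap[[key]] <- genes
        p <- file.path(config$out_dir, paste0("overlap_", key, ".tsv"))
        utils::write.table(data.frame(gene = genes), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        report_paths <- c(report_paths, p)
        log_event(event = "overlap", labels = c(labs[a], labs[b]),
                  n_shared_genes = length(genes))
      }
    }
  }

  xref <- NULL
  if (!is.null(config$mqtl) && length(significant)) {
    mqtl <- read_qtl(config$mqtl, config$qtl_dialect)
    if (!is.null(config$mqtl_source)) {
      mqtl <- filter_mqtl_records(mqtl, config$mqtl_source)
    }
    snps <- unique_snps(significant)
    if (config$mqtl_mode == "smr") {
      # reuse the first GWAS against the mQTL dataset to form instruments
      gwas1 <- read_gwas(config$gwas$path[1], config$gwas_dialect)
      mres <- suppressWarnings(run_smr(gwas1, mqtl, config$smr))
      xref <- cross_reference_mqtl(snps, mqtl_results = mres,
                                   alpha_policy = config$smr$alpha_policy,
                                   mode = "smr")
    } else {
      xref <- cross_reference_mqtl(snps, alpha_policy = config$smr$alpha_policy,
                                   mode = "lookup", mqtl_records = mqtl)
    }
    p <- file.path(config$out_dir, "mqtl_xref.tsv")
    write_crossref_results(xref, p)
    report_paths <- c(report_paths, p)
    s <- attr(xref, "summary")
    log_event(event = "mqtl_xref", mode = config$mqtl_mode,
              n_query = unname(s[["n_query"]]),
              n_with_any_hit = unname(s[["n_with_any_hit"]]))
  }
  log_event(event = "done", n_reports = length(report_paths))
  invisible(list(results = results, significant = significant,
                 overlap = overlap, xref = xref,
                 report_paths = report_paths, log_path = log_path))
}
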