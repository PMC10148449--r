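# One-config orchestration of the full workflow: read signal + PFB + cohort
# files, call CNVs, sample QC, automated signal review, per-contrast
# association with multiple-testing correction, gene-network annotation,
# and a wide multi-contrast summary table.

#' Default pipeline configuration
#'
#' @param signal_dir directory of per-sample signal TSVs.
#' @param pfb PFB file path (also supplies the probe map).
#' @param cohort cohort table path.
#' @param out_dir output directory.
#' @param genes optional gene BED path.
#' @param seed integer seed recorded in the manifest.
#' @param ... overrides for nested settings: `hmm` (list of [hmm_params()]
#'   arguments), `qc` (list of [qc_thresholds()] arguments), `assoc`
#'   (alpha_probe, merge_bp, contrasts, qc_filter, emit_unfiltered,
#'   restrict, restrict_stage).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(signal_dir, pfb, cohort, out_dir, genes = NULL,
                            seed = 1, ...) {
  cfg <- list(signal_dir = signal_dir, pfb = pfb, cohort = cohort,
              out_dir = out_dir, genes = genes, seed = seed,
              hmm = list(), qc = list(),
              assoc = list(alpha_probe = 0.05, merge_bp = 1e6,
                           contrasts = c("ADHD", "ASD", "ADHD+ASD", "NDD"),
                           qc_filter = TRUE, emit_unfiltered = FALSE,
                           restrict = FALSE, restrict_stage = "pre"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("hmm", "qc")) cfg[[nm]] <- dots[[nm]]
    else if (nm == "assoc") cfg$assoc <- utils::modifyList(cfg$assoc, dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(y[c("signal_dir", "pfb", "cohort", "out_dir")],
            list(genes = y$genes, seed = y$seed %||% 1),
            y[intersect(c("hmm", "qc", "assoc"), names(y))]))
}

#' Run the full CNV association pipeline
#'
#' Stages, in order: read inputs, HMM CNV calling, sample QC (call rate,
#' LRR SD, large syndromic events), automated signal review, per-contrast
#' probe-level Fisher association collapsed to CNVRs, multiple-testing
#' correction, gene-network annotation, summary rendering. All outputs are
#' TSV/JSON under `out_dir`; the manifest records the seed, package version
#' and a hash of the configuration, and a rerun with the same configuration
#' reproduces identical tables.
#'
#' @param config a `pipeline_config` or YAML path.
#' @return invisibly, a list with calls, QC tables, per-contrast results and
#'   the summary table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop_arg("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    logf("stage %s: done", name)
    res
  }

  probes <- stage("read_inputs", read_pfb(config$pfb))
  cohort <- read_cohort_table(config$cohort)
  files <- list.files(config$signal_dir, pattern = "\\.signal\\.tsv$",
                      full.names = TRUE)
  assert_that(length(files) > 0, "no signal files found in signal_dir")
  samples <- lapply(files, read_signal_file, probes = probes)
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  m <- match(names(samples), cohort$sample_id)
  assert_that(!anyNA(m), "signal files present for samples missing from the cohort table")
  for (i in seq_along(samples)) {
    samples[[i]]$cohort <- cohort$cohort[m[i]]
    samples[[i]]$subphenotype <- cohort$subphenotype[m[i]]
  }

  params <- do.call(hmm_params, config$hmm)
  calls <- stage("cnv_calling", call_cohort(samples, probes, params))
  write_rawcnv(calls, file.path(out_dir, "calls.rawcnv"))

  qc_report <- stage("sample_qc", sample_qc_cohort(samples, calls))
  utils::write.table(qc_report, file.path(out_dir, "sample_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kept_ids <- qc_report$sample_id[!qc_report$excluded]
  kept_calls <- calls[calls$sample_id %in% kept_ids, , drop = FALSE]
  kept_cohort <- cohort[cohort$sample_id %in% kept_ids, , drop = FALSE]

  thresholds <- do.call(qc_thresholds, config$qc)
  review <- stage("signal_review", qc_filter(kept_calls, samples, probes, thresholds))
  utils::write.table(review$verdicts, file.path(out_dir, "call_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  geneset <- if (!is.null(config$genes)) load_gene_bed(config$genes) else NULL
  ac <- config$assoc
  assoc_input <- if (isTRUE(ac$qc_filter)) review$passed_calls else kept_calls
  results <- stage("association",
                   run_association(assoc_input, kept_cohort, probes,
                                   contrasts = ac$contrasts,
                                   alpha_probe = ac$alpha_probe,
                                   merge_bp = ac$merge_bp, geneset = geneset,
                                   restrict = isTRUE(ac$restrict),
                                   restrict_stage = ac$restrict_stage))
  for (ct in names(results)) {
    utils::write.table(cnvr_table(results[[ct]]),
                       file.path(out_dir, sprintf("assoc_%s.tsv", gsub("\\+", "", ct))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(ac$emit_unfiltered) && isTRUE(ac$qc_filter)) {
    unf <- stage("association_unfiltered",
                 run_association(kept_calls, kept_cohort, probes,
                                 contrasts = ac$contrasts,
                                 alpha_probe = ac$alpha_probe,
                                 merge_bp = ac$merge_bp, geneset = geneset,
                                 restrict = isTRUE(ac$restrict),
                                 restrict_stage = ac$restrict_stage))
    for (ct in names(unf)) {
      utils::write.table(cnvr_table(unf[[ct]]),
                         file.path(out_dir,
                                   sprintf("assoc_unfiltered_%s.tsv", gsub("\\+", "", ct))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary_tab <- stage("summary", render_summary(results))
  utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(package = "cnvflow",
                   version = as.character(utils::packageVersion("cnvflow")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   n_samples = length(samples),
                   n_calls = nrow(calls),
                   n_calls_passed = nrow(review$passed_calls),
                   contrasts = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete")
  invisible(list(probes = probes, samples = samples, calls = calls,
                 sample_qc = qc_report, verdicts = review$verdicts,
                 passed_calls = review$passed_calls, results = results,
                 summary = summary_tab, manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a wide multi-contrast summary table
#'
#' Aligns CNVRs across contrasts (same class, >= 1 bp overlap), yielding one
#' row per locus/class with a p/OR column pair per contrast and a flag for
#' the most significant contrast of each row.
#'
#' @param results named list of per-contrast CNVR tables.
#' @return wide data frame, one row per aligned locus.
#' @export
render_summary <- function(results) {
  assert_that(length(results) >= 1, "need at least one contrast table")
  all <- do.call(rbind, lapply(names(results), function(ct) {
    r <- results[[ct]]
    if (nrow(r) == 0) return(NULL)
    data.frame(contrast = ct, chrom = r$chrom, start_bp = r$start_bp,
               end_bp = r$end_bp, class = r$class, p_raw = r$p_raw,
               odds_ratio = r$odds_ratio, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all))
    return(data.frame(locus = character(), class = character(),
                      best_contrast = character(), stringsAsFactors = FALSE))

  # cluster rows of one class by interval overlap (transitive)
  all$cluster <- NA_integer_
  next_id <- 1L
  for (cl in unique(all$class)) for (ch in unique(all$chrom)) {
    rows <- which(all$class == cl & all$chrom == ch)
    rows <- rows[order(all$start_bp[rows])]
    if (length(rows) == 0) next
    cur_end <- -Inf
    for (r in rows) {
      if (all$start_bp[r] > cur_end) next_id <- next_id + 1L
      all$cluster[r] <- next_id
      cur_end <- max(cur_end, all$end_bp[r])
    }
  }

  rows <- lapply(split(all, all$cluster), function(g) {
    row <- data.frame(locus = sprintf("%s:%d-%d", g$chrom[1], min(g$start_bp),
                                      max(g$end_bp)),
                      class = g$class[1], stringsAsFactors = FALSE)
    for (ct in names(results)) {
      hit <- g[g$contrast == ct, , drop = FALSE]
      row[[paste0("p_", ct)]] <- if (nrow(hit) > 0) min(hit$p_raw) else NA_real_
      row[[paste0("or_", ct)]] <- if (nrow(hit) > 0)
        hit$odds_ratio[which.min(hit$p_raw)] else NA_real_
      row[[paste0("sig_", ct)]] <- if (nrow(hit) > 0) any(hit$significant) else NA
    }
    pcols <- paste0("p_", names(results))
    ps <- unlist(row[pcols])
    row$best_contrast <- names(results)[which.min(ps)]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(chrom_order(sub(":.*", "", out$locus)),
            as.numeric(sub(".*:(\\d+)-.*", "\\1", out$locus))), , drop = FALSE]
}
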