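# Gene-network restriction: interval overlap between CNVRs (or calls) and a
# named set of gene intervals, in the style of the 273-gene mGluR (GRM 1-8
# one/two-degree protein-interaction) network used for NDD CNV screens. Any
# BED gene list is accepted; the set is data, not code.

#' Construct a gene set from intervals
#' @param name set name.
#' @param genes data frame with `symbol`, `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive).
#' @return a `gene_set`.
#' @export
gene_set <- function(name, genes) {
  need <- c("symbol", "chrom", "start_bp", "end_bp")
  assert_that(all(need %in% names(genes)),
              paste("genes must have columns:", paste(need, collapse = ", ")))
  assert_that(all(genes$end_bp >= genes$start_bp), "gene intervals must have end >= start")
  assert_that(!anyDuplicated(genes$symbol), "gene symbols must be unique")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Load a gene set from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to 1-based inclusive.
#' Duplicate symbols are collapsed to the union interval with a warning.
#'
#' @param path BED file with at least chrom, start, end, name columns.
#' @param name gene-set name (defaults to the file name).
#' @return a `gene_set`.
#' @export
load_gene_bed <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    warning("gene BED ", path, " is empty", call. = FALSE)
    return(gene_set(name, data.frame(symbol = character(), chrom = character(),
                                     start_bp = integer(), end_bp = integer(),
                                     stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad) > 0)
    stop_arg("malformed BED line ", bad[1], " in ", path,
             " (need chrom, start, end, name)")
  df <- data.frame(chrom = vapply(parts, `[[`, character(1), 1),
                   start0 = suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2))),
                   end0 = suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3))),
                   symbol = vapply(parts, `[[`, character(1), 4),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start0) | is.na(df$end0) | df$end0 <= df$start0)
  if (length(bad) > 0)
    stop_arg("malformed BED line ", bad[1], " in ", path,
             " (non-numeric or empty interval)")
  df$start_bp <- df$start0 + 1L   # BED 0-based half-open -> 1-based inclusive
  df$end_bp <- df$end0
  if (anyDuplicated(df$symbol)) {
    warning("duplicate gene symbols collapsed to union intervals", call. = FALSE)
    df <- do.call(rbind, lapply(split(df, df$symbol), function(g)
      data.frame(chrom = g$chrom[1], symbol = g$symbol[1],
                 start_bp = min(g$start_bp), end_bp = max(g$end_bp),
                 stringsAsFactors = FALSE)))
  }
  gene_set(name, df[, c("symbol", "chrom", "start_bp", "end_bp")])
}

overlaps_genes <- function(chrom, start_bp, end_bp, genes) {
  hit <- genes$chrom == chrom & genes$start_bp <= end_bp & genes$end_bp >= start_bp
  sort(genes$symbol[hit])
}

#' Annotate CNVRs with overlapping genes, optionally restricting to the set
#'
#' A gene is assigned when its interval overlaps the CNVR by at least 1 bp;
#' gene names are listed alphabetically. In `restrict` mode CNVRs with no
#' overlapping gene are dropped. Annotation is idempotent.
#'
#' @param cnvrs CNVR data frame.
#' @param geneset a `gene_set`.
#' @param mode `"annotate"` or `"restrict"`.
#' @return the annotated (and possibly filtered) CNVR table with a `genes`
#'   column (comma-separated symbols).
#' @export
annotate_and_restrict <- function(cnvrs, geneset, mode = c("annotate", "restrict")) {
  mode <- match.arg(mode)
  if (nrow(cnvrs) == 0) { cnvrs$genes <- character(0); return(cnvrs) }
  cnvrs$genes <- vapply(seq_len(nrow(cnvrs)), function(i)
    paste(overlaps_genes(cnvrs$chrom[i], cnvrs$start_bp[i], cnvrs$end_bp[i],
                         geneset$genes), collapse = ","), character(1))
  if (mode == "restrict") cnvrs <- cnvrs[nzchar(cnvrs$genes), , drop = FALSE]
  rownames(cnvrs) <- NULL
  cnvrs
}

#' Restrict a call set to calls overlapping a gene set
#' @param calls call data frame.
#' @param geneset a `gene_set`.
#' @export
restrict_calls_to_geneset <- function(calls, geneset) {
  if (nrow(calls) == 0) return(calls)
  keep <- vapply(seq_len(nrow(calls)), function(i)
    length(overlaps_genes(calls$chrom[i], calls$start_bp[i], calls$end_bp[i],
                          geneset$genes)) > 0, logical(1))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count samples carrying in-network CNVs, per cohort cell
#'
#' Tallies the distinct samples with at least one passed call overlapping
#' the gene set, broken down by cohort and case subphenotype (and sex when
#' a `sex` column is present in the metadata).
#'
#' @param calls passed call data frame.
#' @param cohort sample metadata (`sample_id`, `cohort`, `subphenotype`,
#'   optional `sex`).
#' @param geneset a `gene_set`.
#' @return data frame of cell counts (`n_samples` per cell) including
#'   zero-count cells for every observed cohort/subphenotype combination.
#' @export
network_burden_summary <- function(calls, cohort, geneset) {
  in_net <- restrict_calls_to_geneset(calls, geneset)
  carriers <- unique(in_net$sample_id)
  cohort$carrier <- cohort$sample_id %in% carriers
  cells <- c("cohort", "subphenotype", intersect("sex", names(cohort)))
  agg <- stats::aggregate(cohort$carrier,
                          by = lapply(cohort[cells], function(x)
                            ifelse(is.na(x), "-", as.character(x))),
                          FUN = sum)
  names(agg) <- c(cells, "n_samples")
  agg[order(agg$cohort, agg[[2]]), , drop = FALSE]
}
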