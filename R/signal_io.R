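# Signal-file I/O in the PennCNV split-signal dialect: one TSV per sample
# with columns Name, Chr, Position, "<sample>.Log R Ratio",
# "<sample>.B Allele Freq", "<sample>.GType".

#' Write per-sample signal files
#'
#' @param samples list of `sample_signal` objects.
#' @param probes the aligned `probe_map`.
#' @param directory output directory (created if missing).
#' @return character vector of file paths, named by sample id.
#' @export
write_signal_files <- function(samples, probes, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(samples, function(s) {
    path <- file.path(directory, paste0(s$sample_id, ".signal.tsv"))
    df <- data.frame(probes$probe_id, probes$chrom, probes$pos_bp,
                     sprintf("%.4f", s$lrr), sprintf("%.4f", s$baf),
                     s$genotype, stringsAsFactors = FALSE)
    names(df) <- c("Name", "Chr", "Position",
                   paste0(s$sample_id, c(".Log R Ratio", ".B Allele Freq", ".GType")))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  names(paths) <- vapply(samples, `[[`, character(1), "sample_id")
  paths
}

#' Read one sample's signal file
#'
#' Reads a split-signal TSV back into a `sample_signal`, validating it
#' against the probe map. Rows in a different order than the map are
#' reordered on probe id with a warning; a probe set that does not match the
#' map, or a missing signal column, is a format error.
#'
#' @param path signal TSV path.
#' @param probes the `probe_map` the file must align to.
#' @param cohort,subphenotype optional sample metadata to attach.
#' @return a `sample_signal`.
#' @export
read_signal_file <- function(path, probes, cohort = NA_character_,
                             subphenotype = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)
  lrr_col <- grep("\\.Log R Ratio$", cols, value = TRUE)
  baf_col <- grep("\\.B Allele Freq$", cols, value = TRUE)
  gt_col <- grep("\\.GType$", cols, value = TRUE)
  if (!("Name" %in% cols) || length(lrr_col) != 1 || length(baf_col) != 1 ||
      length(gt_col) != 1)
    stop_arg("signal file ", path,
             " is missing required columns (Name, .Log R Ratio, .B Allele Freq, .GType)")
  if (nrow(df) != nrow(probes))
    stop_arg("signal file ", path, " has ", nrow(df), " probes; probe map has ",
             nrow(probes))
  if (!identical(df$Name, probes$probe_id)) {
    m <- match(probes$probe_id, df$Name)
    if (anyNA(m)) {
      first <- probes$probe_id[which(is.na(m))[1]]
      stop_arg("signal file ", path, " does not match the probe map; first ",
               "missing probe: ", first)
    }
    warning("signal file ", path, " reordered to match the probe map",
            call. = FALSE)
    df <- df[m, , drop = FALSE]
  }
  sample_id <- sub("\\.Log R Ratio$", "", lrr_col)
  new_sample_signal(sample_id, cohort, subphenotype,
                    list(lrr = as.numeric(df[[lrr_col]]),
                         baf = as.numeric(df[[baf_col]]),
                         genotype = as.character(df[[gt_col]])))
}

#' Write / read a PFB file (Name, Chr, Position, PFB)
#' @param probes a `probe_map`.
#' @param path file path.
#' @return `write_pfb` returns the path; `read_pfb` a `probe_map`.
#' @export
write_pfb <- function(probes, path) {
  df <- data.frame(Name = probes$probe_id, Chr = probes$chrom,
                   Position = probes$pos_bp, PFB = sprintf("%.4f", probes$pfb))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pfb
#' @export
read_pfb <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Name", "Chr", "Position", "PFB")
  if (!all(need %in% names(df)))
    stop_arg("PFB file ", path, " must have columns ", paste(need, collapse = ", "))
  out <- data.frame(probe_id = as.character(df$Name), chrom = as.character(df$Chr),
                    pos_bp = as.integer(df$Position), pfb = as.numeric(df$PFB),
                    stringsAsFactors = FALSE)
  validate_probe_map(out)
}

#' Write / read cohort metadata (sample_id, cohort, subphenotype)
#' @param cohort cohort table.
#' @param path file path.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(df)))
    stop_arg("cohort table must have sample_id and cohort columns")
  if (!"subphenotype" %in% names(df)) df$subphenotype <- NA_character_
  df
}
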