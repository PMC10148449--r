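#!/usr/bin/env Rscript
# Stage 4: probe-level Fisher association collapsed into CNVRs.
#
# Runs the four phenotype contrasts (ADHD, ASD, ADHD+ASD, pooled NDD; each
# against all controls) on the review-passed calls, corrects within each
# discovered family (Bonferroni, BH FDR, simpleM), and also emits the
# unfiltered (no signal review) results for comparison.

suppressPackageStartupMessages(library(cnvflow))

ind <- "results/simulated_cohort"
out <- "results/association"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

probes <- read_pfb(file.path(ind, "probes.pfb"))
cohort <- read_cohort_table(file.path(ind, "cohort.tsv"))
qc <- read.delim("results/calls/sample_qc.tsv")
kept_cohort <- cohort[cohort$sample_id %in% qc$sample_id[!qc$excluded], ]

passed <- read_rawcnv("results/review/calls_passed.rawcnv")
unfiltered <- read_rawcnv("results/calls/calls.rawcnv")
unfiltered <- unfiltered[unfiltered$sample_id %in% kept_cohort$sample_id, ]

contrasts <- c("ADHD", "ASD", "ADHD+ASD", "NDD")
res <- run_association(passed, kept_cohort, probes, contrasts = contrasts)
res_unf <- run_association(unfiltered, kept_cohort, probes, contrasts = contrasts)

for (ct in contrasts) {
  safe <- gsub("\\+", "", ct)
  write.table(cnvr_table(res[[ct]]),
              file.path(out, sprintf("assoc_%s.tsv", safe)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnvr_table(res_unf[[ct]]),
              file.path(out, sprintf("assoc_unfiltered_%s.tsv", safe)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

for (ct in contrasts) {
  r <- res[[ct]]
  cat(sprintf("%-9s: %d CNVRs, %d significant after correction\n",
              ct, nrow(r), sum(r$significant)))
}
n_sig <- sum(vapply(res, function(r) sum(r$significant), 1L))
n_sig_unf <- sum(vapply(res_unf, function(r) sum(r$significant), 1L))
cat(sprintf("significant CNVRs, reviewed vs unfiltered calls: %d vs %d\n",
            n_sig, n_sig_unf))
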