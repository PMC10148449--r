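#!/usr/bin/env Rscript
# Stage 2: HMM CNV calling and sample QC.
#
# Reads the simulated signal batch back through the file interfaces (as a
# real batch would arrive), decodes per-sample copy-number paths with the
# five-state HMM, writes a PennCNV-dialect rawcnv file, and applies the
# sample-level filters: call rate > 0.985, LRR SD < 0.30, no call > 10 Mb.

suppressPackageStartupMessages(library(cnvflow))

ind <- "results/simulated_cohort"
out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

probes <- read_pfb(file.path(ind, "probes.pfb"))
cohort <- read_cohort_table(file.path(ind, "cohort.tsv"))
files <- list.files(file.path(ind, "signal"), pattern = "\\.signal\\.tsv$",
                    full.names = TRUE)
samples <- lapply(files, read_signal_file, probes = probes)
names(samples) <- vapply(samples, `[[`, character(1), "sample_id")

calls <- call_cohort(samples, probes, hmm_params())
write_rawcnv(calls, file.path(out, "calls.rawcnv"))

qc <- sample_qc_cohort(samples, calls)
write.table(qc, file.path(out, "sample_qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim(file.path(ind, "ground_truth.tsv"))
cat(sprintf("%d calls in %d samples (%d truth carriages)\n",
            nrow(calls), length(samples), nrow(truth)))
cat(sprintf("samples excluded by QC: %d (%s)\n", sum(qc$excluded),
            paste(qc$exclusion_reason[qc$excluded], collapse = ", ")))
cat(sprintf("call copy-state table: %s\n",
            paste(names(table(calls$copy_state)), table(calls$copy_state),
                  sep = "=", collapse = " ")))
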