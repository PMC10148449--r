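#!/usr/bin/env Rscript
# Stage 3: automated "review first" signal validation.
#
# Every call is scored against the expected LRR shift and BAF cluster
# structure of its copy state, with diploid-looking flanks required; only
# passing calls go forward to association. Review plots are written for the
# first few calls as the human-readable audit trail.

suppressPackageStartupMessages(library(cnvflow))

ind <- "results/simulated_cohort"
out <- "results/review"
dir.create(file.path(out, "plots"), recursive = TRUE, showWarnings = FALSE)

probes <- read_pfb(file.path(ind, "probes.pfb"))
files <- list.files(file.path(ind, "signal"), pattern = "\\.signal\\.tsv$",
                    full.names = TRUE)
samples <- lapply(files, read_signal_file, probes = probes)
names(samples) <- vapply(samples, `[[`, character(1), "sample_id")

calls <- read_rawcnv("results/calls/calls.rawcnv")
qc <- read.delim("results/calls/sample_qc.tsv")
kept <- calls[calls$sample_id %in% qc$sample_id[!qc$excluded], , drop = FALSE]

review <- qc_filter(kept, samples, probes, qc_thresholds())
write.table(review$verdicts, file.path(out, "call_verdicts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_rawcnv(review$passed_calls, file.path(out, "calls_passed.rawcnv"))

for (i in seq_len(min(4, nrow(review$passed_calls)))) {
  call <- review$passed_calls[i, , drop = FALSE]
  plot_call(call, samples[[call$sample_id]], probes,
            file.path(out, "plots", sprintf("call_%02d.png", i)))
}

cat(sprintf("%d of %d calls passed signal review\n",
            nrow(review$passed_calls), nrow(kept)))
fails <- review$verdicts$fail_reasons[!review$verdicts$passed]
if (length(fails) > 0)
  cat("fail reasons:", paste(sort(unique(fails)), collapse = "; "), "\n")
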