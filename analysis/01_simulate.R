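#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Emulates a SNP-array case/control genotyping batch: a two-chromosome probe
# map (5 kb mean spacing), 120 cases and 120 controls, and four planted CNV
# loci. Two loci are case-enriched (a deletion and a duplication, mirroring
# the structure of NDD-associated CNVRs such as PRLHR deletions and 16p11.2
# duplications: rare in controls, several-fold enriched in cases) and two
# are frequency-matched null loci. Writes PennCNV-dialect signal files, a
# PFB file, the cohort table, a gene BED and the ground truth.

suppressPackageStartupMessages(library(cnvflow))

out <- "results/simulated_cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L

probes <- make_probe_map(n_probes = 4000, n_chrom = 2, spacing_bp = 5000,
                         pfb_source = "uniform", seed = seed)
model <- signal_model()  # conventional Illumina-like noise, 0.5% no-calls

events <- planted_events(
  probes,
  locus_id   = c("DEL_case", "DUP_case", "DEL_null", "DUP_null"),
  chrom      = c("chr1", "chr1", "chr2", "chr2"),
  start_bp   = probes$pos_bp[c(300, 1200, 2300, 3200)],
  end_bp     = probes$pos_bp[c(319, 1219, 2319, 3219)],
  copy_state = c(1L, 3L, 1L, 3L),
  freq_case    = c(0.10, 0.08, 0.05, 0.05),
  freq_control = c(0.01, 0.01, 0.05, 0.05))

sim <- simulate_cohort(probes, model, events, n_case = 120, n_control = 120,
                       seed = seed + 1L,
                       degraded_ids = "case_0001")  # one sample that fails QC

write_signal_files(sim$samples, probes, file.path(out, "signal"))
write_pfb(probes, file.path(out, "probes.pfb"))
write_cohort_table(sim$cohort, file.path(out, "cohort.tsv"))
write.table(sim$truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# a synthetic "network" gene list covering the two case-enriched loci plus
# two genes elsewhere; the null loci are deliberately off-network
bed <- file.path(out, "network_genes.synthetic.bed")
gene_rows <- function(lo, hi, sym)
  sprintf("%s\t%d\t%d\t%s", probes$chrom[lo], probes$pos_bp[lo] - 1L,
          probes$pos_bp[hi], sym)
writeLines(c(gene_rows(290, 330, "NETG1"), gene_rows(1190, 1230, "NETG2"),
             gene_rows(700, 720, "NETG3"), gene_rows(2600, 2620, "NETG4")),
           bed)

cat(sprintf("simulated %d samples over %d probes; %d carried events\n",
            length(sim$samples), nrow(probes), nrow(sim$truth)))
cat(sprintf("outputs in %s\n", out))
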