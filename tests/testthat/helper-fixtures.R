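# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is stored on disk.

# Small two-chromosome probe map with uniform PFB.
fixture_probes <- function(n = 1000, n_chrom = 2, seed = 7) {
  make_probe_map(n, n_chrom = n_chrom, spacing_bp = 5000, seed = seed)
}

# One deletion and one duplication locus, 20 probes each, planted at
# differential case/control frequency.
fixture_events <- function(probes, freq_case = 0.3, freq_control = 0.05,
                           width = 20L) {
  chroms <- unique(probes$chrom)
  idx1 <- which(probes$chrom == chroms[1])
  idx2 <- which(probes$chrom == chroms[2])
  s1 <- idx1[floor(length(idx1) / 3)]
  s2 <- idx2[floor(length(idx2) / 3)]
  stopifnot(s1 + width - 1L <= max(idx1), s2 + width - 1L <= max(idx2))
  planted_events(probes,
                 locus_id = c("delA", "dupB"),
                 chrom = c("chr1", "chr2"),
                 start_bp = probes$pos_bp[c(s1, s2)],
                 end_bp = probes$pos_bp[c(s1 + width - 1L, s2 + width - 1L)],
                 copy_state = c(1L, 3L),
                 freq_case = rep(freq_case, 2),
                 freq_control = rep(freq_control, 2))
}

fixture_cohort_sim <- function(n_case = 20, n_control = 20, seed = 11,
                               probes = fixture_probes(),
                               model = signal_model(),
                               events = fixture_events(probes)) {
  simulate_cohort(probes, model, events, n_case, n_control, seed = seed)
}

# A one-row call data frame over an explicit probe index span.
fixture_call <- function(probes, sample_id, lo, hi, cn) {
  data.frame(sample_id = sample_id, chrom = probes$chrom[lo],
             start_bp = probes$pos_bp[lo], end_bp = probes$pos_bp[hi],
             start_probe = probes$probe_id[lo], end_probe = probes$probe_id[hi],
             n_probes = hi - lo + 1L, copy_state = as.integer(cn),
             length_bp = probes$pos_bp[hi] - probes$pos_bp[lo] + 1L,
             conf = NA_real_, stringsAsFactors = FALSE)
}

# Synthetic gene BED covering given probe index intervals.
write_fixture_bed <- function(probes, spans, symbols, path) {
  lines <- vapply(seq_along(spans), function(i) {
    lo <- spans[[i]][1]; hi <- spans[[i]][2]
    sprintf("%s\t%d\t%d\t%s", probes$chrom[lo], probes$pos_bp[lo] - 1L,
            probes$pos_bp[hi], symbols[i])
  }, character(1))
  writeLines(lines, path)
  path
}
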