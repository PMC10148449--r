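#' Generative signal model for SNP-array intensity tracks
#'
#' Parameterises per-copy-state Log R Ratio (LRR) emission Gaussians and the
#' B-allele-frequency (BAF) cluster spread used both by the simulator and, by
#' default, by the copy-number HMM.
#'
#' LRR means follow conventional Illumina-array behaviour: strongly negative
#' and noisy for homozygous loss (copy number 0, where only background signal
#' remains), moderately negative for hemizygous loss, zero for diploid, and
#' increasingly positive for one- and two-copy gains. BAF clusters sit at
#' k/cn for k B alleles among cn copies: \{0, 1\} at cn = 1; \{0, 0.5, 1\} at
#' cn = 2; \{0, 1/3, 2/3, 1\} at cn = 3; \{0, 0.25, 0.5, 0.75, 1\} at cn = 4;
#' at cn = 0 the BAF is diffuse (uniform noise). Boundary clusters (0 and 1)
#' are half-Gaussians, matching the hard floor/ceiling of BAF.
#'
#' @param lrr_mean named numeric, LRR mean per copy state `"0" ... "4"`;
#'   must be non-decreasing over states 1..4 with the diploid mean fixed at 0.
#' @param lrr_sd named numeric, LRR standard deviation per copy state (> 0).
#' @param baf_sd spread of each BAF cluster (> 0).
#' @param nocall_rate probability that a probe's genotype call fails (signal
#'   is retained); the default 0.005 leaves unmodified samples above the
#'   0.985 call-rate threshold of sample QC.
#' @return a `signal_model` list.
#' @export
signal_model <- function(lrr_mean = c(`0` = -3.5, `1` = -0.66, `2` = 0,
                                      `3` = 0.40, `4` = 0.68),
                         lrr_sd = c(`0` = 1.3, `1` = 0.18, `2` = 0.18,
                                    `3` = 0.18, `4` = 0.18),
                         baf_sd = 0.03,
                         nocall_rate = 0.005) {
  states <- as.character(0:4)
  assert_that(all(states %in% names(lrr_mean)) && all(states %in% names(lrr_sd)),
              "lrr_mean and lrr_sd must be named for copy states 0..4")
  lrr_mean <- lrr_mean[states]; lrr_sd <- lrr_sd[states]
  assert_that(all(lrr_sd > 0), "lrr_sd must be positive")
  assert_that(all(diff(lrr_mean[as.character(1:4)]) >= 0),
              "lrr_mean must be non-decreasing over copy states 1..4")
  assert_that(abs(lrr_mean[["2"]]) < 1e-12, "diploid lrr_mean must be 0")
  assert_that(baf_sd > 0, "baf_sd must be positive")
  assert_that(nocall_rate >= 0 && nocall_rate <= 1, "nocall_rate must be in [0, 1]")
  structure(list(lrr_mean = lrr_mean, lrr_sd = lrr_sd,
                 baf_sd = baf_sd, nocall_rate = nocall_rate),
            class = "signal_model")
}

# BAF cluster centers for a copy state (NULL for cn0: diffuse).
baf_centers <- function(cn) {
  if (cn == 0) return(NULL)
  (0:cn) / cn
}

#' Define planted CNV events for a simulated cohort
#'
#' Builds and validates the table of loci planted at differential frequencies
#' in cases and controls. Events must fall inside the probe map and must not
#' overlap one another (nested or overlapping CNVs are not modelled). Events
#' covering fewer than 3 probes sit below the caller's detection floor and
#' are flagged `detectable = FALSE` so downstream accuracy bookkeeping can
#' exclude them.
#'
#' @param probes a `probe_map`.
#' @param locus_id,chrom,start_bp,end_bp,copy_state,freq_case,freq_control
#'   parallel vectors, one entry per event; `copy_state` in \{0, 1, 3, 4\},
#'   intervals 1-based inclusive, frequencies in \[0, 1\].
#' @return a `planted_events` data frame with added `n_probes` and
#'   `detectable` columns.
#' @export
planted_events <- function(probes, locus_id, chrom, start_bp, end_bp,
                           copy_state, freq_case, freq_control) {
  ev <- data.frame(locus_id = as.character(locus_id), chrom = as.character(chrom),
                   start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                   copy_state = as.integer(copy_state),
                   freq_case = freq_case, freq_control = freq_control,
                   stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(ev$locus_id), "locus_id must be unique")
  assert_that(all(ev$copy_state %in% c(0L, 1L, 3L, 4L)),
              "copy_state must be one of 0, 1, 3, 4")
  assert_that(all(ev$end_bp >= ev$start_bp), "end_bp must be >= start_bp")
  assert_that(all(ev$freq_case >= 0 & ev$freq_case <= 1 &
                  ev$freq_control >= 0 & ev$freq_control <= 1),
              "event frequencies must lie in [0, 1]")
  for (i in seq_len(nrow(ev))) {
    ch <- ev$chrom[i]
    assert_that(ch %in% probes$chrom,
                paste0("event ", ev$locus_id[i], " on unknown chromosome ", ch))
    rng <- range(probes$pos_bp[probes$chrom == ch])
    assert_that(ev$start_bp[i] >= 1 && ev$end_bp[i] <= rng[2],
                paste0("event ", ev$locus_id[i], " lies outside the probe map"))
  }
  # pairwise overlap check (per chromosome)
  if (nrow(ev) > 1) {
    for (ch in unique(ev$chrom)) {
      e <- ev[ev$chrom == ch, , drop = FALSE]
      e <- e[order(e$start_bp), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start_bp[-1] <= e$end_bp[-nrow(e)]))
        stop_arg("planted events must not overlap")
    }
  }
  ev$n_probes <- vapply(seq_len(nrow(ev)), function(i)
    length(probe_indices(probes, ev$chrom[i], ev$start_bp[i], ev$end_bp[i])), 1L)
  ev$detectable <- ev$n_probes >= 3L
  class(ev) <- c("planted_events", "data.frame")
  ev
}
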