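#' Sample-level quality control
#'
#' Applies the array-quality and syndromic-event filters: a sample is
#' excluded if its genotype call rate is not above 0.985, if the standard
#' deviation of its LRR track is not below 0.30, or if it carries any call
#' longer than 10 Mb (large events with syndromic implications are handled
#' clinically, not in cohort association). The first matching reason, in
#' that order, is recorded.
#'
#' @param sample a `sample_signal`.
#' @param calls calls made on this sample (data frame as from
#'   [viterbi_call()]).
#' @param cr_min minimum call rate (exclusive bound; default 0.985).
#' @param lrr_sd_max maximum LRR standard deviation (exclusive; default 0.30).
#' @param max_event_bp maximum tolerated call length in bp (default 1e7).
#' @return one-row data frame: `sample_id`, `call_rate`, `lrr_sd`, `n_calls`,
#'   `max_call_length_bp`, `excluded`, `exclusion_reason`.
#' @export
sample_qc <- function(sample, calls, cr_min = 0.985, lrr_sd_max = 0.30,
                      max_event_bp = 1e7) {
  calls <- calls[calls$sample_id == sample$sample_id, , drop = FALSE]
  max_len <- if (nrow(calls) > 0) max(calls$length_bp) else 0L
  reason <- "none"
  if (sample$call_rate <= cr_min) reason <- "low_call_rate"
  else if (sample$lrr_sd >= lrr_sd_max) reason <- "high_lrr_sd"
  else if (max_len > max_event_bp) reason <- "large_event"
  data.frame(sample_id = sample$sample_id,
             call_rate = sample$call_rate,
             lrr_sd = sample$lrr_sd,
             n_calls = nrow(calls),
             max_call_length_bp = max_len,
             excluded = reason != "none",
             exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' QC every sample in a cohort
#' @param samples list of `sample_signal`.
#' @param calls combined call table.
#' @param ... thresholds passed to [sample_qc()].
#' @return data frame, one row per sample.
#' @export
sample_qc_cohort <- function(samples, calls, ...) {
  out <- do.call(rbind, lapply(samples, sample_qc, calls = calls, ...))
  rownames(out) <- NULL
  out
}
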