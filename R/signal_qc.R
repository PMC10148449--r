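#' Thresholds for automated signal review of CNV calls
#'
#' Quantifies the visual-review rules used to vet array CNV calls: a
#' deletion must show an LRR drop and essentially no heterozygous BAF; a
#' duplication must show an LRR rise and interior BAF clusters at the
#' positions its copy state implies (1/3 and 2/3 for one-copy gains, 1/4,
#' 1/2 and 3/4 for two-copy gains); and the flanking region must look
#' diploid (LRR near zero with a normal heterozygosity fraction).
#'
#' @param del_lrr_max region median LRR must be below this for hemizygous
#'   deletions (default -0.25).
#' @param hom_del_lrr_max region median LRR bound for homozygous deletions
#'   (default -1.0; BAF is diffuse at cn = 0, so no heterozygosity test).
#' @param dup_lrr_min region median LRR must exceed this for duplications.
#' @param het_band open BAF interval counted as heterozygous.
#' @param het_frac_max_del maximum tolerated heterozygous fraction inside a
#'   deletion.
#' @param mid_cluster_tol BAF distance from an expected interior cluster
#'   within which a probe supports the duplication.
#' @param flank_lrr_band flank median LRR must be inside (-band, band).
#' @param flank_het_frac_min minimum heterozygous fraction among informative
#'   flank probes for the flank to count as diploid.
#' @param flank_width_probes flank width per side in probes; the effective
#'   width is `min(call width, flank_width_probes)`.
#' @param pfb_informative PFB range defining informative (polymorphic)
#'   probes; heterozygosity fractions are computed over these only.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(del_lrr_max = -0.25, hom_del_lrr_max = -1.0,
                          dup_lrr_min = 0.15, het_band = c(0.25, 0.75),
                          het_frac_max_del = 0.02, mid_cluster_tol = 0.07,
                          flank_lrr_band = 0.10, flank_het_frac_min = 0.10,
                          flank_width_probes = 50L,
                          pfb_informative = c(0.05, 0.95)) {
  assert_that(het_band[1] > 0 && het_band[2] < 1 && het_band[1] < het_band[2],
              "het_band must be an interval inside (0, 1)")
  assert_that(mid_cluster_tol > 0 && flank_lrr_band > 0 &&
              het_frac_max_del >= 0 && flank_het_frac_min >= 0,
              "tolerances must be positive")
  structure(list(del_lrr_max = del_lrr_max, hom_del_lrr_max = hom_del_lrr_max,
                 dup_lrr_min = dup_lrr_min, het_band = het_band,
                 het_frac_max_del = het_frac_max_del,
                 mid_cluster_tol = mid_cluster_tol,
                 flank_lrr_band = flank_lrr_band,
                 flank_het_frac_min = flank_het_frac_min,
                 flank_width_probes = as.integer(flank_width_probes),
                 pfb_informative = pfb_informative),
            class = "qc_thresholds")
}

# probe indices of the flanks (same chromosome, adjacent on both sides);
# one-sided at chromosome ends.
flank_indices <- function(probes, chrom, span, width) {
  chrom_idx <- which(probes$chrom == chrom)
  lo <- span[1]; hi <- span[length(span)]
  left <- chrom_idx[chrom_idx < lo]
  right <- chrom_idx[chrom_idx > hi]
  c(utils::tail(left, width), utils::head(right, width))
}

#' Score one CNV call against expected signal structure
#'
#' @param call one-row call data frame.
#' @param sample the carrying `sample_signal`.
#' @param probes the `probe_map`.
#' @param thresholds a `qc_thresholds`.
#' @return one-row verdict data frame with the region/flank metrics, a
#'   `passed` flag and a comma-separated `fail_reasons` string (empty iff
#'   passed).
#' @export
score_call <- function(call, sample, probes, thresholds = qc_thresholds()) {
  assert_that(call$sample_id == sample$sample_id,
              "call and sample belong to different sample ids")
  span <- probe_indices(probes, call$chrom, call$start_bp, call$end_bp)
  assert_that(length(span) > 0, "call span covers no probes of the map")
  th <- thresholds
  inform <- span[probes$pfb[span] >= th$pfb_informative[1] &
                 probes$pfb[span] <= th$pfb_informative[2]]
  width <- min(length(span), th$flank_width_probes)
  fl <- flank_indices(probes, call$chrom, span, width)
  fl_inform <- fl[probes$pfb[fl] >= th$pfb_informative[1] &
                  probes$pfb[fl] <= th$pfb_informative[2]]

  in_band <- function(x) x > th$het_band[1] & x < th$het_band[2]
  region_median_lrr <- stats::median(sample$lrr[span], na.rm = TRUE)
  region_het_frac <- if (length(inform) > 0)
    mean(in_band(sample$baf[inform]), na.rm = TRUE) else NA_real_

  cn <- call$copy_state
  interior <- switch(as.character(cn), `3` = c(1, 2) / 3,
                     `4` = c(0.25, 0.5, 0.75), NULL)
  near_cluster <- function(x) {
    if (is.null(interior)) return(rep(FALSE, length(x)))
    Reduce(`|`, lapply(interior, function(c0) abs(x - c0) <= th$mid_cluster_tol))
  }
  mid_cluster_frac <- if (length(inform) > 0)
    mean(near_cluster(sample$baf[inform]), na.rm = TRUE) else NA_real_
  off_cluster_frac <- if (length(inform) > 0)
    mean(in_band(sample$baf[inform]) & !near_cluster(sample$baf[inform]),
         na.rm = TRUE) else NA_real_

  flank_median_lrr <- if (length(fl) > 0)
    stats::median(sample$lrr[fl], na.rm = TRUE) else NA_real_
  flank_het_frac <- if (length(fl_inform) > 0)
    mean(in_band(sample$baf[fl_inform]), na.rm = TRUE) else NA_real_

  reasons <- character()
  if (length(inform) < 3) {
    reasons <- "too_few_informative_probes"
  } else {
    if (cn < 2) {
      lrr_cut <- if (cn == 0) th$hom_del_lrr_max else th$del_lrr_max
      if (!(region_median_lrr < lrr_cut)) reasons <- c(reasons, "lrr_shift_absent")
      if (cn == 1 && region_het_frac > th$het_frac_max_del)
        reasons <- c(reasons, "het_present_in_del")
    } else {
      if (!(region_median_lrr > th$dup_lrr_min))
        reasons <- c(reasons, "lrr_shift_absent")
      if (!(mid_cluster_frac > off_cluster_frac))
        reasons <- c(reasons, "dup_clusters_absent")
    }
    flank_ok <- !is.na(flank_median_lrr) && !is.na(flank_het_frac) &&
      abs(flank_median_lrr) < th$flank_lrr_band &&
      flank_het_frac >= th$flank_het_frac_min
    if (!flank_ok) reasons <- c(reasons, "flank_abnormal")
  }

  data.frame(sample_id = call$sample_id, chrom = call$chrom,
             start_bp = call$start_bp, end_bp = call$end_bp,
             copy_state = cn,
             region_median_lrr = region_median_lrr,
             region_het_frac = region_het_frac,
             mid_cluster_frac = mid_cluster_frac,
             flank_median_lrr = flank_median_lrr,
             flank_het_frac = flank_het_frac,
             passed = length(reasons) == 0,
             fail_reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Filter a call set by automated signal review
#'
#' Scores every call with [score_call()] and keeps the passes; the verdict
#' table preserves the input call order.
#'
#' @param calls call data frame.
#' @param samples named list of `sample_signal` (must cover every call).
#' @param probes a `probe_map`.
#' @param thresholds a `qc_thresholds`.
#' @return list with `passed_calls` and `verdicts`.
#' @export
qc_filter <- function(calls, samples, probes, thresholds = qc_thresholds()) {
  if (nrow(calls) == 0)
    return(list(passed_calls = calls,
                verdicts = score_call_empty()))
  missing <- setdiff(unique(calls$sample_id), names(samples))
  assert_that(length(missing) == 0,
              paste("no signal for sample(s):", paste(missing, collapse = ", ")))
  verdicts <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    score_call(calls[i, , drop = FALSE], samples[[calls$sample_id[i]]],
               probes, thresholds)))
  rownames(verdicts) <- NULL
  list(passed_calls = calls[verdicts$passed, , drop = FALSE],
       verdicts = verdicts)
}

score_call_empty <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = integer(), end_bp = integer(), copy_state = integer(),
             region_median_lrr = numeric(), region_het_frac = numeric(),
             mid_cluster_frac = numeric(), flank_median_lrr = numeric(),
             flank_het_frac = numeric(), passed = logical(),
             fail_reasons = character(), stringsAsFactors = FALSE)
}
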