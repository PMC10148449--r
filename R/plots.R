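#' Plot the LRR/BAF signal of one CNV call
#'
#' Two-panel scatter over genomic position (LRR top, BAF bottom) in the
#' style used for manual CNV review: points inside the call region are red,
#' flanking points are blue, with guide lines at the diploid LRR baseline
#' and the expected BAF cluster positions for the call's copy state.
#'
#' @param call one-row call data frame.
#' @param sample the carrying `sample_signal`.
#' @param probes a `probe_map`.
#' @param out_path PNG output path.
#' @param flank_probes flank width per side (probes).
#' @return `out_path`, invisibly.
#' @export
plot_call <- function(call, sample, probes, out_path, flank_probes = 50L) {
  span <- probe_indices(probes, call$chrom, call$start_bp, call$end_bp)
  assert_that(length(span) > 0, "call span covers no probes")
  fl <- flank_indices(probes, call$chrom, span, flank_probes)
  idx <- sort(c(fl, span))
  col <- ifelse(idx %in% span, "red", "blue")
  pos <- probes$pos_bp[idx] / 1e6

  grDevices::png(out_path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(pos, sample$lrr[idx], col = col, pch = 16, cex = 0.6,
                 xlab = "", ylab = "LRR",
                 main = sprintf("%s %s:%d-%d cn=%d", call$sample_id, call$chrom,
                                call$start_bp, call$end_bp, call$copy_state))
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::plot(pos, sample$baf[idx], col = col, pch = 16, cex = 0.6,
                 ylim = c(0, 1), xlab = sprintf("%s position (Mb)", call$chrom),
                 ylab = "BAF")
  centers <- baf_centers(call$copy_state) %||% c(0, 0.5, 1)
  graphics::abline(h = centers, lty = 3, col = "grey60")
  invisible(out_path)
}

#' Overlay the signal of every carrier of one CNVR
#'
#' Cohort-style review plot: all carriers' in-region points (red) and flank
#' points (blue) on shared LRR and BAF panels.
#'
#' @param cnvr one-row CNVR data frame.
#' @param calls passed calls overlapping the CNVR.
#' @param samples named list of `sample_signal`.
#' @param probes a `probe_map`.
#' @param out_path PNG output path.
#' @return `out_path`, invisibly.
#' @export
plot_cnvr <- function(cnvr, calls, samples, probes, out_path) {
  want_del <- cnvr$class == "Del"
  hit <- calls$chrom == cnvr$chrom & calls$start_bp <= cnvr$end_bp &
    calls$end_bp >= cnvr$start_bp &
    (if (want_del) calls$copy_state < 2 else calls$copy_state > 2)
  carriers <- calls[hit, , drop = FALSE]
  assert_that(nrow(carriers) > 0, "no carrier calls overlap the CNVR")

  grDevices::png(out_path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  pts <- lapply(seq_len(nrow(carriers)), function(i) {
    call <- carriers[i, , drop = FALSE]
    span <- probe_indices(probes, call$chrom, call$start_bp, call$end_bp)
    fl <- flank_indices(probes, call$chrom, span, min(length(span), 50L))
    idx <- sort(c(fl, span))
    s <- samples[[call$sample_id]]
    data.frame(pos = probes$pos_bp[idx] / 1e6, lrr = s$lrr[idx],
               baf = s$baf[idx],
               col = ifelse(idx %in% span, "red", "blue"))
  })
  pts <- do.call(rbind, pts)
  graphics::plot(pts$pos, pts$lrr, col = pts$col, pch = 16, cex = 0.4,
                 xlab = "", ylab = "LRR",
                 main = sprintf("%s %s %s:%d-%d (%d carrier calls)",
                                cnvr$cnvr_id, cnvr$class, cnvr$chrom,
                                cnvr$start_bp, cnvr$end_bp, nrow(carriers)))
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::plot(pts$pos, pts$baf, col = pts$col, pch = 16, cex = 0.4,
                 ylim = c(0, 1),
                 xlab = sprintf("%s position (Mb)", cnvr$chrom), ylab = "BAF")
  graphics::abline(h = c(0, 1/3, 0.5, 2/3, 1), lty = 3, col = "grey60")
  invisible(out_path)
}
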