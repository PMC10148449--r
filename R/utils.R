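`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_arg(msg)
  invisible(TRUE)
}

# Order chromosome labels numerically where possible ("chr2" before "chr10"),
# falling back to lexical order for X/Y/other labels.
chrom_order <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  factor(chrom, levels = u[ord])
}

# Split n items as evenly as possible into k groups.
split_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}
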