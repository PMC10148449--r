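#' Build a synthetic SNP-array probe map
#'
#' Generates an ordered genomic probe map in the style of an Illumina SNP
#' array annotation: probe identifiers, chromosome, base-pair position and the
#' population frequency of the B allele (PFB) used downstream as the allele
#' frequency prior of the copy-number HMM.
#'
#' Inter-probe gaps are drawn from an exponential distribution with mean
#' `spacing_bp`, which reproduces the irregular probe spacing of genotyping
#' arrays; positions are 1-based.
#'
#' @param n_probes total number of probes (>= n_chrom).
#' @param n_chrom number of chromosomes to spread the probes over; labels are
#'   `chr1 ... chrN`.
#' @param spacing_bp mean inter-probe gap in base pairs (> 0).
#' @param pfb_source `"uniform"` draws PFB from U(0, 1); `"beta"` draws from a
#'   U-shaped Beta(0.4, 0.4), mimicking the site-frequency spectrum of common
#'   SNPs where many probes are near-monomorphic.
#' @param seed integer seed; the map is a pure function of the arguments.
#' @return a `probe_map` data frame with columns `probe_id`, `chrom`,
#'   `pos_bp`, `pfb`, sorted by (chrom, pos_bp).
#' @examples
#' pm <- make_probe_map(100, n_chrom = 2, spacing_bp = 5000, seed = 1)
#' head(pm)
#' @export
make_probe_map <- function(n_probes, n_chrom = 1, spacing_bp = 5000,
                           pfb_source = c("uniform", "beta"), seed = 1) {
  pfb_source <- match.arg(pfb_source)
  assert_that(is.numeric(n_probes) && length(n_probes) == 1 && n_probes >= 1,
              "n_probes must be a positive integer")
  assert_that(is.numeric(n_chrom) && n_chrom >= 1, "n_chrom must be positive")
  assert_that(n_probes >= n_chrom, "n_probes must be >= n_chrom")
  assert_that(spacing_bp > 0, "spacing_bp must be > 0")
  n_probes <- as.integer(n_probes)
  n_chrom <- as.integer(n_chrom)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sizes <- split_sizes(n_probes, n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), times = sizes)
  gaps <- pmax(1, round(stats::rexp(n_probes, rate = 1 / spacing_bp)))
  pos <- unlist(lapply(split(gaps, chrom)[unique(chrom)], cumsum),
                use.names = FALSE)
  pfb <- switch(pfb_source,
                uniform = stats::runif(n_probes),
                beta = stats::rbeta(n_probes, 0.4, 0.4))
  out <- data.frame(
    probe_id = sprintf("rs%06d", seq_len(n_probes)),
    chrom = chrom,
    pos_bp = as.integer(pos),
    pfb = pfb,
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_map", "data.frame")
  validate_probe_map(out)
}

#' Validate a probe map
#'
#' Checks the structural invariants of a probe map: unique probe ids, PFB in
#' \[0, 1\], strictly increasing positions within each chromosome.
#'
#' @param probes a data frame with columns `probe_id`, `chrom`, `pos_bp`, `pfb`.
#' @return the validated `probe_map` (invisibly usable in pipelines).
#' @export
validate_probe_map <- function(probes) {
  need <- c("probe_id", "chrom", "pos_bp", "pfb")
  assert_that(all(need %in% names(probes)),
              paste("probe map must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(probes$probe_id), "probe_id must be unique")
  assert_that(all(probes$pfb >= 0 & probes$pfb <= 1), "pfb must lie in [0, 1]")
  for (ch in unique(probes$chrom)) {
    p <- probes$pos_bp[probes$chrom == ch]
    assert_that(all(diff(p) > 0),
                paste0("positions must be strictly increasing within ", ch))
  }
  if (!inherits(probes, "probe_map")) class(probes) <- c("probe_map", class(probes))
  probes
}

# Row indices of probes covered by a 1-based inclusive interval.
probe_indices <- function(probes, chrom, start_bp, end_bp) {
  which(probes$chrom == chrom & probes$pos_bp >= start_bp & probes$pos_bp <= end_bp)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
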