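# Probe-level case-control CNV association: per-probe carrier counts,
# Fisher's exact test per probe, collapse of significant probes into CNV
# regions (CNVRs), and multiple-testing correction within the family of
# discovered CNVRs (Bonferroni, Benjamini-Hochberg FDR, simpleM).

#' Per-probe CNV carrier counts
#'
#' Counts, at every probe, the distinct case and control samples carrying a
#' deletion (copy number < 2) or duplication (copy number > 2) call that
#' overlaps the probe. A sample contributes at most once per probe and class
#' no matter how many of its calls overlap.
#'
#' @param calls QC-passed call data frame.
#' @param cohort sample metadata of QC-passed samples (`sample_id`,
#'   `cohort`, optional `subphenotype`); every call's sample must appear.
#' @param probes a `probe_map`.
#' @return a `probe_burden` object: per-probe count matrix, cohort totals
#'   and the deduplicated per-sample carriage intervals (used later for the
#'   simpleM indicator matrix).
#' @export
probe_burden <- function(calls, cohort, probes) {
  missing <- setdiff(unique(calls$sample_id), cohort$sample_id)
  assert_that(length(missing) == 0,
              paste("call sample(s) absent from cohort table:",
                    paste(missing, collapse = ", ")))
  n <- nrow(probes)
  counts <- matrix(0L, n, 4,
                   dimnames = list(NULL, c("n_case_del", "n_ctrl_del",
                                           "n_case_dup", "n_ctrl_dup")))
  carriage <- NULL
  if (nrow(calls) > 0) {
    cls <- ifelse(calls$copy_state < 2, "del", "dup")
    lo <- integer(nrow(calls)); hi <- integer(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      idx <- probe_indices(probes, calls$chrom[i], calls$start_bp[i],
                           calls$end_bp[i])
      assert_that(length(idx) > 0,
                  paste0("call ", i, " overlaps no probe of the map"))
      lo[i] <- idx[1]; hi[i] <- idx[length(idx)]
    }
    carriage <- merge_sample_ranges(
      data.frame(sample_id = calls$sample_id, class = cls, lo = lo, hi = hi,
                 stringsAsFactors = FALSE))
    carriage$cohort <- cohort$cohort[match(carriage$sample_id, cohort$sample_id)]
    for (j in seq_len(nrow(carriage))) {
      colname <- paste0(if (carriage$cohort[j] == "case") "n_case_" else "n_ctrl_",
                        carriage$class[j])
      rng <- carriage$lo[j]:carriage$hi[j]
      counts[rng, colname] <- counts[rng, colname] + 1L
    }
  }
  structure(list(probes = probes,
                 counts = as.data.frame(counts),
                 n_case_total = sum(cohort$cohort == "case"),
                 n_ctrl_total = sum(cohort$cohort == "control"),
                 cohort = cohort,
                 carriage = carriage %||%
                   data.frame(sample_id = character(), class = character(),
                              lo = integer(), hi = integer(),
                              cohort = character(), stringsAsFactors = FALSE)),
            class = "probe_burden")
}

# Per (sample, class), merge overlapping/adjacent probe index ranges so a
# sample counts once per probe. Chromosomes never share probe indices, so
# merging on indices respects chromosome boundaries for overlap counting.
merge_sample_ranges <- function(rng) {
  pieces <- split(rng, paste(rng$sample_id, rng$class, sep = "\r"))
  out <- lapply(pieces, function(p) {
    p <- p[order(p$lo), , drop = FALSE]
    keep_lo <- p$lo[1]; keep_hi <- p$hi[1]
    res <- list()
    if (nrow(p) > 1) for (i in 2:nrow(p)) {
      if (p$lo[i] <= keep_hi + 1L) keep_hi <- max(keep_hi, p$hi[i])
      else { res[[length(res) + 1]] <- c(keep_lo, keep_hi)
             keep_lo <- p$lo[i]; keep_hi <- p$hi[i] }
    }
    res[[length(res) + 1]] <- c(keep_lo, keep_hi)
    m <- do.call(rbind, res)
    data.frame(sample_id = p$sample_id[1], class = p$class[1],
               lo = m[, 1], hi = m[, 2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collapse significant probes into CNV regions
#'
#' Runs Fisher's exact test at every probe with at least one carrier,
#' separately for deletions and duplications, then merges significant
#' probes (p < `alpha_probe`) of the same class and chromosome into a CNVR
#' whenever consecutive significant probes are at most `merge_bp` apart
#' (intervening non-significant probes do not break a region). The region's
#' reported statistics are taken at the peak probe: the regional minimum p,
#' smallest position on ties.
#'
#' @param burden a `probe_burden`.
#' @param alpha_probe per-probe significance cut for region membership.
#' @param merge_bp maximum distance between consecutive significant probes
#'   of one region (default 1 Mb).
#' @return data frame of CNVRs (`cnvr_id`, `chrom`, `start_bp`, `end_bp`,
#'   `class`, `peak_probe`, `a`, `b`, `p_raw`, `odds_ratio`, plus cohort
#'   totals and a `member_idx` list column of member probe indices).
#' @export
collapse_cnvr <- function(burden, alpha_probe = 0.05, merge_bp = 1e6) {
  assert_that(inherits(burden, "probe_burden"), "burden must be a probe_burden")
  probes <- burden$probes
  out <- list()
  for (class in c("del", "dup")) {
    a <- burden$counts[[paste0("n_case_", class)]]
    b <- burden$counts[[paste0("n_ctrl_", class)]]
    any_carrier <- which(a + b > 0)
    if (length(any_carrier) == 0) next
    # dedup identical count pairs before testing
    key <- paste(a[any_carrier], b[any_carrier])
    uk <- !duplicated(key)
    f <- fisher_p_or(a[any_carrier][uk], b[any_carrier][uk],
                     burden$n_case_total, burden$n_ctrl_total)
    p <- rep(1, nrow(probes))
    or <- rep(NA_real_, nrow(probes))
    m <- match(key, key[uk])
    p[any_carrier] <- f$p[m]
    or[any_carrier] <- f$odds_ratio[m]

    sig <- which(p < alpha_probe)
    if (length(sig) == 0) next
    for (ch in unique(probes$chrom[sig])) {
      s <- sig[probes$chrom[sig] == ch]
      s <- s[order(probes$pos_bp[s])]
      gap_break <- c(TRUE, diff(probes$pos_bp[s]) > merge_bp)
      grp <- cumsum(gap_break)
      for (g in unique(grp)) {
        mem <- s[grp == g]
        peak <- mem[order(p[mem], probes$pos_bp[mem])][1]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch,
          start_bp = probes$pos_bp[mem[1]],
          end_bp = probes$pos_bp[mem[length(mem)]],
          class = if (class == "del") "Del" else "Dup",
          peak_probe = probes$probe_id[peak],
          a = a[peak], b = b[peak],
          n_case_total = burden$n_case_total,
          n_ctrl_total = burden$n_ctrl_total,
          p_raw = p[peak], odds_ratio = or[peak],
          member_idx = I(list(mem)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_cnvrs())
  res <- do.call(rbind, out)
  res <- res[order(chrom_order(res$chrom), res$start_bp, res$class), , drop = FALSE]
  res$cnvr_id <- sprintf("cnvr_%02d_%s", seq_len(nrow(res)), tolower(res$class))
  rownames(res) <- NULL
  res[, c("cnvr_id", setdiff(names(res), "cnvr_id"))]
}

empty_cnvrs <- function() {
  data.frame(cnvr_id = character(), chrom = character(), start_bp = integer(),
             end_bp = integer(), class = character(), peak_probe = character(),
             a = integer(), b = integer(), n_case_total = integer(),
             n_ctrl_total = integer(), p_raw = numeric(),
             odds_ratio = numeric(), member_idx = I(list()),
             stringsAsFactors = FALSE)
}

#' Batch-stratified peak test (Cochran-Mantel-Haenszel)
#'
#' When cases and controls were genotyped on different array batches, the
#' pooled Fisher table can confound batch with phenotype. Given a cohort
#' table with a `batch` column, this recomputes each CNVR's peak-probe test
#' as a Cochran-Mantel-Haenszel test across batch strata, reporting the
#' common odds ratio. Region discovery (membership and span) is left
#' untouched; only the peak statistics change. The pooled Fisher test
#' remains the default analysis.
#'
#' @param cnvrs output of [collapse_cnvr()].
#' @param burden the `probe_burden` the CNVRs came from; its cohort table
#'   must have a `batch` column.
#' @return `cnvrs` with `p_raw` and `odds_ratio` replaced by the CMH
#'   stratified values at the peak probe.
#' @export
cmh_peak_test <- function(cnvrs, burden) {
  cohort <- burden$cohort
  assert_that("batch" %in% names(cohort), "cohort table has no batch column")
  if (nrow(cnvrs) == 0) return(cnvrs)
  for (i in seq_len(nrow(cnvrs))) {
    peak <- match(cnvrs$peak_probe[i], burden$probes$probe_id)
    cls <- tolower(cnvrs$class[i])
    car <- burden$carriage[burden$carriage$class == cls &
                           burden$carriage$lo <= peak &
                           burden$carriage$hi >= peak, , drop = FALSE]
    carrier <- cohort$sample_id %in% car$sample_id
    tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
                 factor(cohort$cohort, levels = c("case", "control")),
                 cohort$batch)
    # strata with no carriers contribute nothing to the CMH statistic
    mh <- stats::mantelhaen.test(tab, exact = FALSE, correct = FALSE)
    cnvrs$p_raw[i] <- unname(mh$p.value)
    cnvrs$odds_ratio[i] <- unname(mh$estimate)
  }
  cnvrs
}

#' Multiple-testing correction over discovered CNVRs
#'
#' The correction family is the set of CNVRs discovered per class (deletion
#' regions and duplication regions are separate families, mirroring their
#' separate tests). Bonferroni multiplies the peak p by the family size;
#' FDR is Benjamini-Hochberg over the family; simpleM multiplies by the
#' effective number of independent tests, the smallest number of principal
#' components of the member-probe carriage-indicator correlation matrix
#' explaining at least 99.5% of its variance. A CNVR is significant when
#' any corrected value is at or below 0.05.
#'
#' @param cnvrs output of [collapse_cnvr()].
#' @param burden the `probe_burden` the CNVRs came from (supplies the
#'   samples x member-probe indicator matrix for simpleM).
#' @param var_explained simpleM variance-explained threshold.
#' @param alpha corrected significance level.
#' @return `cnvrs` with `p_bonferroni`, `q_fdr`, `p_simplem`, `meff` and
#'   `significant` columns.
#' @export
correct_multiple <- function(cnvrs, burden, var_explained = 0.995,
                             alpha = 0.05) {
  if (nrow(cnvrs) == 0) {
    cnvrs$p_bonferroni <- numeric(); cnvrs$q_fdr <- numeric()
    cnvrs$p_simplem <- numeric(); cnvrs$meff <- numeric()
    cnvrs$significant <- logical()
    return(cnvrs)
  }
  cnvrs$p_bonferroni <- NA_real_; cnvrs$q_fdr <- NA_real_
  cnvrs$p_simplem <- NA_real_; cnvrs$meff <- NA_real_
  for (class in unique(cnvrs$class)) {
    rows <- which(cnvrs$class == class)
    m <- length(rows)
    cnvrs$p_bonferroni[rows] <- pmin(1, cnvrs$p_raw[rows] * m)
    cnvrs$q_fdr[rows] <- stats::p.adjust(cnvrs$p_raw[rows], method = "BH")
    member <- sort(unique(unlist(cnvrs$member_idx[rows])))
    meff <- simplem_meff(indicator_matrix(burden, member, tolower(class)),
                         var_explained)
    cnvrs$meff[rows] <- meff
    cnvrs$p_simplem[rows] <- pmin(1, cnvrs$p_raw[rows] * meff)
  }
  cnvrs$significant <- cnvrs$q_fdr <= alpha | cnvrs$p_bonferroni <= alpha |
    cnvrs$p_simplem <= alpha
  cnvrs
}

# samples x probes 0/1 carriage indicator for one class over given probe
# indices; rows cover every sample in the burden's cohort.
indicator_matrix <- function(burden, probe_idx, class) {
  ids <- burden$cohort$sample_id
  M <- matrix(0L, length(ids), length(probe_idx),
              dimnames = list(ids, burden$probes$probe_id[probe_idx]))
  car <- burden$carriage[burden$carriage$class == class, , drop = FALSE]
  if (nrow(car) > 0) for (j in seq_len(nrow(car))) {
    cols <- which(probe_idx >= car$lo[j] & probe_idx <= car$hi[j])
    if (length(cols) > 0) M[car$sample_id[j], cols] <- 1L
  }
  M
}

# simpleM effective number of tests: eigenvalues of the indicator
# correlation matrix, smallest k explaining >= var_explained of variance.
simplem_meff <- function(M, var_explained = 0.995) {
  keep <- apply(M, 2, function(x) stats::var(x) > 0)
  M <- M[, keep, drop = FALSE]
  if (ncol(M) <= 1) return(1)
  ev <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  max(1, which(cumsum(ev) / sum(ev) >= var_explained)[1])
}

#' Run case-control association for the standard phenotype contrasts
#'
#' Executes independent case-control association runs for the requested
#' contrasts: each NDD subphenotype against all controls, and pooled NDD
#' (every case) against all controls. Each contrast restricts the cohort
#' and calls to its own samples, counts probe-level burden, collapses
#' CNVRs and corrects for multiple testing; an optional gene set annotates
#' (or restricts) the regions.
#'
#' @param calls QC-passed call data frame.
#' @param cohort QC-passed sample table (`sample_id`, `cohort`,
#'   `subphenotype` for cases).
#' @param probes a `probe_map`.
#' @param contrasts subset of `c("ADHD", "ASD", "ADHD+ASD", "NDD")`.
#' @param alpha_probe,merge_bp see [collapse_cnvr()].
#' @param geneset optional `gene_set` for annotation.
#' @param restrict if `TRUE` and a gene set is given, keep only in-network
#'   results; corrections are always computed on the final (restricted)
#'   family.
#' @param restrict_stage `"pre"` restricts the call set to in-network calls
#'   before burden counting (the default: the network defines the search
#'   space); `"post"` discovers CNVRs genome-wide and then drops
#'   off-network regions before correction.
#' @return named list of per-contrast CNVR tables.
#' @export
run_association <- function(calls, cohort, probes,
                            contrasts = c("ADHD", "ASD", "ADHD+ASD", "NDD"),
                            alpha_probe = 0.05, merge_bp = 1e6,
                            geneset = NULL, restrict = FALSE,
                            restrict_stage = c("pre", "post")) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  restrict_stage <- match.arg(restrict_stage)
  if (restrict && restrict_stage == "pre") {
    assert_that(!is.null(geneset), "restrict requires a gene set")
    calls <- restrict_calls_to_geneset(calls, geneset)
  }
  out <- list()
  for (ct in contrasts) {
    keep <- cohort$cohort == "control" |
      (cohort$cohort == "case" &
         (ct == "NDD" | (!is.na(cohort$subphenotype) & cohort$subphenotype == ct)))
    sub <- cohort[keep, , drop = FALSE]
    if (!any(sub$cohort == "case") || !any(sub$cohort == "control"))
      stop_arg("contrast ", ct, " has an empty case or control set")
    sub_calls <- calls[calls$sample_id %in% sub$sample_id, , drop = FALSE]
    burden <- probe_burden(sub_calls, sub, probes)
    cnvrs <- collapse_cnvr(burden, alpha_probe = alpha_probe,
                           merge_bp = merge_bp)
    if (!is.null(geneset)) {
      mode <- if (restrict && restrict_stage == "post") "restrict" else "annotate"
      cnvrs <- annotate_and_restrict(cnvrs, geneset, mode = mode)
    }
    cnvrs <- correct_multiple(cnvrs, burden)
    out[[ct]] <- cnvrs
  }
  out
}

#' Flatten a CNVR table for TSV output (drops the member_idx list column)
#' @param cnvrs CNVR data frame.
#' @export
cnvr_table <- function(cnvrs) {
  cnvrs$n_member_probes <- vapply(cnvrs$member_idx, length, 1L)
  cnvrs$member_idx <- NULL
  cnvrs
}
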