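test_that("Fisher test matches enumeration, stats::fisher.test and edge rules", {
  set.seed(101)
  for (trial in 1:80) {
    n_case <- sample(5:30, 1); n_ctrl <- sample(5:30, 1)
    a <- sample(0:n_case, 1); b <- sample(0:n_ctrl, 1)
    got <- fisher_exact_2x2(a, b, n_case, n_ctrl)
    expect_equal(got$p, enum_fisher_p(a, b, n_case, n_ctrl), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, n_case - a, b, n_ctrl - b), 2))
    expect_equal(got$p, ft$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(0, 0, 10, 10), list(p = 1, odds_ratio = NA_real_))
  expect_equal(fisher_exact_2x2(3, 0, 10, 10)$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(0, 3, 10, 10)$odds_ratio, 0)
  expect_error(fisher_exact_2x2(11, 0, 10, 10), "counts")
  # sample odds ratio, not the conditional MLE
  expect_equal(fisher_exact_2x2(4, 2, 10, 12)$odds_ratio, (4 / 6) / (2 / 10))
})

test_that("probe burden counts distinct carriers once per probe and class", {
  pm <- fixture_probes(n = 50, n_chrom = 1, seed = 61)
  cohort <- data.frame(sample_id = c("s1", "s2"), cohort = c("case", "control"),
                       subphenotype = c("ADHD", NA), stringsAsFactors = FALSE)
  calls <- fixture_call(pm, "s1", 10, 20, 1)
  bd <- probe_burden(calls, cohort, pm)
  expect_equal(bd$counts$n_case_del, as.integer(seq_len(50) %in% 10:20))
  expect_true(all(bd$counts$n_case_dup == 0))
  expect_true(all(bd$counts$n_ctrl_del == 0))

  # two overlapping deletions in one sample still count once at shared probes
  calls2 <- rbind(calls, fixture_call(pm, "s1", 15, 25, 0))
  bd2 <- probe_burden(calls2, cohort, pm)
  expect_equal(max(bd2$counts$n_case_del), 1L)
  expect_equal(bd2$counts$n_case_del, as.integer(seq_len(50) %in% 10:25))

  expect_error(probe_burden(fixture_call(pm, "ghost", 1, 5, 1), cohort, pm),
               "absent from cohort")
})

test_that("CNVR collapsing follows the 1 Mb rule between significant probes", {
  # hand-built burden: three significant probe islands on one chromosome
  pm <- make_probe_map(40, n_chrom = 1, spacing_bp = 1000, seed = 71)
  pm$pos_bp <- as.integer(seq(1e5, by = 1e5, length.out = 40))  # 0.1 Mb grid
  cohort <- data.frame(
    sample_id = c(sprintf("case_%02d", 1:30), sprintf("ctrl_%02d", 1:30)),
    cohort = rep(c("case", "control"), each = 30),
    subphenotype = c(rep("ADHD", 30), rep(NA, 30)), stringsAsFactors = FALSE)

  # 12 case carriers at probes 5..7 and at probes 20..22 (1.3 Mb away from 7)
  calls <- do.call(rbind, lapply(sprintf("case_%02d", 1:12), function(id)
    rbind(fixture_call(pm, id, 5, 7, 1), fixture_call(pm, id, 20, 22, 1))))
  bd <- probe_burden(calls, cohort, pm)
  cn <- collapse_cnvr(bd, alpha_probe = 0.05, merge_bp = 1e6)
  expect_equal(nrow(cn), 2)  # the 1.3 Mb gap splits the regions
  expect_true(all(cn$class == "Del"))
  expect_equal(cn$a, c(12L, 12L))

  cn_wide <- collapse_cnvr(bd, alpha_probe = 0.05, merge_bp = 1.5e6)
  expect_equal(nrow(cn_wide), 1)  # wider merge window chains them
  expect_equal(cn_wide$start_bp, pm$pos_bp[5])
  expect_equal(cn_wide$end_bp, pm$pos_bp[22])
})

test_that("peak statistics are the regional minimum p with smallest-position ties", {
  pm <- make_probe_map(30, n_chrom = 1, spacing_bp = 1000, seed = 73)
  cohort <- data.frame(
    sample_id = c(sprintf("case_%02d", 1:20), sprintf("ctrl_%02d", 1:20)),
    cohort = rep(c("case", "control"), each = 20),
    subphenotype = c(rep("ADHD", 20), rep(NA, 20)), stringsAsFactors = FALSE)
  # carriers: 10 cases span probes 5..15, 4 more span 8..12 (deeper peak)
  calls <- rbind(
    do.call(rbind, lapply(sprintf("case_%02d", 1:10), function(id)
      fixture_call(pm, id, 5, 15, 1))),
    do.call(rbind, lapply(sprintf("case_%02d", 11:14), function(id)
      fixture_call(pm, id, 8, 12, 1))))
  bd <- probe_burden(calls, cohort, pm)
  cn <- collapse_cnvr(bd)
  expect_equal(nrow(cn), 1)
  expect_equal(cn$a, 14L)                     # peak counts all 14 carriers
  expect_equal(cn$peak_probe, pm$probe_id[8]) # first probe reaching min p
  member_p <- cnvflow:::fisher_p_or(bd$counts$n_case_del[cn$member_idx[[1]]],
                                    bd$counts$n_ctrl_del[cn$member_idx[[1]]],
                                    20, 20)$p
  expect_equal(cn$p_raw, min(member_p))
})

test_that("multiple-testing corrections behave at their limits", {
  pm <- make_probe_map(30, n_chrom = 1, spacing_bp = 1000, seed = 75)
  cohort <- data.frame(
    sample_id = c(sprintf("case_%02d", 1:15), sprintf("ctrl_%02d", 1:15)),
    cohort = rep(c("case", "control"), each = 15),
    subphenotype = c(rep("ADHD", 15), rep(NA, 15)), stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(sprintf("case_%02d", 1:6), function(id)
    fixture_call(pm, id, 10, 14, 1)))
  bd <- probe_burden(calls, cohort, pm)
  cn <- correct_multiple(collapse_cnvr(bd), bd)
  expect_equal(nrow(cn), 1)
  # single CNVR: Bonferroni with m = 1 leaves p unchanged
  expect_equal(cn$p_bonferroni, cn$p_raw)
  expect_equal(cn$q_fdr, cn$p_raw)
  # all member probes have identical indicator columns: Meff = 1
  expect_equal(cn$meff, 1)
  expect_equal(cn$p_simplem, cn$p_raw)
  expect_true(cn$significant)
})

test_that("null cohorts rarely produce corrected-significant CNVRs", {
  pm <- fixture_probes(n = 300, seed = 81)
  ev <- planted_events(pm, c("n1", "n2", "n3"), c("chr1", "chr1", "chr2"),
                       pm$pos_bp[c(20, 80, 200)], pm$pos_bp[c(29, 89, 209)],
                       c(1L, 3L, 1L),
                       freq_case = c(0.05, 0.05, 0.05),
                       freq_control = c(0.05, 0.05, 0.05))
  n_fp <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    car <- simulate_carriage(pm, ev, 100, 100, seed = 1000 + r)
    calls <- carriage_to_calls(car$truth, pm)
    bd <- probe_burden(calls, car$cohort, pm)
    cn <- correct_multiple(collapse_cnvr(bd), bd)
    if (any(cn$significant)) n_fp <- n_fp + 1
  }
  expect_lte(n_fp / reps, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("a case-enriched locus is recovered with a faithful odds ratio", {
  pm <- fixture_probes(n = 400, seed = 83)
  ev <- planted_events(pm, c("hit", "null"), c("chr1", "chr2"),
                       pm$pos_bp[c(50, 250)], pm$pos_bp[c(64, 264)],
                       c(1L, 3L),
                       freq_case = c(0.02, 0.01), freq_control = c(0.002, 0.01))
  gen_or <- (0.02 / 0.98) / (0.002 / 0.998)
  hits <- 0; log_ors <- numeric(0)
  reps <- 15
  for (r in seq_len(reps)) {
    car <- simulate_carriage(pm, ev, 2000, 2000, seed = 2000 + r)
    calls <- carriage_to_calls(car$truth, pm)
    bd <- probe_burden(calls, car$cohort, pm)
    cn <- correct_multiple(collapse_cnvr(bd), bd)
    found <- cn[cn$significant & cn$class == "Del" & cn$chrom == "chr1" &
                cn$start_bp <= ev$end_bp[1] & cn$end_bp >= ev$start_bp[1], ]
    if (nrow(found) > 0) {
      hits <- hits + 1
      log_ors <- c(log_ors, log(found$odds_ratio[1]))
    }
  }
  expect_gte(hits / reps, 0.9)
  se <- sd(log_ors) / sqrt(length(log_ors))
  expect_lt(abs(mean(log_ors) - log(gen_or)), 3 * se + 1e-9)
})

test_that("contrasts run independently and a subtype locus stays subtype-specific", {
  pm <- fixture_probes(n = 300, seed = 85)
  ev <- planted_events(pm, "adhd_only", "chr1", pm$pos_bp[40], pm$pos_bp[54],
                       1L, freq_case = 0.1, freq_control = 0.005)
  # carriage drawn per subphenotype: only ADHD cases carry
  car <- simulate_carriage(pm, ev, 900, 900, seed = 301)
  adhd <- car$cohort$sample_id[car$cohort$cohort == "case" &
                               car$cohort$subphenotype == "ADHD"]
  car$truth <- car$truth[car$truth$sample_id %in% adhd |
                         grepl("^ctrl", car$truth$sample_id), ]
  calls <- carriage_to_calls(car$truth, pm)
  res <- run_association(calls, car$cohort, pm, contrasts = c("ADHD", "ASD"))
  expect_true(any(res$ADHD$significant))
  expect_false(any(res$ASD$significant))
  # determinism: identical inputs give identical tables
  res2 <- run_association(calls, car$cohort, pm, contrasts = c("ADHD", "ASD"))
  expect_identical(res, res2)
  # an empty contrast errors by name
  no_cases <- car$cohort[car$cohort$cohort == "control", ]
  expect_error(run_association(calls[0, ], no_cases, pm, contrasts = "ADHD"),
               "ADHD")
})

test_that("batch-stratified CMH peak test agrees with pooling when batches are exchangeable", {
  pm <- make_probe_map(60, n_chrom = 1, spacing_bp = 1000, seed = 95)
  cohort <- data.frame(
    sample_id = c(sprintf("case_%02d", 1:40), sprintf("ctrl_%02d", 1:40)),
    cohort = rep(c("case", "control"), each = 40),
    subphenotype = c(rep("ADHD", 40), rep(NA, 40)),
    batch = rep(rep(c("b1", "b2"), 2), each = 20), stringsAsFactors = FALSE)
  # 16 case carriers, 4 control carriers, spread evenly over both batches
  # (cases 1-20 / controls 1-20 are batch b1, the rest b2)
  ids <- c(sprintf("case_%02d", c(1:8, 21:28)), sprintf("ctrl_%02d", c(1:2, 21:22)))
  calls <- do.call(rbind, lapply(ids, function(id) fixture_call(pm, id, 20, 30, 1)))
  bd <- probe_burden(calls, cohort, pm)
  cn <- collapse_cnvr(bd)
  expect_equal(nrow(cn), 1)
  cmh <- cmh_peak_test(cn, bd)
  # balanced strata: CMH common OR matches the pooled sample OR
  expect_equal(cmh$odds_ratio, cn$odds_ratio, tolerance = 1e-9)
  expect_lt(cmh$p_raw, 0.05)
  no_batch <- bd; no_batch$cohort$batch <- NULL
  expect_error(cmh_peak_test(cn, no_batch), "batch")
})

test_that("signal review never adds significant regions at null loci", {
  pm <- fixture_probes(n = 400, seed = 87)
  ev <- planted_events(pm, c("nullA", "nullB"), c("chr1", "chr2"),
                       pm$pos_bp[c(60, 260)], pm$pos_bp[c(74, 274)],
                       c(1L, 3L), freq_case = c(0.08, 0.08),
                       freq_control = c(0.08, 0.08))
  for (seed in 1:4) {
    sim <- simulate_cohort(pm, signal_model(), ev, 25, 25, seed = 400 + seed)
    calls <- call_cohort(sim$samples, pm)
    filt <- qc_filter(calls, sim$samples, pm)$passed_calls
    n_sig <- function(cl) {
      bd <- probe_burden(cl, sim$cohort, pm)
      sum(correct_multiple(collapse_cnvr(bd), bd)$significant)
    }
    expect_lte(n_sig(filt), n_sig(calls))
  }
})
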