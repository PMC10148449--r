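test_that("probe maps honour their dimensional and ordering contracts", {
  pm <- make_probe_map(1000, n_chrom = 2, spacing_bp = 5000, seed = 7)
  expect_equal(nrow(pm), 1000)
  expect_equal(length(unique(pm$chrom)), 2)
  expect_false(anyDuplicated(pm$probe_id) > 0)
  expect_true(all(pm$pfb >= 0 & pm$pfb <= 1))
  for (ch in unique(pm$chrom))
    expect_true(all(diff(pm$pos_bp[pm$chrom == ch]) > 0))

  # degenerate single-probe map is valid
  one <- make_probe_map(1, n_chrom = 1, spacing_bp = 100, seed = 1)
  expect_equal(nrow(one), 1)

  # pure function of (arguments, seed)
  expect_identical(pm, make_probe_map(1000, n_chrom = 2, spacing_bp = 5000, seed = 7))
  expect_false(identical(pm$pos_bp,
                         make_probe_map(1000, 2, 5000, seed = 8)$pos_bp))
  expect_error(make_probe_map(0), "positive")
  expect_error(make_probe_map(10, n_chrom = 20), "n_chrom")
})

test_that("planted events are validated against the probe map", {
  pm <- fixture_probes()
  expect_error(planted_events(pm, "x", "chr9", 1, 100, 1L, 0.1, 0.1),
               "unknown chromosome")
  expect_error(planted_events(pm, "x", "chr1", 1, max(pm$pos_bp) * 10, 1L, 0.1, 0.1),
               "outside")
  expect_error(planted_events(pm, "x", "chr1", pm$pos_bp[10], pm$pos_bp[20],
                              1L, 1.2, 0.1), "frequencies")
  expect_error(planted_events(pm, c("x", "y"), c("chr1", "chr1"),
                              pm$pos_bp[c(10, 15)], pm$pos_bp[c(20, 25)],
                              c(1L, 3L), c(.1, .1), c(.1, .1)),
               "overlap")
  # sub-detection-floor events are flagged, not rejected
  tiny <- planted_events(pm, "tiny", "chr1", pm$pos_bp[10], pm$pos_bp[11],
                         1L, 0.1, 0.1)
  expect_false(tiny$detectable)
  expect_equal(tiny$n_probes, 2L)
})

test_that("deletion spans carry no heterozygous genotypes and shifted LRR", {
  pm <- fixture_probes(seed = 3)
  ev <- planted_events(pm, "del", "chr1", pm$pos_bp[50], pm$pos_bp[89],
                       1L, 1.0, 1.0)  # every sample carries it
  sim <- simulate_cohort(pm, signal_model(), ev, 5, 0, seed = 2)
  idx <- 50:89
  for (s in sim$samples) {
    expect_false(any(s$genotype[idx] == "AB"))
    # essentially no BAF mass in the heterozygous band
    expect_lt(mean(s$baf[idx] > 0.25 & s$baf[idx] < 0.75), 0.03)
    expect_lt(mean(s$lrr[idx]), -0.4)
  }
})

test_that("duplication BAF clusters sit at the copy-state positions", {
  # cn=3 at pfb 0.5: clusters at 0, 1/3, 2/3, 1 recovered within +/- 0.02
  pm <- make_probe_map(2500, n_chrom = 1, spacing_bp = 1000, seed = 5)
  pm$pfb[] <- 0.5
  ev <- planted_events(pm, "dup", "chr1", pm$pos_bp[1], pm$pos_bp[2500],
                       3L, 1.0, 1.0)
  sim <- simulate_cohort(pm, signal_model(), ev, 1, 0, seed = 9)
  baf <- sim$samples[[1]]$baf
  km <- stats::kmeans(baf, centers = c(0.05, 0.35, 0.65, 0.95), iter.max = 50)
  expect_lt(max(abs(sort(km$centers[, 1]) - c(0, 1/3, 2/3, 1))), 0.02)

  # cn=4: clusters at 0, 1/4, 1/2, 3/4, 1
  ev4 <- planted_events(pm, "dup4", "chr1", pm$pos_bp[1], pm$pos_bp[2500],
                        4L, 1.0, 1.0)
  sim4 <- simulate_cohort(pm, signal_model(), ev4, 1, 0, seed = 9)
  km4 <- stats::kmeans(sim4$samples[[1]]$baf,
                       centers = c(0.05, 0.27, 0.5, 0.73, 0.95), iter.max = 50)
  expect_lt(max(abs(sort(km4$centers[, 1]) - c(0, 0.25, 0.5, 0.75, 1))), 0.02)
})

test_that("event carriage frequency matches the generative frequency", {
  pm <- fixture_probes(n = 200, seed = 13)
  ev <- fixture_events(pm, freq_case = 0.10, freq_control = 0.02, width = 10L)
  car <- simulate_carriage(pm, ev, 2000, 2000, seed = 21)
  for (loc in ev$locus_id) {
    hit <- car$truth[car$truth$locus_id == loc, ]
    carriers <- table(factor(sub("_.*", "", hit$sample_id),
                             levels = c("case", "ctrl")))
    for (grp in c("case", "ctrl")) {
      f0 <- if (grp == "case") 0.10 else 0.02
      se <- sqrt(f0 * (1 - f0) / 2000)
      expect_lt(abs(carriers[[grp]] / 2000 - f0), 3 * se)
    }
  }
})

test_that("a cohort with no events is diploid everywhere", {
  pm <- fixture_probes(n = 400, seed = 17)
  sim <- simulate_cohort(pm, signal_model(), NULL, 4, 4, seed = 3)
  expect_equal(nrow(sim$truth), 0)
  for (s in sim$samples)
    expect_lt(abs(mean(s$lrr)), 3 * 0.18 / sqrt(400))
})

test_that("simulation is reproducible and degraded samples fail call rate", {
  pm <- fixture_probes(n = 300, seed = 19)
  ev <- fixture_events(pm, width = 10L)
  a <- simulate_cohort(pm, signal_model(), ev, 5, 5, seed = 4)
  b <- simulate_cohort(pm, signal_model(), ev, 5, 5, seed = 4)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)

  deg <- simulate_cohort(pm, signal_model(), ev, 5, 5, seed = 4,
                         degraded_ids = "case_0001",
                         degraded_nocall_rate = 0.05)
  expect_lt(deg$samples[["case_0001"]]$call_rate, 0.985)
  expect_gt(mean(vapply(deg$samples[-1], `[[`, numeric(1), "call_rate")), 0.985)
})

test_that("signal files round-trip, reorder on shuffled rows, and reject bad schema", {
  pm <- fixture_probes(n = 150, seed = 23)
  sim <- simulate_cohort(pm, signal_model(), NULL, 1, 0, seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_signal_files(sim$samples, pm, dir)
  back <- read_signal_file(paths[[1]], pm)
  expect_lt(max(abs(back$lrr - sim$samples[[1]]$lrr)), 1e-4)
  expect_lt(max(abs(back$baf - sim$samples[[1]]$baf)), 1e-4)
  expect_identical(back$genotype, sim$samples[[1]]$genotype)
  expect_equal(back$call_rate, sim$samples[[1]]$call_rate)

  # shuffled probe order: reordered with a warning
  tab <- utils::read.delim(paths[[1]], check.names = FALSE)
  shuf <- tab[sample(nrow(tab)), ]
  p2 <- file.path(dir, "shuffled.signal.tsv")
  utils::write.table(shuf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(back2 <- read_signal_file(p2, pm), "reordered")
  expect_equal(back2$lrr, back$lrr)

  # missing BAF column: format error
  p3 <- file.path(dir, "broken.signal.tsv")
  utils::write.table(tab[, -5], p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signal_file(p3, pm), "B Allele Freq")

  # PFB round-trip
  pfb_path <- file.path(dir, "probes.pfb")
  write_pfb(pm, pfb_path)
  pm2 <- read_pfb(pfb_path)
  expect_equal(pm2$pfb, pm$pfb, tolerance = 1e-4)
  expect_identical(pm2$probe_id, pm$probe_id)
})
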