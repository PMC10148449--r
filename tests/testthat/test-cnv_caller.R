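params_default <- hmm_params()
empty_calls_df <- function() cnvflow:::empty_calls()

test_that("emission log-likelihood equals a hand-summed mixture", {
  p <- params_default
  lrr <- -0.5; baf <- 0.31; pfb <- 0.4
  for (cn in 0:4) {
    lrr_part <- dnorm(lrr, p$lrr_mean[[as.character(cn)]],
                      p$lrr_sd[[as.character(cn)]])
    baf_part <- if (cn == 0) 1 else {
      total <- 0
      for (k in 0:cn) {
        center <- k / cn
        comp <- dnorm(baf, center, p$baf_sd) * (if (center %in% c(0, 1)) 2 else 1)
        total <- total + dbinom(k, cn, pfb) * comp
      }
      total
    }
    expected <- log(max(lrr_part, 1e-9)) + log(max(baf_part, 1e-9))
    expect_equal(emission_loglik(lrr, baf, pfb, cn, p), expected)
  }
  expect_error(emission_loglik(0, 0.5, 0.5, 7, params_default), "unknown")
})

test_that("emission structure matches copy-state BAF geometry", {
  p <- params_default
  # a heterozygous BAF at a deletion state is strongly penalised: cn=1 has
  # clusters only at 0 and 1
  ll_cn1 <- emission_loglik(-0.66, 0.5, 0.5, 1, p)
  ll_cn2 <- emission_loglik(-0.66, 0.5, 0.5, 2, p)
  expect_lt(ll_cn1, ll_cn2 - 5)
  # diploid-looking signal maximises at cn=2
  ll <- vapply(0:4, function(s) emission_loglik(0, 0.5, 0.5, s, p), numeric(1))
  expect_equal(which.max(ll) - 1L, 2L)
  # no-call probes drop the BAF factor: value is the pure LRR term
  expect_equal(emission_loglik(0.1, 0.99, 0.5, 2, p, genotype = "NoCall"),
               log(dnorm(0.1, 0, p$lrr_sd[["2"]])))
})

test_that("transition matrices are stochastic, distance-saturating and identity at 0", {
  p <- params_default
  expect_equal(transition_matrix(0, p), diag(5), ignore_attr = TRUE)
  for (d in c(1, 1e3, 1e5, 1e7)) {
    A <- transition_matrix(d, p)
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(A >= 0))
  }
  off_inf <- 1 - diag(transition_matrix(1e12, p))
  expect_equal(off_inf, rep(p$off_diag_base, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # longer gaps are less sticky
  expect_lt(transition_matrix(1e3, p)[3, 1], transition_matrix(1e5, p)[3, 1])
  expect_error(transition_matrix(-1, p), "distance")
})

test_that("Viterbi decoding equals exhaustive path enumeration on small instances", {
  set.seed(42)
  p <- params_default
  for (trial in 1:60) {
    n <- sample(2:7, 1)
    pos <- cumsum(sample(1e3:2e5, n, replace = TRUE))
    E <- matrix(rnorm(n * 5, sd = 3), n, 5)
    oracle <- brute_force_best_path(E, pos, p)
    got <- cnvflow:::viterbi_decode(E, pos, p)
    expect_identical(got, as.integer(oracle$path))
  }
})

test_that("a planted 20-probe deletion is recovered within 2 probes per edge", {
  pm <- fixture_probes(seed = 3)
  ev <- planted_events(pm, "del", "chr1", pm$pos_bp[100], pm$pos_bp[119],
                       1L, 1.0, 1.0)
  sim <- simulate_cohort(pm, signal_model(), ev, 6, 0, seed = 8)
  for (s in sim$samples) {
    calls <- viterbi_call(s, pm, params_default)
    del <- calls[calls$copy_state == 1L & calls$chrom == "chr1", ]
    expect_equal(nrow(del), 1)
    lo <- match(del$start_probe, pm$probe_id)
    hi <- match(del$end_probe, pm$probe_id)
    expect_lte(abs(lo - 100), 2)
    expect_lte(abs(hi - 119), 2)
    expect_gt(del$conf, 0)
  }
})

test_that("a clean diploid sample yields no calls and no call has under 3 probes", {
  pm <- fixture_probes(n = 600, seed = 5)
  sim <- simulate_cohort(pm, signal_model(), NULL, 8, 0, seed = 12)
  calls <- call_cohort(sim$samples, pm, params_default)
  expect_equal(nrow(calls), 0)

  # with planted short and long events, emitted calls always have >= 3 probes
  ev <- planted_events(pm, c("d3", "d10"), c("chr1", "chr2"),
                       pm$pos_bp[c(50, 400)], pm$pos_bp[c(52, 409)],
                       c(1L, 3L), c(1, 1), c(1, 1))
  sim2 <- simulate_cohort(pm, signal_model(), ev, 10, 0, seed = 13)
  calls2 <- call_cohort(sim2$samples, pm, params_default)
  expect_true(all(calls2$n_probes >= 3))
  expect_true(all(calls2$copy_state != 2L))
})

test_that("sample QC applies the call-rate, LRR-SD and large-event rules in order", {
  s <- structure(list(sample_id = "s1", cohort = "case", subphenotype = NA,
                      lrr = rnorm(100, 0, 0.1), baf = runif(100),
                      genotype = rep("AA", 100), call_rate = 0.984,
                      lrr_sd = 0.1), class = "sample_signal")
  rep1 <- sample_qc(s, empty_calls_df())
  expect_true(rep1$excluded)
  expect_equal(rep1$exclusion_reason, "low_call_rate")

  s$call_rate <- 0.99; s$lrr_sd <- 0.31
  rep2 <- sample_qc(s, empty_calls_df())
  expect_equal(rep2$exclusion_reason, "high_lrr_sd")

  s$lrr_sd <- 0.12
  big <- data.frame(sample_id = "s1", chrom = "chr1", start_bp = 1L,
                    end_bp = 11000000L, start_probe = "a", end_probe = "b",
                    n_probes = 500L, copy_state = 1L, length_bp = 11000000L,
                    conf = 10, stringsAsFactors = FALSE)
  rep3 <- sample_qc(s, big)
  expect_equal(rep3$exclusion_reason, "large_event")

  rep4 <- sample_qc(s, empty_calls_df())
  expect_false(rep4$excluded)
  expect_equal(rep4$exclusion_reason, "none")
  # boundary: call rate exactly 0.985 fails (strict inequality required)
  s$call_rate <- 0.985
  expect_true(sample_qc(s, empty_calls_df())$excluded)
})

test_that("rawcnv files round-trip losslessly and reject diploid records", {
  pm <- fixture_probes(n = 100, seed = 31)
  calls <- rbind(fixture_call(pm, "s1", 10, 20, 1),
                 fixture_call(pm, "s2", 60, 80, 3))
  calls$conf <- c(12.3456, 98.7654)
  path <- withr::local_tempfile()
  write_rawcnv(calls, path)
  back <- read_rawcnv(path)
  expect_equal(back, calls, tolerance = 1e-6)

  writeLines(character(0), path)
  expect_equal(nrow(read_rawcnv(path)), 0)

  writeLines("chr1:100-200 numsnp=5 length=101,bp state=3,cn=2 s1 startsnp=a endsnp=b conf=1.0",
             path)
  expect_error(read_rawcnv(path), "cn=2")

  writeLines("not a rawcnv line", path)
  expect_error(read_rawcnv(path), "malformed rawcnv line 1")

  bad <- calls; bad$copy_state <- c(2L, 3L)
  expect_error(write_rawcnv(bad, path), "diploid")
})

test_that("noisier arrays never improve recall (3-point noise grid, paired seeds)", {
  pm <- fixture_probes(n = 500, seed = 41)
  ev <- planted_events(pm, "del", "chr1", pm$pos_bp[60], pm$pos_bp[74],
                       1L, 0.5, 0.5)
  recalls <- vapply(c(0.15, 0.25, 0.35), function(sd2) {
    model <- signal_model(lrr_sd = c(`0` = 1.3, `1` = 0.18, `2` = sd2,
                                     `3` = 0.18, `4` = 0.18))
    sim <- simulate_cohort(pm, model, ev, 15, 15, seed = 77)
    calls <- call_cohort(sim$samples, pm, hmm_params_from_model(model))
    if (nrow(sim$truth) == 0) return(1)
    call_accuracy(calls, sim$truth, pm)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
})

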