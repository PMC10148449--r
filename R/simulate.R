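#' Simulate a case/control cohort of SNP-array signal tracks
#'
#' Draws per-sample Log R Ratio, B-allele frequency and genotype-call vectors
#' over a probe map, planting each CNV event independently per sample with
#' probability `freq_case` or `freq_control` according to the sample's cohort.
#'
#' Outside planted events every probe is diploid: the number of B alleles is
#' k ~ Binomial(2, pfb), BAF is drawn around k/2 with spread `model$baf_sd`
#' (half-Gaussians at the 0/1 boundaries), LRR ~ N(0, lrr_sd\[2\]). Inside a
#' carried event of copy state cn, k ~ Binomial(cn, pfb), BAF clusters at
#' k/cn, and LRR ~ N(lrr_mean\[cn\], lrr_sd\[cn\]); at cn = 0 the BAF is
#' uniform on \[0, 1\] and the genotype call fails (no template DNA).
#' Genotype calls are the diploid call nearest the BAF cluster (AA below
#' 0.25, BB above 0.75, AB between), so hemizygous deletions show no
#' heterozygous calls. A fraction `model$nocall_rate` of probes lose their
#' genotype call but keep their signal.
#'
#' @param probes a `probe_map`.
#' @param model a `signal_model`.
#' @param events a `planted_events` table (may have zero rows).
#' @param n_case,n_control cohort sizes.
#' @param seed integer seed; the simulation is a pure function of its
#'   arguments and the seed.
#' @param subpheno_prob probabilities of case subphenotypes ADHD, ASD and
#'   ADHD+ASD; defaults mirror a large paediatric NDD cohort composition
#'   (roughly 51/27/22).
#' @param degraded_ids sample ids to degrade with `degraded_nocall_rate`
#'   no-calls, for exercising the call-rate filter.
#' @param degraded_nocall_rate no-call rate applied to degraded samples.
#' @return a list with `samples` (named list of `sample_signal`), `truth`
#'   (data frame of carried events: sample_id, locus_id, chrom, start_bp,
#'   end_bp, copy_state), `cohort` (sample metadata table) and `events`.
#' @export
simulate_cohort <- function(probes, model, events, n_case, n_control, seed = 1,
                            subpheno_prob = c(ADHD = 0.506, ASD = 0.276,
                                              `ADHD+ASD` = 0.218),
                            degraded_ids = character(),
                            degraded_nocall_rate = 0.02) {
  probes <- validate_probe_map(probes)
  assert_that(inherits(model, "signal_model"), "model must be a signal_model")
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(locus_id = character(), chrom = character(),
                         start_bp = integer(), end_bp = integer(),
                         copy_state = integer(), freq_case = numeric(),
                         freq_control = numeric())
  } else {
    assert_that(inherits(events, "planted_events"),
                "events must come from planted_events()")
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cohort <- make_cohort_table(n_case, n_control, subpheno_prob)
  ev_idx <- lapply(seq_len(nrow(events)), function(i)
    probe_indices(probes, events$chrom[i], events$start_bp[i], events$end_bp[i]))

  samples <- vector("list", nrow(cohort))
  truth <- vector("list", nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[s]
    is_case <- cohort$cohort[s] == "case"
    carried <- integer(0)
    if (nrow(events) > 0) {
      freq <- if (is_case) events$freq_case else events$freq_control
      carried <- which(stats::runif(nrow(events)) < freq)
    }
    ncr <- if (sid %in% degraded_ids) degraded_nocall_rate else model$nocall_rate
    sig <- simulate_signal_track(probes, model, events[carried, , drop = FALSE],
                                 ev_idx[carried], ncr)
    samples[[s]] <- new_sample_signal(sid, cohort$cohort[s],
                                      cohort$subphenotype[s], sig)
    if (length(carried) > 0) {
      truth[[s]] <- data.frame(sample_id = sid,
                               events[carried, c("locus_id", "chrom", "start_bp",
                                                 "end_bp", "copy_state")],
                               row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  names(samples) <- cohort$sample_id
  truth <- if (length(tr <- Filter(Negate(is.null), truth)) > 0)
    do.call(rbind, tr)
  else data.frame(sample_id = character(), locus_id = character(),
                  chrom = character(), start_bp = integer(),
                  end_bp = integer(), copy_state = integer())
  list(samples = samples, truth = truth, cohort = cohort, events = events)
}

# One sample's lrr/baf/genotype vectors: diploid background, then event spans.
simulate_signal_track <- function(probes, model, carried_events, carried_idx,
                                  nocall_rate) {
  n <- nrow(probes)
  k <- stats::rbinom(n, 2L, probes$pfb)
  lrr <- stats::rnorm(n, 0, model$lrr_sd[["2"]])
  baf <- draw_baf(k / 2, model$baf_sd)
  geno <- c("AA", "AB", "BB")[k + 1L]

  for (j in seq_along(carried_idx)) {
    idx <- carried_idx[[j]]
    if (length(idx) == 0) next
    cn <- carried_events$copy_state[j]
    lrr[idx] <- stats::rnorm(length(idx), model$lrr_mean[[as.character(cn)]],
                             model$lrr_sd[[as.character(cn)]])
    if (cn == 0) {
      baf[idx] <- stats::runif(length(idx))
      geno[idx] <- "NoCall"
    } else {
      kk <- stats::rbinom(length(idx), cn, probes$pfb[idx])
      centers <- kk / cn
      baf[idx] <- draw_baf(centers, model$baf_sd)
      geno[idx] <- ifelse(centers < 0.25, "AA", ifelse(centers > 0.75, "BB", "AB"))
    }
  }
  nc <- stats::runif(n) < nocall_rate
  geno[nc] <- "NoCall"
  list(lrr = lrr, baf = baf, genotype = geno)
}

# Gaussian spread around the cluster centers, clipped to [0, 1]: boundary
# clusters become half-Gaussians with an atom of mass exactly at 0 or 1,
# matching the hard floor/ceiling of array BAF.
draw_baf <- function(centers, baf_sd) {
  pmin(1, pmax(0, centers + stats::rnorm(length(centers), 0, baf_sd)))
}

new_sample_signal <- function(sample_id, cohort, subphenotype, sig) {
  structure(list(sample_id = sample_id, cohort = cohort,
                 subphenotype = subphenotype,
                 lrr = sig$lrr, baf = sig$baf, genotype = sig$genotype,
                 call_rate = mean(sig$genotype != "NoCall"),
                 lrr_sd = stats::sd(sig$lrr)),
            class = "sample_signal")
}

make_cohort_table <- function(n_case, n_control, subpheno_prob) {
  assert_that(n_case >= 0 && n_control >= 0, "cohort sizes must be non-negative")
  sub <- if (n_case > 0)
    sample(names(subpheno_prob), n_case, replace = TRUE,
           prob = subpheno_prob / sum(subpheno_prob))
  else character()
  data.frame(
    sample_id = c(sprintf("case_%04d", seq_len(n_case)),
                  sprintf("ctrl_%04d", seq_len(n_control))),
    cohort = rep(c("case", "control"), c(n_case, n_control)),
    subphenotype = c(sub, rep(NA_character_, n_control)),
    stringsAsFactors = FALSE
  )
}

#' Simulate event carriage only (no per-probe signal)
#'
#' Draws which samples carry which planted events, without generating
#' intensity tracks. This supports association-level experiments at cohort
#' sizes (thousands of samples, many replicates) where full signal simulation
#' and HMM decoding are unnecessary: the output feeds [carriage_to_calls()]
#' to produce the call set the association stage would see from a perfect
#' caller.
#'
#' @inheritParams simulate_cohort
#' @return list with `truth` and `cohort` as in [simulate_cohort()].
#' @export
simulate_carriage <- function(probes, events, n_case, n_control, seed = 1,
                              subpheno_prob = c(ADHD = 0.506, ASD = 0.276,
                                                `ADHD+ASD` = 0.218)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cohort <- make_cohort_table(n_case, n_control, subpheno_prob)
  ne <- nrow(events)
  if (ne == 0)
    return(list(truth = data.frame(sample_id = character(), locus_id = character(),
                                   chrom = character(), start_bp = integer(),
                                   end_bp = integer(), copy_state = integer()),
                cohort = cohort))
  freq <- ifelse(cohort$cohort == "case", 1, 0) %o% events$freq_case +
    ifelse(cohort$cohort == "control", 1, 0) %o% events$freq_control
  hit <- matrix(stats::runif(nrow(cohort) * ne), nrow(cohort), ne) < freq
  who <- which(hit, arr.ind = TRUE)
  truth <- data.frame(
    sample_id = cohort$sample_id[who[, 1]],
    events[who[, 2], c("locus_id", "chrom", "start_bp", "end_bp", "copy_state")],
    row.names = NULL, stringsAsFactors = FALSE
  )
  truth <- truth[order(match(truth$sample_id, cohort$sample_id)), , drop = FALSE]
  rownames(truth) <- NULL
  list(truth = truth, cohort = cohort)
}

#' Convert ground-truth carriage records into CNV call records
#'
#' Produces the call table an error-free caller would emit for a set of
#' carried events: one call per (sample, event) with probe span, copy state
#' and probe count taken from the probe map.
#'
#' @param truth carriage records as returned by [simulate_carriage()] or
#'   [simulate_cohort()].
#' @param probes the `probe_map` the events were planted on.
#' @return a call data frame in the same shape as [viterbi_call()] output.
#' @export
carriage_to_calls <- function(truth, probes) {
  if (nrow(truth) == 0) return(empty_calls())
  key <- paste(truth$chrom, truth$start_bp, truth$end_bp)
  uniq <- !duplicated(key)
  span <- do.call(rbind, lapply(which(uniq), function(i) {
    idx <- probe_indices(probes, truth$chrom[i], truth$start_bp[i], truth$end_bp[i])
    if (length(idx) == 0) return(NULL)
    data.frame(key = key[i],
               start_probe = probes$probe_id[idx[1]],
               end_probe = probes$probe_id[idx[length(idx)]],
               start_bp = probes$pos_bp[idx[1]],
               end_bp = probes$pos_bp[idx[length(idx)]],
               n_probes = length(idx), stringsAsFactors = FALSE)
  }))
  m <- match(key, span$key)
  keep <- !is.na(m)
  truth <- truth[keep, , drop = FALSE]; m <- m[keep]
  data.frame(
    sample_id = truth$sample_id,
    chrom = truth$chrom,
    start_bp = span$start_bp[m],
    end_bp = span$end_bp[m],
    start_probe = span$start_probe[m],
    end_probe = span$end_probe[m],
    n_probes = span$n_probes[m],
    copy_state = truth$copy_state,
    length_bp = span$end_bp[m] - span$start_bp[m] + 1L,
    conf = NA_real_,
    stringsAsFactors = FALSE
  )
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = integer(), end_bp = integer(),
             start_probe = character(), end_probe = character(),
             n_probes = integer(), copy_state = integer(),
             length_bp = integer(), conf = numeric(),
             stringsAsFactors = FALSE)
}
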