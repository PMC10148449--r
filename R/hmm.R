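# Five-state copy-number HMM over SNP-array probes. States are total copy
# number 0..4 (diploid = 2); emissions combine a Gaussian LRR term with a
# binomial-weighted BAF cluster mixture driven by the probe's population
# B-allele frequency; transitions decay with inter-probe distance.

PROB_FLOOR <- 1e-9

#' HMM parameters for copy-number calling
#'
#' @param lrr_mean,lrr_sd per-state LRR emission Gaussians, named `"0" ... "4"`.
#' @param baf_sd BAF cluster spread.
#' @param off_diag_base asymptotic per-transition probability mass of leaving
#'   the current state (in (0,1)); small values penalise state changes so
#'   calls need multi-probe support.
#' @param decay_bp length scale (bp) of the distance dependence: at gap d the
#'   off-diagonal mass is `off_diag_base * (1 - exp(-d / decay_bp))`, so
#'   adjacent probes are sticky and distant probes approach independence.
#' @param min_probes minimum probes per emitted call (>= 3).
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(lrr_mean = c(`0` = -3.5, `1` = -0.66, `2` = 0,
                                    `3` = 0.40, `4` = 0.68),
                       lrr_sd = c(`0` = 1.3, `1` = 0.18, `2` = 0.18,
                                  `3` = 0.18, `4` = 0.18),
                       baf_sd = 0.03,
                       off_diag_base = 1e-3,
                       decay_bp = 1e5,
                       min_probes = 3L) {
  states <- as.character(0:4)
  assert_that(all(states %in% names(lrr_mean)) && all(states %in% names(lrr_sd)),
              "lrr_mean and lrr_sd must be named for copy states 0..4")
  assert_that(all(lrr_sd[states] > 0), "lrr_sd must be positive")
  assert_that(baf_sd > 0, "baf_sd must be positive")
  assert_that(off_diag_base > 0 && off_diag_base < 1,
              "off_diag_base must be in (0, 1)")
  assert_that(decay_bp > 0, "decay_bp must be positive")
  assert_that(min_probes >= 3, "min_probes must be >= 3")
  structure(list(lrr_mean = lrr_mean[states], lrr_sd = lrr_sd[states],
                 baf_sd = baf_sd, off_diag_base = off_diag_base,
                 decay_bp = decay_bp, min_probes = as.integer(min_probes)),
            class = "hmm_params")
}

#' Convert a generative signal model into HMM parameters
#' @param model a `signal_model`.
#' @param ... overrides passed on to [hmm_params()].
#' @export
hmm_params_from_model <- function(model, ...) {
  hmm_params(lrr_mean = model$lrr_mean, lrr_sd = model$lrr_sd,
             baf_sd = model$baf_sd, ...)
}

# BAF mixture density at one copy state: binomial weights over k B alleles,
# half-Gaussian clusters at the 0/1 boundaries, Gaussian interior clusters.
# cn = 0 has no clusters: uniform density 1 on [0, 1].
baf_density <- function(baf, pfb, cn, baf_sd) {
  if (cn == 0) return(rep(1, length(baf)))
  dens <- numeric(length(baf))
  for (k in 0:cn) {
    w <- stats::dbinom(k, cn, pfb)
    center <- k / cn
    comp <- if (center == 0 || center == 1)
      2 * stats::dnorm(baf, center, baf_sd)
    else
      stats::dnorm(baf, center, baf_sd)
    dens <- dens + w * comp
  }
  dens
}

# n x 5 matrix of per-probe per-state emission log-likelihoods. Probes with
# failed genotype calls still contribute (signal is present when genotyping
# fails); probes with missing LRR and BAF contribute 0 to every state.
emission_matrix <- function(lrr, baf, pfb, params) {
  n <- length(lrr)
  E <- matrix(0, n, 5)
  # callers pass baf = NA where the BAF factor is marginalised (no-calls,
  # missing signal); such probes contribute the LRR factor only
  use_baf <- !is.na(baf)
  use_lrr <- !is.na(lrr)
  for (s in 0:4) {
    col <- s + 1L
    if (any(use_lrr)) {
      d <- stats::dnorm(lrr[use_lrr], params$lrr_mean[[as.character(s)]],
                        params$lrr_sd[[as.character(s)]])
      E[use_lrr, col] <- log(pmax(d, PROB_FLOOR))
    }
    if (any(use_baf)) {
      d <- baf_density(baf[use_baf], pfb[use_baf], s, params$baf_sd)
      E[use_baf, col] <- E[use_baf, col] + log(pmax(d, PROB_FLOOR))
    }
  }
  E
}

#' Per-probe emission log-likelihood
#'
#' Log of `Normal(lrr; lrr_mean[state], lrr_sd[state])` times the
#' binomial-weighted BAF cluster mixture for that copy state (uniform density
#' 1 for copy number 0). Both factors are floored at 1e-9 so the result is
#' finite for any input.
#'
#' @param lrr_value,baf_value one probe's LRR and BAF.
#' @param pfb the probe's population B-allele frequency, in \[0, 1\].
#' @param state copy state: one of 0:4 or `"cn0" ... "cn4"`.
#' @param params an `hmm_params`.
#' @param genotype the probe's genotype call; `"NoCall"` marginalises the BAF
#'   factor (LRR only).
#' @return scalar log-likelihood.
#' @export
emission_loglik <- function(lrr_value, baf_value, pfb, state, params,
                            genotype = "AA") {
  s <- parse_state(state)
  assert_that(pfb >= 0 && pfb <= 1, "pfb must lie in [0, 1]")
  baf <- if (identical(genotype, "NoCall")) NA_real_ else baf_value
  emission_matrix(lrr_value, baf, pfb, params)[1, s + 1L]
}

parse_state <- function(state) {
  if (is.character(state)) state <- sub("^cn", "", state)
  s <- suppressWarnings(as.integer(state))
  if (is.na(s) || !(s %in% 0:4)) stop_arg("unknown copy state: ", state)
  s
}

#' Distance-dependent transition matrix
#'
#' The probability of leaving the current state over a gap of `distance_bp`
#' is `off_diag_base * (1 - exp(-distance_bp / decay_bp))`: zero at distance
#' 0 (the matrix is the identity) and saturating at `off_diag_base`. From the
#' diploid state the exit mass is split equally over the four CNV states;
#' from a CNV state 80% of the exit mass returns to diploid (diploid is the
#' favoured exit) and the remainder is split over the other CNV states.
#'
#' @param distance_bp inter-probe gap in bp (>= 0).
#' @param params an `hmm_params`.
#' @return a 5x5 row-stochastic matrix ordered cn0..cn4.
#' @export
transition_matrix <- function(distance_bp, params) {
  assert_that(distance_bp >= 0, "distance_bp must be >= 0")
  off <- params$off_diag_base * (1 - exp(-distance_bp / params$decay_bp))
  A <- matrix(0, 5, 5, dimnames = list(paste0("cn", 0:4), paste0("cn", 0:4)))
  dip <- 3L  # cn2 column
  for (r in 1:5) {
    A[r, r] <- 1 - off
    if (r == dip) {
      A[r, -dip] <- off / 4
    } else {
      A[r, dip] <- off * 0.8
      others <- setdiff(1:5, c(r, dip))
      A[r, others] <- off * 0.2 / 3
    }
  }
  A
}

# log transition matrix for a vector-free single gap
log_transition <- function(distance_bp, params) {
  log(pmax(transition_matrix(distance_bp, params), 0))
}

#' Call CNVs in one sample by Viterbi decoding
#'
#' Decodes the maximum a posteriori copy-state path per chromosome and emits
#' maximal runs of non-diploid states with at least `min_probes` probes as
#' calls. The initial distribution puts `1 - off_diag_base` on diploid.
#' Confidence is the log-likelihood ratio (emissions plus within-span
#' transitions) of the called path against the all-diploid path over the
#' same span.
#'
#' @param sample a `sample_signal` aligned to `probes`.
#' @param probes a `probe_map`.
#' @param params an `hmm_params`.
#' @return a data frame of calls (possibly zero rows) with columns
#'   `sample_id`, `chrom`, `start_bp`, `end_bp`, `start_probe`, `end_probe`,
#'   `n_probes`, `copy_state`, `length_bp`, `conf`.
#' @export
viterbi_call <- function(sample, probes, params = hmm_params()) {
  assert_that(length(sample$lrr) == nrow(probes),
              "sample signal length must equal the probe map length")
  calls <- list()
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    lrr <- sample$lrr[idx]; baf <- sample$baf[idx]
    geno <- sample$genotype[idx]
    baf[!is.na(geno) & geno == "NoCall"] <- NA  # genotype failed: LRR only
    if (all(is.na(lrr) & is.na(baf))) {
      warning("chromosome ", ch, " has no usable signal for sample ",
              sample$sample_id, "; skipped", call. = FALSE)
      next
    }
    E <- emission_matrix(lrr, baf, probes$pfb[idx], params)
    path <- viterbi_decode(E, probes$pos_bp[idx], params)
    calls[[ch]] <- path_to_calls(path, E, idx, probes, sample$sample_id, params)
  }
  if (length(calls) == 0) return(empty_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# Viterbi over an n x 5 log-emission matrix with distance-dependent
# transitions; returns the integer copy-state path (0..4).
viterbi_decode <- function(E, pos, params) {
  n <- nrow(E)
  off0 <- params$off_diag_base
  pi0 <- log(c(off0 / 4, off0 / 4, 1 - off0, off0 / 4, off0 / 4))
  delta <- pi0 + E[1, ]
  psi <- matrix(0L, n, 5)
  if (n > 1) {
    for (t in 2:n) {
      logA <- log_transition(pos[t] - pos[t - 1], params)
      cand <- delta + logA          # 5x5: rows = from, cols = to
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], 1:5)] + E[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path - 1L
}

# Convert a decoded path on one chromosome into call records.
path_to_calls <- function(path, E, idx, probes, sample_id, params) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 2L & r$lengths >= params$min_probes
  if (!any(keep)) return(NULL)
  recs <- lapply(which(keep), function(j) {
    lo <- starts[j]; hi <- ends[j]
    span <- lo:hi
    conf <- sum(E[cbind(span, path[span] + 1L)]) - sum(E[span, 3])
    if (length(span) > 1) {
      pos <- probes$pos_bp[idx[span]]
      for (t in 2:length(span)) {
        logA <- log_transition(pos[t] - pos[t - 1], params)
        conf <- conf + logA[path[span[t - 1]] + 1L, path[span[t]] + 1L] - logA[3, 3]
      }
    }
    g <- idx[span]
    data.frame(sample_id = sample_id,
               chrom = probes$chrom[g[1]],
               start_bp = probes$pos_bp[g[1]],
               end_bp = probes$pos_bp[g[length(g)]],
               start_probe = probes$probe_id[g[1]],
               end_probe = probes$probe_id[g[length(g)]],
               n_probes = length(g),
               copy_state = r$values[j],
               length_bp = probes$pos_bp[g[length(g)]] - probes$pos_bp[g[1]] + 1L,
               conf = conf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Call CNVs for every sample in a cohort
#' @param samples list of `sample_signal`.
#' @inheritParams viterbi_call
#' @return combined call data frame.
#' @export
call_cohort <- function(samples, probes, params = hmm_params()) {
  out <- lapply(samples, viterbi_call, probes = probes, params = params)
  out <- out[vapply(out, nrow, 1L) > 0]
  if (length(out) == 0) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
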