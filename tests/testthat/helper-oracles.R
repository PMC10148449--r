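# Independent oracles used to validate the HMM decoder and the exact test.

# Best state path by exhaustive enumeration of all 5^n paths, scored with
# the same emission matrix and transition matrices as the decoder but
# without any dynamic programming. Enumerates in chunks to bound memory.
brute_force_best_path <- function(E, pos, params, chunk = 5e5) {
  n <- nrow(E)
  off0 <- params$off_diag_base
  pi0 <- log(c(off0 / 4, off0 / 4, 1 - off0, off0 / 4, off0 / 4))
  logA <- lapply(seq_len(n - 1), function(t)
    log(pmax(transition_matrix(pos[t + 1] - pos[t], params), 0)))
  total <- 5^n
  best <- -Inf
  best_path <- NULL
  start <- 0
  while (start < total) {
    idx <- start:min(start + chunk - 1, total - 1)
    P <- matrix(0L, length(idx), n)
    rem <- idx
    for (t in seq_len(n)) { P[, t] <- as.integer(rem %% 5); rem <- rem %/% 5 }
    sc <- pi0[P[, 1] + 1L] + E[1, ][P[, 1] + 1L]
    if (n > 1) for (t in 2:n) {
      sc <- sc + logA[[t - 1]][cbind(P[, t - 1] + 1L, P[, t] + 1L)] +
        E[t, ][P[, t] + 1L]
    }
    j <- which.max(sc)
    if (sc[j] > best) { best <- sc[j]; best_path <- P[j, ] }
    start <- start + chunk
  }
  list(path = best_path, score = best)
}

# Two-sided Fisher p by direct enumeration of all tables at fixed margins,
# with probabilities computed from binomial coefficients.
enum_fisher_p <- function(a, b, n_case, n_ctrl) {
  K <- a + b
  if (K == 0) return(1)
  xs <- max(0, K - n_ctrl):min(K, n_case)
  prob <- vapply(xs, function(x)
    choose(n_case, x) * choose(n_ctrl, K - x) / choose(n_case + n_ctrl, K),
    numeric(1))
  obs <- prob[xs == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Match calls to ground-truth carried events by probe-range reciprocal
# overlap (same sample, same del/dup class); returns recall and precision.
call_accuracy <- function(calls, truth, probes, min_overlap = 0.5) {
  truth_rng <- t(vapply(seq_len(nrow(truth)), function(i) {
    idx <- probe_indices(probes, truth$chrom[i], truth$start_bp[i], truth$end_bp[i])
    c(idx[1], idx[length(idx)])
  }, c(lo = 0L, hi = 0L)))
  call_rng <- t(vapply(seq_len(nrow(calls)), function(i) {
    idx <- probe_indices(probes, calls$chrom[i], calls$start_bp[i], calls$end_bp[i])
    c(idx[1], idx[length(idx)])
  }, c(lo = 0L, hi = 0L)))
  cls <- function(cn) ifelse(cn < 2, "del", "dup")
  truth_hit <- logical(nrow(truth))
  call_hit <- logical(nrow(calls))
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$sample_id == truth$sample_id[i] &
                  cls(calls$copy_state) == cls(truth$copy_state[i]))
    for (j in cand) {
      ov <- min(truth_rng[i, 2], call_rng[j, 2]) -
        max(truth_rng[i, 1], call_rng[j, 1]) + 1
      len_t <- truth_rng[i, 2] - truth_rng[i, 1] + 1
      len_c <- call_rng[j, 2] - call_rng[j, 1] + 1
      if (ov >= min_overlap * len_t && ov >= min_overlap * len_c) {
        truth_hit[i] <- TRUE
        call_hit[j] <- TRUE
      }
    }
  }
  list(recall = mean(truth_hit), precision = mean(call_hit))
}

probe_indices <- cnvflow:::probe_indices
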