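#' Two-sided Fisher's exact test for carrier counts
#'
#' Tests a 2x2 carrier table (a of `n_case` cases vs b of `n_ctrl` controls).
#' The two-sided p-value sums the hypergeometric probabilities, at the
#' table's fixed margins, of every table no more probable than the observed
#' one (with the conventional relative tolerance of 1e-7). The odds ratio is
#' the sample odds ratio `[a/(n_case-a)] / [b/(n_ctrl-b)]`, reported as
#' `Inf` when b = 0 < a, 0 when a = 0 < b, and `NA` when a = b = 0 (p = 1).
#' No continuity correction is applied.
#'
#' @param a carriers among cases; `0 <= a <= n_case`.
#' @param b carriers among controls; `0 <= b <= n_ctrl`.
#' @param n_case,n_ctrl cohort sizes.
#' @return list with `p` and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(40, 12, 7920, 19993)
#' @export
fisher_exact_2x2 <- function(a, b, n_case, n_ctrl) {
  assert_that(a >= 0 && b >= 0 && a <= n_case && b <= n_ctrl,
              "counts must satisfy 0 <= a <= n_case and 0 <= b <= n_ctrl")
  v <- fisher_p_or(a, b, n_case, n_ctrl)
  list(p = v$p, odds_ratio = v$odds_ratio)
}

# Vectorised Fisher p and sample OR over parallel count vectors.
fisher_p_or <- function(a, b, n_case, n_ctrl) {
  n <- length(a)
  n_case <- rep_len(n_case, n); n_ctrl <- rep_len(n_ctrl, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    K <- a[i] + b[i]
    if (K == 0) { p[i] <- 1; next }
    x <- max(0, K - n_ctrl[i]):min(K, n_case[i])
    d <- stats::dhyper(x, n_case[i], n_ctrl[i], K)
    p[i] <- min(1, sum(d[d <= stats::dhyper(a[i], n_case[i], n_ctrl[i], K) *
                          (1 + 1e-7)]))
  }
  or <- ifelse(a == 0 & b == 0, NA_real_,
        ifelse(b == 0, Inf,
        ifelse(a == 0, 0,
               (a / (n_case - a)) / (b / (n_ctrl - b)))))
  list(p = p, odds_ratio = or)
}
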