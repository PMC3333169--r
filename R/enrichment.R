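#' Upper-tail hypergeometric test
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a population of `N` items of which `K` are
#' successes: `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Evaluated through the log-space hypergeometric CDF, so it is exact and
#' stable for large populations. All over-representation tests in the
#' package funnel through this single code path.
#'
#' @param k Successes in the sample.
#' @param n Sample size.
#' @param K Successes in the population.
#' @param N Population size.
#' @return A tibble with columns `k`, `n`, `K`, `N`, `p_value`
#'   (vectorised over the inputs, recycled to a common length).
#' @export
#' @examples
#' hypergeometric_tail(k = 3, n = 5, K = 4, N = 10)  # 66/252
hypergeometric_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  k <- args$k; n <- args$n; K <- args$K; N <- args$N
  bad <- is.na(k) | is.na(n) | is.na(K) | is.na(N) |
    k < 0 | k > pmin(n, K) | n > N | K > N
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "invalid hypergeometric arguments: k=%s, n=%s, K=%s, N=%s (need 0 <= k <= min(n, K), n <= N, K <= N)",
      k[i], n[i], K[i], N[i]))
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(k = as.integer(k), n = as.integer(n), K = as.integer(K),
                 N = as.integer(N), p_value = p)
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}
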