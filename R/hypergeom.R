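#' Hypergeometric survivor-function test for shared miRNA regulators
#'
#' Computes `p = P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: from a
#' universe of `N` miRNAs, one RNA is targeted by `K` of them, the other by
#' `n`, and the two share `k`. Small p means the RNAs share more regulators
#' than expected given their target-set sizes — the evidence used to call a
#' ceRNA pair. The same computation backs over-representation analysis,
#' where `N` is the gene universe, `K` a term's size, `n` the query list
#' size and `k` the hits.
#'
#' By default the tail sum is accumulated in log space
#' (`lchoose` + log-sum-exp), which is stable for large universes; the
#' direct path sums `choose()` ratios and is retained for cross-checking.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K,n the two set sizes (each <= N).
#' @param N universe size.
#' @param log_space use the log-space path (default `TRUE`).
#' @return `P(X >= k)`, a probability in (0, 1]. Vectorized over `k`, `K`,
#'   `n`, `N`.
#' @export
#' @examples
#' hypergeom_shared(3, 4, 5, 10) # 66/252
hypergeom_shared <- function(k, K, n, N, log_space = TRUE) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  with(args, {
    if (any(k < 0 | K < 0 | n < 0 | N < 0)) {
      abort("hypergeometric arguments must be non-negative")
    }
    if (any(K > N | n > N)) abort("K and n must not exceed N")
    if (any(k > pmin(K, n))) abort("k must not exceed min(K, n)")
    vapply(seq_along(k), function(j) {
      hyper_upper_tail(k[j], K[j], n[j], N[j], log_space)
    }, numeric(1))
  })
}

hyper_upper_tail <- function(k, K, n, N, log_space) {
  if (k <= max(0, K + n - N)) {
    return(1)
  }
  i <- k:min(K, n)
  if (log_space) {
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    min(exp(logsumexp(lt)), 1)
  } else {
    min(sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n), 1)
  }
}

# minimal common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  bad <- lengths(xs) != 1 & lengths(xs) != len
  if (any(bad)) abort("arguments must have length 1 or a common length")
  lapply(xs, rep_len, length.out = len)
}
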