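#' Hypergeometric and Fisher's noncentral hypergeometric distributions
#'
#' The statistical kernel of the package. The urn has `N` genes (or miRNAs),
#' `K` of which are "successes" (e.g. members of a disease gene list); `n`
#' items are drawn (a miRNA's predicted target set) and `k` is the observed
#' overlap. Under Fisher's noncentral variant each success carries an odds
#' multiplier `omega` relative to a failure, conditioned on the total draw
#' size; `omega = 1` recovers the central distribution.
#'
#' All tail probabilities are the upper (enrichment) tail
#' \eqn{P(X \ge k)}: the "crossover probability" of seeing at least the
#' observed overlap. Probabilities are accumulated in log space so the
#' noncentral mass is stable for populations of tens of thousands of genes.
#'
#' @param N population size (non-negative integer).
#' @param K number of successes in the population, `0 <= K <= N`.
#' @param n draw size, `0 <= n <= N`.
#' @param k observed overlap. For `hypergeom_pmf`/`fnch_pmf` a `k` outside
#'   the support `max(0, n + K - N) .. min(n, K)` returns 0 (a total
#'   function, so tail sums never error); for the `_sf` functions a `k` at
#'   or below the support minimum returns 1.
#' @param omega odds multiplier for success items, `> 0`. May be `Inf`,
#'   which puts all mass on the support maximum.
#'
#' @return A probability (vectorised over `k`).
#'
#' @examples
#' hypergeom_pmf(4, 2, 2, 1)            # 2/3
#' hypergeom_sf(56, 43, 11, 11)         # ~0.0386
#' fnch_pmf(4, 2, 2, 2, omega = 2)      # 4/13
#' fnch_sf(4, 2, 2, 1, omega = 2)       # 12/13
#' @name nchg
NULL

check_urn <- function(N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L)
    stop("urn parameters N, K, n must be scalars")
  if (any(c(N, K, n) < 0) || any(c(N, K, n) != round(c(N, K, n))))
    stop("urn parameters must be non-negative integers")
  if (K > N) stop("K must satisfy 0 <= K <= N (got K=", K, ", N=", N, ")")
  if (n > N) stop("n must satisfy 0 <= n <= N (got n=", n, ", N=", N, ")")
  invisible(TRUE)
}

support_min <- function(N, K, n) max(0L, n + K - N)
support_max <- function(K, n) min(n, K)

#' @rdname nchg
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  check_urn(N, K, n)
  out <- numeric(length(k))
  ok <- k == round(k)
  out[ok] <- stats::dhyper(k[ok], m = K, n = N - K, k = n)
  out
}

#' @rdname nchg
#' @export
hypergeom_sf <- function(N, K, n, k) {
  check_urn(N, K, n)
  # P(X >= k) = P(X > k - 1); floor so non-integer k means P(X >= ceiling(k))
  stats::phyper(ceiling(k) - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' @rdname nchg
#' @export
hypergeom_cdf <- function(N, K, n, k) {
  check_urn(N, K, n)
  stats::phyper(k, m = K, n = N - K, k = n)
}

# log weights over the full support: lchoose(K,j) + lchoose(N-K,n-j) + j*log(w)
fnch_log_weights <- function(N, K, n, omega) {
  j <- support_min(N, K, n):support_max(K, n)
  lw <- lchoose(K, j) + lchoose(N - K, n - j)
  if (is.infinite(omega)) {
    # all conditional mass at the support maximum
    lw <- ifelse(j == support_max(K, n), 0, -Inf)
  } else {
    lw <- lw + j * log(omega)
  }
  list(j = j, lw = lw)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @rdname nchg
#' @export
fnch_pmf <- function(N, K, n, k, omega = 1) {
  check_urn(N, K, n)
  if (length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("omega must be a single positive number")
  w <- fnch_log_weights(N, K, n, omega)
  lz <- logsumexp(w$lw)
  vapply(k, function(ki) {
    if (ki != round(ki) || ki < w$j[1] || ki > w$j[length(w$j)]) return(0)
    exp(w$lw[match(ki, w$j)] - lz)
  }, numeric(1))
}

#' @rdname nchg
#' @export
fnch_sf <- function(N, K, n, k, omega = 1) {
  check_urn(N, K, n)
  if (length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("omega must be a single positive number")
  w <- fnch_log_weights(N, K, n, omega)
  lz <- logsumexp(w$lw)
  vapply(k, function(ki) {
    ki <- ceiling(ki)
    if (ki <= w$j[1]) return(1)
    if (ki > w$j[length(w$j)]) return(0)
    exp(logsumexp(w$lw[w$j >= ki]) - lz)
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of raw p-values,
#' order-preserving with respect to input positions and capped at 1.
#'
#' @param raw numeric vector of p-values in `[0, 1]`.
#' @return A list with components `raw` and `adjusted`, both in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted  # all 0.04
#' @export
bh_adjust <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw) || any(raw < 0 | raw > 1))
    stop("raw p-values must all lie in [0, 1]")
  list(raw = raw, adjusted = stats::p.adjust(raw, method = "BH"))
}
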