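# Independent oracles: direct (non-log) enumeration over the support with
# choose() products and ascending summation. Deliberately shares no code
# with the package's log-space implementation. For N <= 200 all quantities
# stay inside double range and the relative error is ~1e-12; for N <= 20
# every binomial and product is an exactly representable integer.

oracle_hyper_pmf <- function(N, K, n, k) {
  if (k < max(0, n + K - N) || k > min(n, K)) return(0)
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

oracle_hyper_sf <- function(N, K, n, k) {
  ks <- max(0, n + K - N):min(n, K)
  ks <- ks[ks >= k]
  if (!length(ks)) return(0)
  w <- vapply(ks, function(j) choose(K, j) * choose(N - K, n - j),
              numeric(1))
  sum(sort(w)) / choose(N, n)
}

oracle_fnch_pmf <- function(N, K, n, k, omega) {
  ks <- max(0, n + K - N):min(n, K)
  w <- vapply(ks, function(j)
    choose(K, j) * choose(N - K, n - j) * omega^j, numeric(1))
  if (k < ks[1] || k > ks[length(ks)]) return(0)
  w[match(k, ks)] / sum(sort(w))
}

oracle_fnch_sf <- function(N, K, n, k, omega) {
  ks <- max(0, n + K - N):min(n, K)
  w <- vapply(ks, function(j)
    choose(K, j) * choose(N - K, n - j) * omega^j, numeric(1))
  if (k <= ks[1]) return(1)
  sum(sort(w[ks >= k])) / sum(sort(w))
}

# conditioned-Bernoulli Monte-Carlo oracle for Fisher's noncentral
# distribution: success items are Bernoulli(omega*p/(1+omega*p)), failures
# Bernoulli(p/(1+p)), conditioned on the total drawn equalling n by
# rejection; returns the empirical upper tail and its standard error
mc_fnch_sf <- function(N, K, n, k, omega, n_accept = 1e5, p = NULL) {
  if (is.null(p)) p <- n / N  # centre acceptance near the target total
  ps <- c(rep(omega * p / (1 + omega * p), K), rep(p / (1 + p), N - K))
  acc <- integer(0)
  while (length(acc) < n_accept) {
    draws <- matrix(stats::runif(N * 20000) < ps, nrow = N)
    tot <- colSums(draws)
    succ <- colSums(draws[seq_len(K), , drop = FALSE])
    acc <- c(acc, succ[tot == n])
  }
  acc <- acc[seq_len(n_accept)]
  est <- mean(acc >= k)
  list(est = est, se = sqrt(est * (1 - est) / n_accept))
}

# random valid urn draws for property-style tests
random_urns <- function(n_cases, n_max, seed) {
  set.seed(seed)
  data.frame(
    N = N <- sample(2:n_max, n_cases, replace = TRUE),
    K = K <- vapply(N, function(x) sample(0:x, 1), integer(1)),
    n = vapply(N, function(x) sample(0:x, 1), integer(1)),
    omega = exp(stats::runif(n_cases, -2, 2)))
}
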