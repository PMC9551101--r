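test_that("central hypergeometric pmf and sf match enumeration and known values", {
  expect_equal(hypergeom_pmf(4, 2, 2, 1), 2 / 3)
  expect_equal(hypergeom_pmf(10, 0, 5, 0), 1)
  expect_equal(hypergeom_pmf(10, 4, 5, 7), 0)   # outside support
  expect_equal(hypergeom_pmf(10, 4, 5, 2.5), 0) # non-integer

  # printed-count urns, frozen from the enumeration oracle
  expect_equal(hypergeom_pmf(56, 43, 11, 11), oracle_hyper_pmf(56, 43, 11, 11))
  expect_equal(hypergeom_sf(56, 43, 11, 11), 0.0386294, tolerance = 1e-5)
  expect_equal(hypergeom_sf(56, 34, 11, 10), 0.0212953, tolerance = 1e-5)
  expect_equal(hypergeom_sf(56, 15, 11, 5), 0.1207362, tolerance = 1e-5)

  # sf at the support minimum is 1
  expect_equal(hypergeom_sf(30, 25, 10, max(0, 10 + 25 - 30)), 1)

  # parameter validation
  expect_error(hypergeom_pmf(4, 5, 2, 1), "K must")
  expect_error(hypergeom_sf(4, 2, 5, 1), "n must")
})

test_that("sf + cdf(k-1) = 1 exactly on small integer-exact instances", {
  # for N <= 20 all binomial weights are exact integers in doubles, so the
  # oracle's tail split sums to 1 with no rounding at all; the package
  # tails must agree with those exact values to double precision
  urns <- random_urns(40, 20, seed = 11)
  for (i in seq_len(nrow(urns))) {
    N <- urns$N[i]; K <- urns$K[i]; n <- urns$n[i]
    ks <- max(0, n + K - N):min(n, K)
    w <- vapply(ks, function(j) choose(K, j) * choose(N - K, n - j),
                numeric(1))
    for (k in ks) {
      expect_identical((sum(w[ks >= k]) + sum(w[ks < k])) / sum(w), 1)
      expect_equal(hypergeom_sf(N, K, n, k), sum(w[ks >= k]) / sum(w),
                   tolerance = 1e-14)
      expect_equal(hypergeom_cdf(N, K, n, k - 1), sum(w[ks < k]) / sum(w),
                   tolerance = 1e-14)
    }
  }
})

test_that("fnch pmf matches enumeration and reduces to the central case", {
  expect_equal(fnch_pmf(4, 2, 2, 2, omega = 2), 4 / 13)
  expect_equal(fnch_sf(4, 2, 2, 1, omega = 2), 12 / 13)
  expect_equal(fnch_sf(4, 2, 2, 2, omega = 1e14), 1, tolerance = 1e-10)
  expect_equal(fnch_pmf(4, 2, 2, 2, omega = Inf), 1)
  expect_error(fnch_pmf(4, 2, 2, 1, omega = 0), "omega")
  expect_error(fnch_sf(4, 2, 2, 1, omega = -1), "omega")

  urns <- random_urns(60, 200, seed = 7)
  for (i in seq_len(nrow(urns))) {
    N <- urns$N[i]; K <- urns$K[i]; n <- urns$n[i]; w <- urns$omega[i]
    supp <- max(0, n + K - N):min(n, K)
    # omega = 1 equals the central distribution pointwise
    expect_equal(fnch_pmf(N, K, n, supp, omega = 1),
                 hypergeom_pmf(N, K, n, supp), tolerance = 1e-12)
    # pmf sums to 1 over the support
    expect_equal(sum(fnch_pmf(N, K, n, supp, omega = w)), 1,
                 tolerance = 1e-10)
    # agreement with the enumeration oracle (relative error)
    k <- supp[ceiling(length(supp) / 2)]
    po <- oracle_fnch_pmf(N, K, n, k, w)
    expect_equal(fnch_pmf(N, K, n, k, omega = w), po,
                 tolerance = 1e-9)
    so <- oracle_fnch_sf(N, K, n, k, w)
    expect_equal(fnch_sf(N, K, n, k, omega = w), so, tolerance = 1e-9)
    # sf is 1 at the support minimum, and non-increasing in k
    sf <- fnch_sf(N, K, n, supp, omega = w)
    expect_equal(sf[1], 1)
    expect_true(all(diff(sf) <= 1e-12))
  }
})

test_that("fnch upper tail is non-decreasing in omega", {
  urns <- random_urns(25, 100, seed = 13)
  for (i in seq_len(nrow(urns))) {
    N <- urns$N[i]; K <- urns$K[i]; n <- urns$n[i]
    supp <- max(0, n + K - N):min(n, K)
    k <- supp[length(supp)]
    sf <- vapply(c(0.25, 0.5, 1, 2, 4, 8),
                 function(w) fnch_sf(N, K, n, k, omega = w), numeric(1))
    expect_true(all(diff(sf) >= -1e-12))
  }
})

test_that("fnch tail agrees with the conditional test in stats::fisher.test", {
  # fisher.test's one-sided p at a null odds ratio is the same Fisher
  # noncentral upper tail; an implementation-independent cross-check
  cases <- list(c(20, 8, 9, 5, 2), c(40, 15, 12, 7, 0.5),
                c(60, 30, 20, 13, 3))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; n <- cs[3]; k <- cs[4]; w <- cs[5]
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    pf <- stats::fisher.test(tab, or = w, alternative = "greater")$p.value
    expect_equal(fnch_sf(N, K, n, k, omega = w), pf, tolerance = 1e-9)
  }
})

test_that("fnch log-space path is stable for large populations", {
  # N of 25000 genes: finite, in [0,1], monotone tail
  p <- fnch_sf(25000, 2000, 300, c(10, 24, 40, 60), omega = 1.5)
  expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
  expect_true(all(diff(p) <= 0))
  expect_equal(sum(fnch_pmf(25000, 2000, 300, 0:300, omega = 1.5)), 1,
               tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up definition and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_equal(bh_adjust(0.5)$adjusted, 0.5)
  expect_equal(bh_adjust(c(1.0, 0.001))$adjusted, c(1.0, 0.002))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
  # positional order preserved under shuffling
  set.seed(1)
  p <- runif(50)
  idx <- sample(50)
  expect_equal(bh_adjust(p[idx])$adjusted, bh_adjust(p)$adjusted[idx])
  # adjusted values monotone when raws sorted ascending, all in [0,1]
  adj <- bh_adjust(sort(p))$adjusted
  expect_true(all(diff(adj) >= 0) && all(adj >= 0 & adj <= 1))
})
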