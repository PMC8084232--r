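test_that("per-site diversity equals exhaustive pair counting for all n <= 8", {
  for (n in 2:8) {
    for (k in 0:n) {
      alleles <- c(rep(1L, k), rep(0L, n - k))
      expect_equal(site_pi(k, n), pi_pair_oracle(alleles),
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
  # stated hand-arithmetic cases
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_equal(site_pi(7, 14), 2 * 7 * 7 / (14 * 13))
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_equal(site_pi(1, 1), 0)      # fewer than two alleles
  expect_error(site_pi(5, 4), "alt_count")
})

test_that("per-site diversity is symmetric in the two alleles", {
  for (n in c(2, 5, 9, 14)) {
    k <- 0:n
    expect_equal(site_pi(k, n), site_pi(n - k, n))
  }
})

test_that("window diversity is the per-site sum over the span", {
  expect_equal(window_pi(numeric(), 50000), 0)
  expect_equal(window_pi(2 / 3, 50000), 2 / 3 / 50000)
  expect_equal(window_pi(2 / 3, 50000), 1.3333e-5, tolerance = 1e-4)
  set.seed(42)
  ps <- site_pi(rbinom(40, 20, 0.3), 20)
  acc <- 0
  for (v in ps) acc <- acc + v          # explicit per-site accumulation
  expect_equal(window_pi(ps, 50000), acc / 50000)
})

test_that("W&C components match hand-checkable configurations", {
  # identical frequency and heterozygosity, equal n: the among-population
  # variance term s^2 is exactly 0, so the a estimate is its (non-positive)
  # finite-sample correction; it must never be positive, and the oracle
  # must agree. (The panmictic-null test below checks that the estimator
  # centres on 0 in expectation.)
  d <- c(0L, 1L, 1L, 2L)
  comp <- wc_fst_components(d, d)
  expect_lte(comp$a, 0)
  expect_equal(unlist(comp), wc_site_oracle(d, d), tolerance = 1e-12,
               ignore_attr = TRUE)
  # fixed difference, n1 = n2 = 5 -> window-level F_ST = 1
  comp2 <- wc_fst_components(rep(0L, 5), rep(2L, 5))
  expect_equal(window_fst(comp2), 1)
  # a population with no called genotype -> NA row with a log message
  expect_message(comp3 <- wc_fst_components(c(NA, NA), c(0L, 1L)), "skipped")
  expect_true(all(is.na(comp3)))
})

test_that("W&C components agree with an independent textbook oracle to 1e-12", {
  set.seed(123)
  n_sites <- 400
  t_m <- matrix(rbinom(n_sites * 7, 2, rep(runif(n_sites, 0.02, 0.98), 7)),
                nrow = n_sites)
  r_m <- matrix(rbinom(n_sites * 15, 2, rep(runif(n_sites, 0.02, 0.98), 15)),
                nrow = n_sites)
  t_m[runif(length(t_m)) < 0.1] <- NA
  r_m[runif(length(r_m)) < 0.1] <- NA
  comp <- suppressMessages(wc_fst_components(t_m, r_m))
  for (i in sample(n_sites, 100)) {
    o <- wc_site_oracle(t_m[i, ], r_m[i, ])
    expect_equal(unlist(comp[i, ]), o, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("window F_ST is a ratio of sums, undefined when empty", {
  expect_true(is.na(window_fst(data.frame(a = numeric(), b = numeric(),
                                          c = numeric()))))
  # all sites with a = 0 but positive b + c -> exactly 0
  expect_equal(window_fst(data.frame(a = c(0, 0), b = c(0.1, 0.2),
                                     c = c(0.05, 0))), 0)
  # zero denominator -> NA, not 0
  expect_true(is.na(window_fst(data.frame(a = 0, b = 0, c = 0))))
  # ratio of sums on random components matches explicit summation
  set.seed(5)
  comp <- data.frame(a = rnorm(20, 0.01, 0.02), b = runif(20, 0, 0.2),
                     c = runif(20, 0, 0.2))
  expect_equal(window_fst(comp), sum(comp$a) / sum(comp$a + comp$b + comp$c))
  # negative estimates are retained as computed
  compn <- data.frame(a = -0.01, b = 0.2, c = 0.1)
  expect_lt(window_fst(compn), 0)
})

test_that("Hudson estimator agrees on the extremes", {
  expect_equal(window_fst(hudson_fst_components(rep(0L, 5), rep(2L, 5))), 1)
  set.seed(6)
  d1 <- matrix(rbinom(200 * 10, 2, 0.5), nrow = 200)
  d2 <- matrix(rbinom(200 * 10, 2, 0.5), nrow = 200)
  f <- window_fst(hudson_fst_components(d1, d2))
  expect_lt(abs(f), 0.05)   # panmictic -> near zero
})

test_that("low-diversity score is a guarded, monotone -log10 transform", {
  expect_equal(diversity_score(0.001, epsilon = 0), 3)
  expect_equal(diversity_score(0), -log10(1e-8))
  expect_true(is.finite(diversity_score(0)))
  pis <- sort(runif(50, 0, 0.01))
  sc <- diversity_score(pis)
  expect_true(all(diff(sc) <= 0))   # pi1 < pi2 => score1 > score2
  expect_error(diversity_score(-0.1), ">= 0")
})

test_that("window F_ST of two samples from one panmictic pool centres on zero", {
  set.seed(21)
  n_sites <- 10000          # 500 windows x 20 sites
  p <- runif(n_sites, 0.05, 0.95)
  d1 <- matrix(rbinom(n_sites * 20, 2, rep(p, 20)), nrow = n_sites)
  d2 <- matrix(rbinom(n_sites * 20, 2, rep(p, 20)), nrow = n_sites)
  comp <- wc_fst_components(d1, d2)
  win <- rep(seq_len(500), each = 20)
  fst <- vapply(split(seq_len(n_sites), win),
                function(i) window_fst(comp[i, ]), 0)
  expect_lt(mean(abs(fst)), 0.02)
})

test_that("windowed diversity recovers the simulated heterozygosity within 5%", {
  set.seed(31)
  n_sites <- 1e5
  p <- runif(n_sites, 0.1, 0.9)
  dos <- matrix(rbinom(n_sites * 20, 2, rep(p, 20)), nrow = n_sites)
  alt <- rowSums(dos)
  pi_est <- sum(site_pi(alt, 40))
  pi_true <- sum(2 * p * (1 - p))
  expect_equal(pi_est / pi_true, 1, tolerance = 0.05)
})
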