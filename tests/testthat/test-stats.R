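# Independent conditional-NB oracle: enumerate the negative-hypergeometric
# mass over all splits of the total via dnbinom products.
nb_oracle <- function(ya, yb, ra, rb, disp) {
  n <- ya + yb
  w <- dnbinom(0:n, size = ra / disp, prob = 0.5) *
    dnbinom(n:0, size = rb / disp, prob = 0.5)
  w <- w / sum(w)
  sum(w[w <= w[ya + 1] * (1 + 1e-12)])
}

test_that("balanced outcomes are not significant", {
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), 1e6, 1e6, 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 1e6, 1e6, 0.1), 1)
})

test_that("the Poisson limit reduces to the two-sided binomial exact test", {
  # closed form: totals (10, 0), equal library sizes
  expect_equal(nb_exact_test(10, 0, 1, 1, dispersion = 0), 2 / 1024)
  # independent binomial oracle across all splits of n <= 50
  for (n in c(5L, 20L, 50L)) for (ya in 0:n) {
    w <- dbinom(0:n, n, 0.5)
    p_oracle <- sum(w[w <= w[ya + 1] * (1 + 1e-12)])
    expect_equal(nb_exact_test(ya, n - ya, 1, 1, 0), p_oracle,
                 tolerance = 1e-9)
  }
})

test_that("small-total p-values match brute-force enumeration", {
  set.seed(1)
  for (i in 1:100) {
    ya <- sample(0:20, 1); yb <- sample(0:10, 1)
    if (ya + yb == 0) next
    ra <- sample(1:3, 1); rb <- sample(1:3, 1)
    disp <- runif(1, 0.05, 1)
    expect_equal(
      nb_exact_test(rep(ya / ra, ra), rep(yb / rb, rb), 1, 1, disp),
      nb_oracle(ya, yb, ra, rb, disp), tolerance = 1e-10)
  }
})

test_that("the exact test agrees with edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  cnt <- matrix(rnbinom(300 * 4, mu = 50, size = 5), 300, 4)
  p_ours <- vapply(seq_len(300), function(i)
    nb_exact_test(cnt[i, 1:2], cnt[i, 3:4], 1e6, 1e6, 0.2), 0)
  p_ref <- edgeR::exactTestBySmallP(cnt[, 1:2], cnt[, 3:4],
                                    dispersion = 0.2)
  expect_equal(p_ours, as.numeric(p_ref), tolerance = 1e-10)
})

test_that("rejection rate grows with the true fold change", {
  set.seed(5)
  rate <- vapply(c(1, 2, 4, 8), function(fc) {
    mu <- 30
    a <- matrix(rnbinom(300 * 2, mu = mu, size = 10), 300, 2)
    b <- matrix(rnbinom(300 * 2, mu = mu * fc, size = 10), 300, 2)
    mean(vapply(seq_len(300), function(i)
      nb_exact_test(a[i, ], b[i, ], 1e6, 1e6, 0.1), 0) < 0.05)
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.1)
  expect_gt(rate[4], 0.9)
})

test_that("dispersion estimation recovers the simulation truth", {
  set.seed(3)
  groups <- rep(c("a", "b"), each = 3)
  mp <- matrix(rpois(500 * 6, 100), 500, 6)
  expect_lt(estimate_common_dispersion(mp, rep(1e6, 6), groups), 0.02)
  mn <- matrix(rnbinom(500 * 6, mu = 100, size = 1 / 0.4), 500, 6)
  est <- estimate_common_dispersion(mn, rep(1e6, 6), groups)
  expect_gt(est, 0.25); expect_lt(est, 0.55)
  const <- matrix(7, 20, 6)
  expect_equal(estimate_common_dispersion(const, rep(1e6, 6), groups), 0)
  expect_warning(
    est0 <- estimate_common_dispersion(mn[, c(1, 4)], rep(1e6, 2),
                                       c("a", "b")),
    "no replication")
  expect_equal(est0, 0.1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(100)^2
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))      # monotone in rank
  expect_true(all(q >= p - 1e-12 & q <= 1))   # q >= p, capped at 1
  expect_equal(bh_fdr(p[o]), q[o])  # permutation-equivariant
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
  expect_error(bh_fdr(1.4), "0,1")
})

test_that("segregation chi-square matches the closed form", {
  expect_equal(segregation_test(89, 178)$chi2, 0)
  s <- segregation_test(83, 178)
  expect_equal(s$chi2, (83 - 89)^2 / 89 + (95 - 89)^2 / 89)
  expect_equal(s$chi2, 0.809, tolerance = 5e-4)
  expect_equal(s$p, pchisq(0.8089888, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(segregation_test(0, 178)$chi2, 178)
  expect_error(segregation_test(200, 178), "n_mutant")
})

test_that("effective library sizes undo a composition shift", {
  set.seed(8)
  mu <- rexp(400, 1 / 50)
  cnt <- cbind(rpois(400, mu), rpois(400, mu),
               rpois(400, mu * 0.4), rpois(400, mu * 0.4))
  eff <- effective_library_sizes(cnt, rep(1e6, 4))
  expect_equal(eff[3] / eff[1], 0.4, tolerance = 0.05)
})
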