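test_that("lost-count parameters follow the closed form", {
  p <- lost_count_params(1, mu = 10, phi = 2, beta = 0.1)
  expect_equal(p$zeta_mean, 9)
  expect_equal(p$zeta_size, 3)
  p0 <- lost_count_params(0, mu = 10, phi = 2, beta = 0.5)
  expect_equal(p0$zeta_mean, 10 / 7)
  expect_equal(p0$zeta_size, 2)
  expect_equal(lost_count_params(3:5, 10, 2, 1)$zeta_mean, rep(0, 3))
  expect_error(lost_count_params(-1, 1, 1, 0.5), "non-negative")
  expect_error(lost_count_params(1, 1, 1, 0), "beta")
})

test_that("posterior mean and variance evaluate to the closed forms", {
  expect_equal(posterior_mean(1, 10, 2, 0.1), 10)
  expect_equal(posterior_var(1, 10, 2, 0.1), 36)
  expect_equal(posterior_mean(0, 10, 2, 0.1), 6)
  expect_equal(posterior_var(0, 10, 2, 0.1), 24)
  expect_equal(posterior_mean(5, 3, 7, 1), 5)
  expect_equal(posterior_var(5, 3, 7, 1), 0)
  # mean = x + E[zeta], always >= x
  g <- posterior_grid()
  expect_equal(posterior_mean(g$x, g$mu, g$phi, g$beta),
               g$x + lost_count_params(g$x, g$mu, g$phi, g$beta)$zeta_mean)
  expect_true(all(posterior_mean(g$x, g$mu, g$phi, g$beta) >= g$x))
})

test_that("posterior pmf matches the brute-force Bayes oracle", {
  g <- posterior_grid()
  worst <- 0
  for (i in seq_len(nrow(g))) {
    n <- 0:500
    closed <- posterior_pmf(n, g$x[i], g$mu[i], g$phi[i], g$beta[i])
    brute <- oracle_posterior(n, g$x[i], g$mu[i], g$phi[i], g$beta[i])
    worst <- max(worst, max(abs(closed - brute)))
  }
  expect_lt(worst, 1e-10)
})

test_that("posterior pmf normalizes and reproduces the moment identities", {
  g <- posterior_grid()
  for (i in seq_len(nrow(g))) {
    n <- 0:3000
    p <- posterior_pmf(n, g$x[i], g$mu[i], g$phi[i], g$beta[i])
    expect_lt(abs(sum(p) - 1), 1e-8)
    m_num <- sum(n * p)
    v_num <- sum((n - m_num)^2 * p)
    m_cl <- posterior_mean(g$x[i], g$mu[i], g$phi[i], g$beta[i])
    v_cl <- posterior_var(g$x[i], g$mu[i], g$phi[i], g$beta[i])
    expect_lt(abs(m_num - m_cl) / m_cl, 1e-8)
    if (v_cl > 0) expect_lt(abs(v_num - v_cl) / v_cl, 1e-8)
  }
})

test_that("posterior pmf support and degenerate cases behave", {
  expect_equal(posterior_pmf(0:2, x = 3, mu = 5, phi = 1, beta = 0.2),
               rep(0, 3))
  expect_equal(posterior_pmf(4, x = 4, mu = 5, phi = 1, beta = 1), 1)
  expect_equal(posterior_pmf(5, x = 4, mu = 5, phi = 1, beta = 1), 0)
})

test_that("MAP is the argmax of the posterior pmf with ties to the smaller count", {
  expect_identical(posterior_map(2, 10, 2, 0.3), 6)
  expect_identical(posterior_map(7, 10, 2, 1), 7)
  expect_identical(posterior_map(0, 10, 2, 0.5), 0)
  # exhaustive argmax oracle over the grid; exact ties (pmf ratio = 1 at an
  # integer crossing) break to the smaller count, so the oracle takes the
  # first n within float noise of the maximum
  g <- posterior_grid()
  for (i in seq_len(nrow(g))) {
    n <- 0:2000
    p <- posterior_pmf(n, g$x[i], g$mu[i], g$phi[i], g$beta[i])
    oracle_map <- n[which(p >= max(p) * (1 - 1e-12))[1]]
    expect_equal(posterior_map(g$x[i], g$mu[i], g$phi[i], g$beta[i]),
                 oracle_map)
  }
})

test_that("posterior sampling agrees with the closed-form moments and pmf", {
  set.seed(1234)
  s <- posterior_sample(1, 10, 2, 0.1, n_samples = 1e5)
  se <- sqrt(36 / 1e5)
  expect_lt(abs(mean(s) - 10), 3 * se)
  expect_lt(abs(var(s) - 36) / 36, 0.05)
  expect_true(all(s >= 1))

  # total variation distance between empirical and exact pmf
  emp <- table(factor(s, levels = 0:max(s))) / length(s)
  exact <- posterior_pmf(0:max(s), 1, 10, 2, 0.1)
  expect_lt(0.5 * sum(abs(as.vector(emp) - exact)), 0.01)

  expect_true(all(posterior_sample(4, 8, 2, 1, n_samples = 50) == 4))
})

test_that("marginal pmf is the NB of thinned counts and normalizes", {
  expect_equal(marginal_pmf(0, 10, 2, 0.1), (2 / 3)^2)
  expect_equal(marginal_pmf(1, 10, 2, 0.1), 8 / 27)
  expect_equal(marginal_pmf(3, 10, 2, 1), dnbinom(3, size = 2, mu = 10))
  expect_lt(abs(sum(marginal_pmf(0:5000, 10, 2, 0.1)) - 1), 1e-8)
})

test_that("posterior mean decreases in capture efficiency at fixed inputs", {
  betas <- seq(0.02, 1, by = 0.02)
  for (x in c(0, 1, 5)) {
    m <- posterior_mean(x, mu = 10, phi = 2, beta = betas)
    expect_true(all(diff(m) <= 1e-12))
  }
})

test_that("non-UMI rescaling divides and rounds half-up", {
  m <- tiny_counts(matrix(c(10, 7, 3, 0), 2, 2))
  expect_identical(unname(unclass(scale_non_umi(m, 1))),
                   unname(unclass(m)))
  out <- scale_non_umi(m, 2)
  expect_equal(unname(unclass(out)), matrix(c(5, 4, 2, 0), 2, 2))
  expect_equal(unclass(scale_non_umi(tiny_counts(matrix(10, 1, 1)), 5))[1, 1],
               2)
  expect_error(scale_non_umi(m, 0.5), "amplification")
})
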