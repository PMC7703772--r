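test_that("true counts hit the requested NB moments", {
  spec <- sim_spec(n_genes = 5, n_cells = 5000,
                   mu = c(0.5, 2, 8, 30, 100),
                   phi = c(0.5, 1, 3, 10, 50), beta_cv = 0, seed = 3)
  set.seed(spec$seed)
  x0 <- simulate_true_counts(spec)
  mu <- spec$mu
  phi <- spec$phi
  sample_mean <- rowMeans(x0)
  sample_var <- apply(x0, 1, var)
  se <- sqrt((mu + mu^2 / phi) / 5000)
  expect_true(all(abs(sample_mean - mu) < 3 * se))
  expect_true(all(abs(sample_var - (mu + mu^2 / phi)) /
                    (mu + mu^2 / phi) < 0.25))
})

test_that("simulation is deterministic under the spec seed", {
  spec <- sim_spec(n_genes = 30, n_cells = 20, seed = 77)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(unclass(a$truth), unclass(b$truth))
  expect_identical(unclass(a$observed), unclass(b$observed))
  expect_identical(a$beta$beta, b$beta$beta)
})

test_that("capture efficiencies have the requested mean and spread", {
  spec0 <- sim_spec(n_cells = 500, beta_bar = 0.1, beta_cv = 0, seed = 1)
  expect_equal(simulate_beta(spec0)$beta, rep(0.1, 500))

  spec <- sim_spec(n_cells = 2000, beta_bar = 0.1, beta_cv = 0.3, seed = 2)
  set.seed(2)
  b <- simulate_beta(spec)$beta
  expect_true(all(b > 0 & b < 1))
  expect_lt(abs(mean(b) - 0.1), 2 * 0.1 * 0.3 / sqrt(2000))
  # higher dispersion spreads per-cell dropout (monotone property)
  spread <- function(cv) {
    sim <- simulate_dataset(sim_spec(n_genes = 300, n_cells = 300,
                                     beta_bar = 0.1, beta_cv = cv,
                                     seed = 5))
    sd(cell_dropout(sim$observed)$dropout)
  }
  expect_gt(spread(0.4), spread(0.05))
})

test_that("binomial thinning preserves the capture expectation", {
  spec <- sim_spec(n_genes = 2000, n_cells = 8, beta_bar = 0.2,
                   beta_cv = 0.3, seed = 9)
  sim <- simulate_dataset(spec)
  x0 <- unclass(sim$truth)
  x <- unclass(sim$observed)
  expect_true(all(x <= x0))
  ratio <- colMeans(x) / colMeans(x0)
  expect_true(all(abs(ratio - sim$beta$beta) < 0.02))

  expect_true(all(unclass(thin_binomial(sim$truth, rep(1, 8))) == x0))
})

test_that("NB thinned by a constant beta is NB with scaled mean", {
  set.seed(41)
  n <- 1e5
  x0 <- rnbinom(n, size = 3, mu = 20)
  x <- rbinom(n, x0, 0.25)
  # chi-square GOF against NB(mean 5, size 3)
  upper <- qnbinom(0.9999, size = 3, mu = 5)
  obs <- tabulate(pmin(x, upper) + 1L, nbins = upper + 1L)
  p_exp <- dnbinom(0:upper, size = 3, mu = 5)
  p_exp[upper + 1L] <- p_exp[upper + 1L] + pnbinom(upper, size = 3, mu = 5,
                                                   lower.tail = FALSE)
  keep <- p_exp * n >= 5
  chi <- sum((obs[keep] - n * p_exp[keep])^2 / (n * p_exp[keep]))
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("per-gene dropout matches the NB zero-class prediction", {
  spec <- sim_spec(n_genes = 40, n_cells = 3000,
                   mu = rep(c(2, 5, 10, 20), each = 10),
                   phi = rep(c(0.5, 2, 5, 20), 10),
                   beta_bar = 0.1, beta_cv = 0, seed = 15)
  sim <- simulate_dataset(spec)
  drop_obs <- gene_stats(sim$observed)$dropout
  drop_exp <- expected_dropout_nb(spec$mu * 0.1, spec$phi)
  se <- sqrt(drop_exp * (1 - drop_exp) / 3000)
  expect_true(all(abs(drop_obs - drop_exp) < 4 * se + 1e-3))
  # observed marginal mean is mu * beta_bar
  expect_true(all(abs(gene_stats(sim$observed)$mean - spec$mu * 0.1) /
                    (spec$mu * 0.1) < 0.15))
})

test_that("closed-form dropout predictions and their Poisson limit", {
  expect_equal(expected_dropout_nb(1, 2), 4 / 9)
  expect_equal(expected_dropout_nb(0, 5), 1)
  expect_equal(expected_dropout_nb(1, 1e6), exp(-1), tolerance = 1e-5)
  expect_equal(dropout_approx_exp(0), 1)
  expect_equal(dropout_approx_exp(1), exp(-1))
  m_grid <- seq(0, 10, by = 0.25)
  err <- function(phi) max(abs(dropout_approx_exp(m_grid) -
                                 expected_dropout_nb(m_grid, phi)))
  expect_lt(err(1e4), err(100))
  expect_lt(err(100), err(1))
  expect_lt(err(1e4), 1e-3)
})

test_that("two-group designs apply the fold change to group B only", {
  spec <- sim_spec(n_genes = 400, n_cells = 2000, beta_bar = 0.3,
                   beta_cv = 0, group_fraction = 0.5, de_fraction = 0.1,
                   de_lfc = 1, seed = 19)
  sim <- simulate_dataset(spec)
  g <- cell_groups(sim$truth)
  expect_identical(sort(unique(g)), c("A", "B"))
  expect_equal(sum(sim$de_genes), 40)
  x0 <- unclass(sim$truth)
  ratio <- rowMeans(x0[, g == "B"]) / rowMeans(x0[, g == "A"])
  expect_gt(median(ratio[sim$de_genes]), 1.6)
  expect_lt(abs(median(ratio[!sim$de_genes]) - 1), 0.15)
})
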