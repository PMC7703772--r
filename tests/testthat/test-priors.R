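test_that("moment estimator of the prior mean rescales by capture", {
  m <- tiny_counts(matrix(c(2, 1, 4, 2, 6, 3), 2, 3))
  expect_equal(unname(mme_mu(m, rep(1, 3))), c(4, 2))
  m2 <- tiny_counts(matrix(c(1, 0, 2, 0), 2, 2))
  expect_equal(unname(mme_mu(m2, c(0.5, 0.5))), c(3, 0))
})

test_that("moment estimator of dispersion inverts the NB variance", {
  # at beta = 1 there is no thinning correction: phi = mu^2 / (var - mu)
  row <- matrix(c(0, 2, 4, 6, 8), 1, 5)  # mean 4, var 10
  phi <- mme_phi(row, rep(1, 5), mu_hat = 4)
  expect_equal(phi, 16 / 6)
  # var == mean (Poisson-like) clamps to phi_max
  row2 <- matrix(c(2, 4, 6), 1, 3)
  expect_equal(mme_phi(row2, rep(1, 3), mu_hat = 4), 1e3)
})

test_that("moment estimators recover known NB parameters after thinning", {
  set.seed(7)
  q <- 5000
  x0 <- matrix(rnbinom(q, size = 3, mu = 8), 1, q)
  beta <- pmin(pmax(rgamma(q, shape = 25, scale = 0.1 / 25), 1e-4), 0.95)
  x <- matrix(rbinom(q, x0, rep(beta, each = 1)), 1, q)
  mu_hat <- mme_mu(x, beta)
  expect_lt(abs(mu_hat - 8) / 8, 0.1)
  phi_hat <- mme_phi(x, beta, mu_hat)
  expect_lt(abs(phi_hat - 3) / 3, 0.3)
})

test_that("dispersion shrinkage blends toward the log-log trend", {
  mu <- c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512)
  phi <- sqrt(mu)          # exact trend: log phi = 0.5 log mu
  expect_equal(shrink_phi(mu, phi, w = 0.5), phi)      # fixed point
  expect_equal(shrink_phi(mu, phi, w = 0), phi)        # raw passthrough

  phi_out <- phi
  phi_out[5] <- 40         # one extreme outlier
  shr <- shrink_phi(mu, phi_out, w = 0.5)
  # oracle: closed-form OLS fit on the 10 points, blended on log scale
  fit <- lm(log(phi_out) ~ log(mu))
  expected <- exp(0.5 * (coef(fit)[1] + coef(fit)[2] * log(mu)) +
                  0.5 * log(phi_out))
  expect_equal(shr, unname(expected))
  expect_lt(shr[5], 40)    # outlier moved toward the trend

  expect_warning(out <- shrink_phi(mu[1:3], phi[1:3]), "fewer than 10")
  expect_equal(out, phi[1:3])
})

test_that("global and local prior estimation agree on degenerate partitions", {
  sim <- simulate_dataset(sim_spec(n_genes = 80, n_cells = 60, seed = 11))
  ce <- estimate_capture(sim$observed, beta_bar = 0.1)

  one_group <- sim$observed
  cell_groups(one_group) <- rep("A", 60)
  glob <- estimate_priors(sim$observed, ce, scope = "global")
  loc <- estimate_priors(one_group, ce, scope = "local")
  expect_equal(loc$mu, glob$mu)
  expect_equal(loc$phi, glob$phi)

  # two identical groups: identical per-group priors
  dup <- count_matrix(cbind(unclass(sim$observed), unclass(sim$observed)),
                      gene_ids = rownames(sim$observed),
                      cell_ids = paste0("c", 1:120),
                      groups = rep(c("A", "B"), each = 60))
  loc2 <- estimate_priors(dup, c(ce$beta, ce$beta), scope = "local")
  a <- loc2[loc2$group == "A", c("mu", "phi")]
  b <- loc2[loc2$group == "B", c("mu", "phi")]
  expect_equal(a, b)

  expect_error(estimate_priors(sim$observed, ce, scope = "local"),
               "group labels")
  tiny_groups <- c("A", rep("B", 59))
  expect_error(estimate_priors(sim$observed, ce, scope = "local",
                               groups = tiny_groups), ">= 2 cells")
})

test_that("local priors track group-specific means", {
  set.seed(21)
  q <- 400
  mu_a <- 4
  mu_b <- 16   # 4-fold shift for the focal gene
  xa <- rnbinom(q, size = 2, mu = mu_a)
  xb <- rnbinom(q, size = 2, mu = mu_b)
  filler <- matrix(rnbinom(20 * 2 * q, size = 2, mu = 5), 20, 2 * q)
  m <- count_matrix(rbind(c(xa, xb), filler),
                    groups = rep(c("A", "B"), each = q))
  beta <- rep(1, 2 * q)
  loc <- estimate_priors(m, beta, scope = "local")
  glob <- estimate_priors(m, beta, scope = "global")
  ratio <- loc$mu[loc$group == "B"][1] / loc$mu[loc$group == "A"][1]
  expect_lt(abs(ratio - 4) / 4, 0.2)
  expect_gt(glob$mu[1], loc$mu[loc$group == "A"][1])
  expect_lt(glob$mu[1], loc$mu[loc$group == "B"][1])
})

test_that("all-zero genes are flagged, never silently dropped", {
  m <- tiny_counts(matrix(c(0, 3, 0, 5, 0, 2), 2, 3))
  pr <- estimate_priors(m, rep(0.5, 3))
  expect_identical(pr$flagged, c(TRUE, FALSE))
  expect_identical(nrow(pr), 2L)
  expect_identical(pr$mu[1], 0)
})

test_that("likelihood refinement stays near the moment estimates on clean data", {
  set.seed(31)
  q <- 800
  x <- matrix(rnbinom(3 * q, size = rep(c(1, 3, 10), q),
                      mu = rep(c(5, 10, 20), q) * 0.2), 3, q)
  beta <- rep(0.2, q)
  mme <- estimate_priors(x, beta, shrink_weight = 0)
  mle <- estimate_priors(x, beta, shrink_weight = 0, mle_refine = TRUE)
  expect_equal(mle$mu, mme$mu, tolerance = 0.15)
  # refinement must not decrease the marginal NB likelihood
  ll <- function(pr) {
    sum(vapply(1:3, function(i) {
      sum(dnbinom(x[i, ], size = pr$phi[i], mu = pr$mu[i] * beta,
                  log = TRUE))
    }, numeric(1)))
  }
  expect_gte(ll(mle) + 1e-6, ll(mme))
})
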