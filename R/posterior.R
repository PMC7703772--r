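# Closed-form posterior of the original transcript count.
#
# Model per (gene, cell): original count x0 ~ NB(mean = mu, size = phi);
# observed count x | x0 ~ Binom(x0, beta). The posterior of x0 is a shifted
# negative binomial, x0 = x + zeta with
#   zeta ~ NB(mean = mu (1 - beta) (x + phi) / (mu beta + phi),
#             size = x + phi),
# and the marginal of x is NB(mean = mu beta, size = phi). Everything below
# evaluates these forms; pmfs go through dnbinom (log-gamma based), never
# through raw binomial-coefficient products, so large counts do not overflow.

check_post_args <- function(x, mu, phi, beta) {
  if (any(x < 0) || any(x != floor(x))) {
    abort("`x` must be a non-negative integer count")
  }
  if (any(mu <= 0) || any(phi <= 0)) abort("`mu` and `phi` must be positive")
  if (any(beta <= 0) || any(beta > 1)) abort("`beta` must be in (0, 1]")
  invisible(NULL)
}

#' Lost-count posterior parameters
#'
#' The unobserved ("lost") count `zeta = x0 - x` is NB-distributed with
#' mean `mu (1 - beta) (x + phi) / (mu beta + phi)` and size `x + phi`. At
#' `beta = 1` nothing is lost and the posterior is a point mass at `x`.
#'
#' @param x observed count(s).
#' @param mu,phi gene prior mean and NB size (dispersion).
#' @param beta capture efficiency in (0, 1].
#' @return tibble with columns `x`, `zeta_mean`, `zeta_size`, `mu`, `phi`,
#'   `beta` (inputs recycled to a common length).
#' @examples
#' lost_count_params(1, mu = 10, phi = 2, beta = 0.1)  # zeta_mean 9, size 3
#' @export
lost_count_params <- function(x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  tibble::tibble(
    x = x, mu = mu, phi = phi, beta = beta,
    zeta_mean = mu * (1 - beta) * (x + phi) / (mu * beta + phi),
    zeta_size = x + phi
  )
}

#' Posterior mean of the original count
#'
#' `E[x0] = (x (mu + phi) + mu phi (1 - beta)) / (mu beta + phi)`, which is
#' `x + E[zeta]` and never below `x`. For small `phi` it tends to the plain
#' scaling estimate `x / beta`; for large `phi` it shrinks strongly toward
#' the prior mean.
#'
#' @inheritParams lost_count_params
#' @return numeric vector.
#' @examples
#' posterior_mean(1, 10, 2, 0.1)  # 10
#' posterior_mean(0, 10, 2, 0.1)  # 6: imputation of a dropout
#' @export
posterior_mean <- function(x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  (x * (mu + phi) + mu * phi * (1 - beta)) / (mu * beta + phi)
}

#' Posterior variance of the original count
#'
#' `Var[x0] = (x + phi) mu (1 - beta) (mu + phi) / (mu beta + phi)^2`;
#' zero at full capture.
#'
#' @inheritParams lost_count_params
#' @return numeric vector.
#' @examples
#' posterior_var(1, 10, 2, 0.1)  # 36
#' @export
posterior_var <- function(x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  (x + phi) * mu * (1 - beta) * (mu + phi) / (mu * beta + phi)^2
}

#' Posterior probability mass of the original count
#'
#' `P(x0 = n | x)`: zero below the observed count, otherwise the NB mass of
#' the lost count `n - x`. Computed in log space.
#'
#' @param n candidate original count(s), >= 0.
#' @inheritParams lost_count_params
#' @return numeric vector of probabilities.
#' @export
posterior_pmf <- function(n, x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  if (any(n < 0) || any(n != floor(n))) {
    abort("`n` must be a non-negative integer count")
  }
  p <- lost_count_params(x, mu, phi, beta)
  k <- n - p$x
  out <- numeric(length(k))
  pos <- k >= 0
  # beta = 1 gives a degenerate zeta (mean 0): point mass at k = 0
  deg <- rep_len(p$zeta_mean == 0, length(k))
  out[pos & deg] <- as.numeric(k[pos & deg] == 0)
  i <- pos & !deg
  if (any(i)) {
    out[i] <- exp(dnbinom(k[i], size = rep_len(p$zeta_size, length(k))[i],
                          mu = rep_len(p$zeta_mean, length(k))[i],
                          log = TRUE))
  }
  out
}

#' Posterior mode (MAP) of the original count
#'
#' `x` plus the mode of the lost-count NB. The mode is located through the
#' pmf ratio `P(k+1)/P(k) = q (k + r) / (k + 1)` with `q = m / (m + r)`:
#' the mass increases while the ratio exceeds 1, so the mode is the first
#' `k` where it drops below 1, and an exact tie (`ratio = 1`) is broken to
#' the smaller count — deterministic and conservative for imputation.
#'
#' @inheritParams lost_count_params
#' @return integer-valued numeric vector, always >= `x`.
#' @examples
#' posterior_map(2, 10, 2, 0.3)  # 6
#' posterior_map(7, 10, 2, 1)    # 7: full capture
#' @export
posterior_map <- function(x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  p <- lost_count_params(x, mu, phi, beta)
  x + nb_mode(p$zeta_mean, p$zeta_size)
}

# mode of NB(mean = m, size = r), ties to the smaller value
nb_mode <- function(m, r) {
  n <- max(length(m), length(r))
  m <- rep_len(m, n)
  r <- rep_len(r, n)
  q <- m / (m + r)
  # ratio(k) >= 1  <=>  k <= t with t = (q r - 1) / (1 - q)
  t <- (q * r - 1) / (1 - q)
  k0 <- pmax(0, floor(t))
  k1 <- k0 + 1
  out <- numeric(n)
  pos <- m > 0 & t >= 0
  if (any(pos)) {
    l0 <- dnbinom(k0[pos], size = r[pos], mu = m[pos], log = TRUE)
    l1 <- dnbinom(k1[pos], size = r[pos], mu = m[pos], log = TRUE)
    out[pos] <- ifelse(l0 >= l1, k0[pos], k1[pos])
  }
  out
}

#' Sample original counts from the posterior
#'
#' Draws `x + zeta` with `zeta ~ NB(zeta_mean, zeta_size)` (a Gamma-Poisson
#' mixture, exact for arbitrary real size). All draws are >= `x`.
#'
#' @inheritParams lost_count_params
#' @param n_samples number of posterior draws.
#' @return numeric vector of `n_samples` draws (for scalar inputs) or an
#'   `n_samples x length(x)` matrix.
#' @export
posterior_sample <- function(x, mu, phi, beta, n_samples = 1) {
  check_post_args(x, mu, phi, beta)
  stopifnot(n_samples >= 1)
  p <- lost_count_params(x, mu, phi, beta)
  k <- nrow(p)
  draws <- matrix(0, nrow = n_samples, ncol = k)
  live <- p$zeta_mean > 0
  if (any(live)) {
    draws[, live] <- rnbinom(n_samples * sum(live),
                             size = rep(p$zeta_size[live],
                                        each = n_samples),
                             mu = rep(p$zeta_mean[live], each = n_samples))
  }
  draws <- sweep(draws, 2L, p$x, "+")
  if (k == 1L) drop(draws) else draws
}

#' Marginal probability mass of the observed count
#'
#' Integrating the binomial capture over the NB prior gives an NB marginal
#' for the observed count: `x ~ NB(mean = mu beta, size = phi)`. Useful for
#' goodness-of-fit checks and likelihood-based prior refinement.
#'
#' @inheritParams lost_count_params
#' @return numeric vector of probabilities.
#' @examples
#' marginal_pmf(0, 10, 2, 0.1)  # (2/3)^2
#' @export
marginal_pmf <- function(x, mu, phi, beta) {
  check_post_args(x, mu, phi, beta)
  exp(dnbinom(x, size = phi, mu = mu * beta, log = TRUE))
}
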