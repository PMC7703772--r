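# Empirical-Bayes estimation of gene-specific NB prior parameters (mu, phi).
#
# Under the capture model the observed count of gene i in cell j has mean
# mu_i * beta_j, so x_ij / beta_j is unbiased for mu_i, and its variance
# decomposes as mu_i * (1/beta_j) + mu_i^2 / phi_i. The method-of-moments
# estimators below invert these identities; dispersion estimates are then
# shrunk toward a log-log mean-dispersion trend fitted across genes.

PHI_MIN <- 1e-3
PHI_MAX <- 1e3

#' Method-of-moments prior mean per gene
#'
#' `mu_hat[i] = mean_j(x[i, j] / beta[j])`, unbiased for the prior mean
#' because the observed count has expectation `mu[i] * beta[j]` under
#' binomial capture.
#'
#' @param cm a [count_matrix()] or numeric genes x cells matrix.
#' @param ce capture efficiencies ([estimate_capture()] tibble or bare
#'   numeric vector of per-cell probabilities).
#' @return numeric vector of length `nrow(cm)`; all-zero genes yield 0 and
#'   are flagged by [estimate_priors()].
#' @export
mme_mu <- function(cm, ce) {
  x <- as_base_matrix(cm)
  beta <- as_beta(ce, ncol(x))
  rowMeans(sweep(x, 2L, beta, "/"))
}

#' Method-of-moments prior dispersion per gene (raw, clamped)
#'
#' The variance of the rescaled counts `x/beta` exceeds the prior variance by
#' the binomial thinning term `mu * mean((1 - beta) / beta)`; subtracting it
#' leaves an estimate of `mu + mu^2 / phi`, inverted to
#' `phi_hat = mu_hat^2 / (v_hat - mu_hat)`. Non-finite or non-positive
#' intermediates (sub-Poisson genes) are clamped to `phi_max`, i.e. treated
#' as Poisson-like; all estimates are clamped into `[phi_min, phi_max]`.
#'
#' @inheritParams mme_mu
#' @param mu_hat per-gene prior means from [mme_mu()].
#' @param phi_min,phi_max clamp bounds; beyond them the NB is numerically
#'   indistinguishable from a degenerate or Poisson distribution.
#' @return numeric vector of raw dispersion estimates in
#'   `[phi_min, phi_max]`.
#' @export
mme_phi <- function(cm, ce, mu_hat, phi_min = PHI_MIN, phi_max = PHI_MAX) {
  x <- as_base_matrix(cm)
  beta <- as_beta(ce, ncol(x))
  scaled <- sweep(x, 2L, beta, "/")
  v_scaled <- apply(scaled, 1L, stats::var)
  v_hat <- v_scaled - mu_hat * mean((1 - beta) / beta)
  phi <- mu_hat^2 / (v_hat - mu_hat)
  phi[!is.finite(phi) | phi <= 0] <- phi_max
  pmin(pmax(phi, phi_min), phi_max)
}

#' Shrink dispersion estimates toward a mean-dispersion trend
#'
#' Per-gene dispersion estimates are noisy at realistic cell numbers, so they
#' are shrunk toward an ordinary-least-squares fit of `log(phi_hat)` on
#' `log(mu_hat)` across genes: the final dispersion is the blend
#' `w * fitted + (1 - w) * raw` on the log scale, back-transformed and
#' re-clamped. With fewer than 10 usable genes no trend can be fitted and the
#' raw estimates are returned with a warning.
#'
#' @param mu_hat,phi_raw per-gene estimates; genes with non-finite or
#'   non-positive `mu_hat` are passed through unshrunk.
#' @param w blend weight in `[0, 1]`; `0` returns the raw estimates.
#' @inheritParams mme_phi
#' @return numeric vector of shrunken dispersions.
#' @export
shrink_phi <- function(mu_hat, phi_raw, w = 0.5,
                       phi_min = PHI_MIN, phi_max = PHI_MAX) {
  stopifnot(length(mu_hat) == length(phi_raw), w >= 0, w <= 1)
  ok <- is.finite(mu_hat) & mu_hat > 0 & is.finite(phi_raw) & phi_raw > 0
  if (sum(ok) < 10L) {
    warn("fewer than 10 usable genes: dispersion shrinkage skipped")
    return(phi_raw)
  }
  if (w == 0) return(phi_raw)
  fit <- stats::lm(log(phi_raw[ok]) ~ log(mu_hat[ok]))
  fitted_log <- coef(fit)[[1L]] + coef(fit)[[2L]] * log(mu_hat[ok])
  out <- phi_raw
  out[ok] <- exp(w * fitted_log + (1 - w) * log(phi_raw[ok]))
  pmin(pmax(out, phi_min), phi_max)
}

#' Estimate gene-specific NB priors, globally or per cell group
#'
#' Pools information across cells to estimate each gene's prior mean `mu` and
#' dispersion `phi`: method-of-moments ([mme_mu()], [mme_phi()]) followed by
#' trend shrinkage of the dispersion ([shrink_phi()]), optionally refined by
#' a per-gene numerical NB maximum-likelihood pass initialized at the moment
#' estimates (`mle_refine = TRUE`).
#'
#' With `scope = "local"` priors are estimated within each cell group
#' (condition/batch) separately, using only that group's cells but the
#' capture efficiencies calibrated on the full dataset; local priors amplify
#' between-group expression differences and increase DE sensitivity, at the
#' cost of no longer sharing information across conditions.
#'
#' Genes never observed in any contributing cell are flagged
#' (`flagged = TRUE`, `mu = 0`): recovering a count for a gene with no
#' observation anywhere is unidentifiable, so such genes pass through
#' [recover_counts()] unchanged.
#'
#' @inheritParams mme_mu
#' @param scope `"global"` (all cells pooled) or `"local"` (per group).
#' @param groups per-cell labels; defaults to `cell_groups(cm)`. Required for
#'   `scope = "local"`.
#' @param shrink_weight dispersion shrinkage blend weight (see
#'   [shrink_phi()]).
#' @param mle_refine if `TRUE`, refine each retained gene's `(mu, phi)` by
#'   numerical maximum likelihood of the observed-count NB marginal.
#' @inheritParams mme_phi
#' @return a `gene_priors` tibble with columns `gene_id`, `mu`, `phi`,
#'   `phi_raw`, `flagged` (plus `group` when local; identical gene order
#'   within every group) and attribute `scope`.
#' @examples
#' sim <- simulate_dataset(sim_spec(n_genes = 50, n_cells = 200, seed = 1))
#' ce <- estimate_capture(sim$observed, beta_bar = 0.1)
#' estimate_priors(sim$observed, ce)
#' @export
estimate_priors <- function(cm, ce, scope = c("global", "local"),
                            groups = NULL, shrink_weight = 0.5,
                            mle_refine = FALSE,
                            phi_min = PHI_MIN, phi_max = PHI_MAX) {
  scope <- match.arg(scope)
  x <- as_base_matrix(cm)
  beta <- as_beta(ce, ncol(x))
  gene_ids <- rownames(cm) %||% paste0("gene_", seq_len(nrow(x)))
  groups <- groups %||% cell_groups(cm)

  estimate_one <- function(xg, bg, label = NULL) {
    mu <- unname(mme_mu(xg, bg))
    flagged <- mu <= 0
    phi_raw <- mme_phi(xg, bg, mu, phi_min, phi_max)
    phi <- shrink_phi(ifelse(flagged, NA_real_, mu), phi_raw,
                      w = shrink_weight, phi_min = phi_min,
                      phi_max = phi_max)
    if (mle_refine) {
      ref <- mle_refine_priors(xg, bg, mu, phi, flagged, phi_min, phi_max)
      mu <- ref$mu
      phi <- ref$phi
    }
    out <- tibble::tibble(gene_id = gene_ids, mu = mu, phi = phi,
                          phi_raw = phi_raw, flagged = flagged)
    if (!is.null(label)) out <- tibble::add_column(out, group = label,
                                                   .before = 1L)
    out
  }

  if (scope == "global") {
    out <- estimate_one(x, beta)
  } else {
    if (is.null(groups)) abort("`scope = \"local\"` requires group labels")
    if (length(groups) != ncol(x)) {
      abort("`groups` must supply one label per cell")
    }
    sizes <- table(groups)
    if (any(sizes < 2L)) {
      abort(paste0("local priors need >= 2 cells per group; too small: ",
                   paste(names(sizes)[sizes < 2L], collapse = ", ")))
    }
    out <- dplyr::bind_rows(lapply(sort(unique(groups)), function(g) {
      sel <- groups == g
      estimate_one(x[, sel, drop = FALSE], beta[sel], label = g)
    }))
  }
  structure(out, scope = scope,
            class = c("gene_priors", class(tibble::tibble())))
}

# per-gene numerical MLE of the observed-count marginal NB(mu * beta_j, phi),
# initialized at the moment estimates; opt-in refinement pass
mle_refine_priors <- function(x, beta, mu, phi, flagged, phi_min, phi_max) {
  for (i in which(!flagged)) {
    xi <- x[i, ]
    nll <- function(par) {
      -sum(dnbinom(xi, size = exp(par[2L]), mu = exp(par[1L]) * beta,
                   log = TRUE))
    }
    fit <- tryCatch(
      stats::optim(c(log(mu[i]), log(phi[i])), nll, method = "Nelder-Mead"),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$convergence == 0L) {
      mu[i] <- exp(fit$par[1L])
      phi[i] <- min(max(exp(fit$par[2L]), phi_min), phi_max)
    }
  }
  list(mu = mu, phi = phi)
}

#' @export
print.gene_priors <- function(x, ...) {
  cat(sprintf("gene_priors (%s scope): %d rows, %d flagged\n",
              attr(x, "scope"), nrow(x), sum(x$flagged)))
  NextMethod()
}
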