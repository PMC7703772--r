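# Generative simulator: ground-truth NB counts binomially thinned by
# cell-specific capture efficiencies. Supplies every fixture the tests and
# vignette use, plus closed-form dropout predictions for the classic
# dropout-versus-mean diagnostics.

#' Specify a simulated scRNA-seq experiment
#'
#' Ground truth: original counts `x0[i, j] ~ NB(mean = mu[i], size = phi[i])`
#' per cell; observation: `x[i, j] ~ Binom(x0[i, j], beta[j])`. When gene
#' means are not supplied they are drawn log-normal (`meanlog = 1`,
#' `sdlog = 1.5`), and dispersions follow a log-log trend
#' `log(phi) = 0.5 * log(mu) + N(0, 0.5)` — together these produce the
#' mean-variance fan and dropout-versus-mean curve typical of droplet data.
#' Capture efficiencies are Gamma-distributed with mean `beta_bar` and
#' coefficient of variation `beta_cv`.
#'
#' Two-group designs: `group_fraction` splits cells into groups "A"/"B";
#' `de_fraction` of genes get their group-B mean multiplied by
#' `2^de_lfc` (differential expression), and `beta_bar_b` gives group B a
#' different mean capture efficiency (capture-bias designs) — group A always
#' uses `beta_bar`.
#'
#' @param n_genes,n_cells dimensions.
#' @param mu,phi optional per-gene prior parameter vectors; drawn as above
#'   when `NULL`.
#' @param beta_bar mean capture efficiency (default 0.1, a typical
#'   UMI-protocol efficiency).
#' @param beta_cv coefficient of variation of capture efficiencies across
#'   cells (default 0.2).
#' @param group_fraction fraction of cells in group "A" (`NULL` for a single
#'   unlabelled population).
#' @param de_fraction fraction of genes differentially expressed between the
#'   groups.
#' @param de_lfc log2 fold change applied to DE genes in group "B".
#' @param beta_bar_b optional distinct mean capture efficiency for group "B".
#' @param seed integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 2000, n_cells = 1000, mu = NULL, phi = NULL,
                     beta_bar = 0.1, beta_cv = 0.2,
                     group_fraction = NULL, de_fraction = 0, de_lfc = 1,
                     beta_bar_b = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_cells >= 1,
            beta_bar > 0, beta_bar < 1, beta_cv >= 0,
            de_fraction >= 0, de_fraction <= 1)
  if (!is.null(mu) && (length(mu) != n_genes || any(mu <= 0))) {
    abort("`mu` must be positive and of length `n_genes`")
  }
  if (!is.null(phi) && (length(phi) != n_genes || any(phi <= 0))) {
    abort("`phi` must be positive and of length `n_genes`")
  }
  if (!is.null(group_fraction) &&
      (group_fraction <= 0 || group_fraction >= 1)) {
    abort("`group_fraction` must be strictly inside (0, 1)")
  }
  structure(list(n_genes = n_genes, n_cells = n_cells, mu = mu, phi = phi,
                 beta_bar = beta_bar, beta_cv = beta_cv,
                 group_fraction = group_fraction,
                 de_fraction = de_fraction, de_lfc = de_lfc,
                 beta_bar_b = beta_bar_b, seed = as.integer(seed)),
            class = "sim_spec")
}

# materialize per-gene parameters, groups and DE flags (deterministic given
# the RNG state)
resolve_spec <- function(spec) {
  mu <- spec$mu %||% rlnorm(spec$n_genes, meanlog = 1, sdlog = 1.5)
  phi <- spec$phi %||%
    exp(0.5 * log(mu) + rnorm(spec$n_genes, sd = 0.5))
  groups <- NULL
  de <- rep(FALSE, spec$n_genes)
  if (!is.null(spec$group_fraction)) {
    n_a <- round(spec$group_fraction * spec$n_cells)
    if (n_a < 1L || n_a > spec$n_cells - 1L) {
      abort("group split leaves an empty group")
    }
    groups <- rep(c("A", "B"), c(n_a, spec$n_cells - n_a))
    if (spec$de_fraction > 0) {
      n_de <- round(spec$de_fraction * spec$n_genes)
      de[sample.int(spec$n_genes, n_de)] <- TRUE
    }
  }
  list(mu = mu, phi = phi, groups = groups, de = de)
}

#' Simulate ground-truth (pre-capture) counts
#'
#' @param spec a [sim_spec()]. Call inside an established RNG state or use
#'   [simulate_dataset()] for seeded end-to-end generation.
#' @param pars resolved parameters (internal use); by default drawn from
#'   `spec`.
#' @return a [count_matrix()] of original counts `x0`, with group labels
#'   attached for two-group designs.
#' @export
simulate_true_counts <- function(spec, pars = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  pars <- pars %||% resolve_spec(spec)
  mu_mat <- matrix(pars$mu, spec$n_genes, spec$n_cells)
  if (!is.null(pars$groups) && any(pars$de)) {
    b_cells <- pars$groups == "B"
    mu_mat[pars$de, b_cells] <- mu_mat[pars$de, b_cells] * 2^spec$de_lfc
  }
  x0 <- matrix(rnbinom(spec$n_genes * spec$n_cells,
                       size = rep(pars$phi, spec$n_cells),
                       mu = as.vector(mu_mat)),
               spec$n_genes, spec$n_cells)
  count_matrix(x0,
               gene_ids = paste0("gene_", seq_len(spec$n_genes)),
               cell_ids = paste0("cell_", seq_len(spec$n_cells)),
               groups = pars$groups)
}

#' Simulate per-cell capture efficiencies
#'
#' Draws Gamma-distributed capture efficiencies with mean `beta_bar` (or the
#' group-specific means for capture-bias designs) and coefficient of
#' variation `beta_cv`, clips them into `(1e-4, 0.95)` and re-centers the
#' mean onto the target after clipping. `beta_cv = 0` gives every cell
#' exactly the mean efficiency.
#'
#' @inheritParams simulate_true_counts
#' @param groups per-cell group labels (for `beta_bar_b` designs).
#' @return a `capture_efficiencies` tibble of true per-cell probabilities.
#' @export
simulate_beta <- function(spec, groups = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  target <- rep(spec$beta_bar, spec$n_cells)
  if (!is.null(spec$beta_bar_b)) {
    if (is.null(groups)) abort("`beta_bar_b` needs group labels")
    target[groups == "B"] <- spec$beta_bar_b
  }
  if (spec$beta_cv == 0) {
    beta <- target
  } else {
    shape <- 1 / spec$beta_cv^2
    beta <- rgamma(spec$n_cells, shape = shape, scale = target / shape)
    beta <- pmin(pmax(beta, 1e-4), 0.95)
    # clipping biases the mean; rescale back onto the target profile
    for (tv in unique(target)) {
      sel <- target == tv
      beta[sel] <- beta[sel] * tv / mean(beta[sel])
    }
    beta <- pmin(pmax(beta, 1e-4), 0.95)
  }
  out <- tibble::tibble(cell_id = paste0("cell_", seq_len(spec$n_cells)),
                        s = beta, beta = beta)
  structure(out, beta_bar = mean(beta), source = "simulated",
            class = c("capture_efficiencies", class(out)))
}

#' Binomially thin true counts
#'
#' Models capture: each original transcript of cell j is observed
#' independently with probability `beta[j]`, so
#' `x[i, j] ~ Binom(x0[i, j], beta[j])` and `x <= x0` elementwise.
#'
#' @param x0 true counts ([count_matrix()]).
#' @param ce capture efficiencies (tibble or bare vector).
#' @return observed [count_matrix()] with the same IDs and groups.
#' @export
thin_binomial <- function(x0, ce) {
  x <- as_base_matrix(x0)
  beta <- as_beta(ce, ncol(x))
  obs <- matrix(rbinom(length(x), size = as.vector(x),
                       prob = rep(beta, each = nrow(x))),
                nrow(x), ncol(x))
  count_matrix(obs, gene_ids = rownames(x0), cell_ids = colnames(x0),
               groups = cell_groups(x0))
}

#' Simulate a complete dataset with ground truth
#'
#' Seeds the RNG from `spec$seed`, then draws gene parameters, true counts,
#' capture efficiencies and observed (thinned) counts. Returns everything a
#' recovery experiment needs: the truth, the observation, the true capture
#' efficiencies, the true priors (as a `gene_priors` tibble) and the DE gene
#' flags for two-group designs.
#'
#' @inheritParams simulate_true_counts
#' @return list with elements `truth`, `observed`, `beta`, `priors_true`
#'   (tibble `gene_id`, `mu`, `phi`, `flagged`), `de_genes` (logical),
#'   `spec`.
#' @examples
#' sim <- simulate_dataset(sim_spec(n_genes = 100, n_cells = 50, seed = 7))
#' mean(sim$observed == 0) > mean(sim$truth == 0)  # thinning adds dropouts
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  pars <- resolve_spec(spec)
  truth <- simulate_true_counts(spec, pars)
  beta <- simulate_beta(spec, groups = pars$groups)
  observed <- thin_binomial(truth, beta)
  priors_true <- structure(
    tibble::tibble(gene_id = rownames(truth), mu = pars$mu, phi = pars$phi,
                   phi_raw = pars$phi, flagged = FALSE),
    scope = "global",
    class = c("gene_priors", class(tibble::tibble()))
  )
  list(truth = truth, observed = observed, beta = beta,
       priors_true = priors_true, de_genes = pars$de, spec = spec)
}

#' Expected dropout probability of an NB-distributed count
#'
#' For an observed count `x ~ NB(mean, size = phi)` the zero-class
#' probability is `(phi / (phi + mean))^phi`. As `phi` grows this tends to
#' the Poisson limit `exp(-mean)`.
#'
#' @param mean_obs observed mean expression (>= 0).
#' @param phi NB size (> 0).
#' @return probability of a zero count.
#' @export
expected_dropout_nb <- function(mean_obs, phi) {
  if (any(mean_obs < 0)) abort("`mean_obs` must be >= 0")
  if (any(phi <= 0)) abort("`phi` must be > 0")
  (phi / (phi + mean_obs))^phi
}

#' Parameter-free exponential dropout approximation
#'
#' The binomial capture model predicts the dropout fraction of a gene to be
#' approximately the exponential of its negative mean observed expression:
#' `exp(-mean_obs)`, the large-`phi` (Poisson) limit of
#' [expected_dropout_nb()]. A useful zero-parameter reference curve for
#' dropout-versus-mean diagnostics.
#'
#' @inheritParams expected_dropout_nb
#' @return probability.
#' @export
dropout_approx_exp <- function(mean_obs) {
  if (any(mean_obs < 0)) abort("`mean_obs` must be >= 0")
  exp(-mean_obs)
}
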