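#' Recover original transcript counts (normalize a count matrix)
#'
#' The package's main entry point. For every (gene, cell) entry the posterior
#' of the original count given the observed count, the cell's capture
#' efficiency and the gene's NB prior is evaluated, and either a point
#' estimate or posterior draws are returned:
#'
#' * `mode = "mean"` — posterior mean, real-valued (left unrounded; rounding
#'   is the caller's choice);
#' * `mode = "map"` — posterior mode, integer-valued;
#' * `mode = "samples"` — `n_samples` posterior draws per entry (a
#'   genes x cells x samples array) that propagate recovery uncertainty into
#'   downstream analyses such as differential expression ([de_call_3d()]).
#'
#' Capture efficiencies and priors are estimated from the data when not
#' supplied. With `prior_scope = "local"` each cell is recovered under its
#' own group's priors (groups from `cell_groups(cm)` unless given); capture
#' efficiencies are always calibrated on the full dataset. Flagged all-zero
#' genes pass through as zeros. Every output is >= the observed count: the
#' model only ever adds back lost transcripts.
#'
#' When `seed` is given, sample slice `s` is drawn under a deterministic
#' per-slice substream, so `n_samples = 3` reproduces the first three slices
#' of a later `n_samples = 20` run with the same seed.
#'
#' @param cm a [count_matrix()] (or numeric genes x cells matrix).
#' @param ce capture efficiencies ([estimate_capture()] output or a bare
#'   per-cell vector); estimated from column totals when `NULL`.
#' @param priors gene priors ([estimate_priors()] output); estimated when
#'   `NULL`.
#' @param beta_bar mean capture efficiency used when `ce` is estimated here.
#' @param mode `"mean"`, `"map"` or `"samples"`.
#' @param n_samples posterior draws per entry when `mode = "samples"`.
#' @param prior_scope `"global"` or `"local"`; used when `priors` is
#'   estimated here, and checked against supplied priors otherwise.
#' @param groups per-cell group labels; defaults to `cell_groups(cm)`.
#' @param seed optional integer seed for sample mode.
#' @return a `recovered_counts` object: a list with elements `values`
#'   (matrix, or 3D array for samples), `mode`, `gene_ids`, `cell_ids`,
#'   `n_samples`, `beta_bar`, `prior_scope`.
#' @examples
#' sim <- simulate_dataset(sim_spec(n_genes = 60, n_cells = 150, seed = 4))
#' rec <- recover_counts(sim$observed, beta_bar = 0.1, mode = "mean")
#' glance(rec)
#' @export
recover_counts <- function(cm, ce = NULL, priors = NULL, beta_bar = 0.06,
                           mode = c("mean", "map", "samples"),
                           n_samples = 5, prior_scope = c("global", "local"),
                           groups = NULL, seed = NULL) {
  mode <- match.arg(mode)
  prior_scope <- match.arg(prior_scope)
  x <- as_base_matrix(cm)
  validate_count_values(x)
  groups <- groups %||% cell_groups(cm)
  if (is.null(ce)) ce <- estimate_capture(cm, beta_bar = beta_bar)
  beta <- as_beta(ce, ncol(x))
  beta_bar <- attr(ce, "beta_bar", exact = TRUE) %||% beta_bar
  if (is.null(priors)) {
    priors <- estimate_priors(cm, beta, scope = prior_scope, groups = groups)
  } else if (!is.null(attr(priors, "scope", exact = TRUE))) {
    prior_scope <- attr(priors, "scope", exact = TRUE)
  }

  gene_ids <- rownames(cm) %||% paste0("gene_", seq_len(nrow(x)))
  cell_ids <- colnames(cm) %||% paste0("cell_", seq_len(ncol(x)))

  if ("group" %in% names(priors)) {
    if (is.null(groups)) {
      abort("grouped priors supplied but the matrix has no group labels")
    }
    missing <- setdiff(unique(groups), unique(priors$group))
    if (length(missing)) {
      abort(paste0("no priors for group(s): ",
                   paste(missing, collapse = ", ")))
    }
    vals <- allocate_values(mode, nrow(x), ncol(x), n_samples)
    for (g in unique(groups)) {
      sel <- groups == g
      pg <- priors[priors$group == g, ]
      pg <- pg[match(gene_ids, pg$gene_id), ]
      slab <- recover_block(x[, sel, drop = FALSE], beta[sel], pg,
                            mode, n_samples, seed)
      if (mode == "samples") vals[, sel, ] <- slab else vals[, sel] <- slab
    }
  } else {
    p <- priors[match(gene_ids, priors$gene_id), ]
    vals <- recover_block(x, beta, p, mode, n_samples, seed)
  }

  dn <- list(gene_ids, cell_ids)
  if (mode == "samples") {
    dimnames(vals) <- c(dn, list(paste0("sample_", seq_len(n_samples))))
  } else {
    dimnames(vals) <- dn
  }
  structure(list(values = vals, mode = mode, gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 n_samples = if (mode == "samples") n_samples else 1L,
                 beta_bar = beta_bar, prior_scope = prior_scope),
            class = "recovered_counts")
}

allocate_values <- function(mode, p, q, s) {
  if (mode == "samples") array(0, dim = c(p, q, s)) else matrix(0, p, q)
}

# closed-form recovery for one block of cells sharing a prior table
recover_block <- function(x, beta, priors, mode, n_samples, seed) {
  mu <- priors$mu
  phi <- priors$phi
  flagged <- priors$flagged %||% (mu <= 0)
  # flagged genes carry no information; neutral parameters, output overwritten
  mu_s <- ifelse(flagged, 1, mu)
  p <- nrow(x)
  q <- ncol(x)
  denom <- outer(mu_s, beta) + phi              # mu_i beta_j + phi_i
  if (mode == "mean") {
    out <- (x * (mu_s + phi) + outer(mu_s * phi, 1 - beta)) / denom
    out[flagged, ] <- x[flagged, , drop = FALSE]
    return(out)
  }
  zeta_mean <- outer(mu_s, 1 - beta) * (x + phi) / denom
  zeta_size <- x + phi
  if (mode == "map") {
    out <- x + matrix(nb_mode(as.vector(zeta_mean), as.vector(zeta_size)),
                      p, q)
    out[flagged, ] <- x[flagged, , drop = FALSE]
    return(out)
  }
  out <- array(0, dim = c(p, q, n_samples))
  m_vec <- as.vector(zeta_mean)
  r_vec <- as.vector(zeta_size)
  live <- m_vec > 0
  for (s in seq_len(n_samples)) {
    if (!is.null(seed)) set.seed(seed + s)
    zeta <- numeric(p * q)
    if (any(live)) {
      zeta[live] <- rnbinom(sum(live), size = r_vec[live], mu = m_vec[live])
    }
    slab <- x + matrix(zeta, p, q)
    slab[flagged, ] <- x[flagged, , drop = FALSE]
    out[, , s] <- slab
  }
  out
}

#' Rescale non-UMI read counts to molecule scale
#'
#' Protocols without unique molecular identifiers report reads, not
#' molecules; dividing by a constant amplification factor (the average number
#' of times each original molecule was sequenced) and rounding half-up yields
#' counts compatible with the binomial capture model, which can then be fed
#' to [recover_counts()] unchanged.
#'
#' @param cm a [count_matrix()].
#' @param amplification constant factor >= 1.
#' @return a [count_matrix()] of rescaled integer counts.
#' @export
scale_non_umi <- function(cm, amplification) {
  if (!is.numeric(amplification) || amplification < 1) {
    abort("`amplification` must be >= 1")
  }
  x <- as_base_matrix(cm)
  out <- floor(x / amplification + 0.5)
  count_matrix(out, gene_ids = rownames(cm), cell_ids = colnames(cm),
               groups = cell_groups(cm))
}

#' @export
print.recovered_counts <- function(x, ...) {
  cat(sprintf("recovered_counts: %d genes x %d cells, mode = %s%s\n",
              length(x$gene_ids), length(x$cell_ids), x$mode,
              if (x$mode == "samples") {
                sprintf(" (%d posterior samples)", x$n_samples)
              } else ""))
  cat(sprintf("beta_bar = %g, %s priors\n", x$beta_bar, x$prior_scope))
  invisible(x)
}

#' Tidy recovered counts into a long tibble
#'
#' @param x a `recovered_counts` object.
#' @param ... unused.
#' @return tibble with columns `gene_id`, `cell_id`, (`sample`,) `value`.
#' @export
tidy.recovered_counts <- function(x, ...) {
  if (x$mode == "samples") {
    purrr::map_dfr(seq_len(x$n_samples), function(s) {
      tibble::tibble(
        gene_id = rep(x$gene_ids, times = length(x$cell_ids)),
        cell_id = rep(x$cell_ids, each = length(x$gene_ids)),
        sample = s,
        value = as.vector(x$values[, , s])
      )
    })
  } else {
    tibble::tibble(
      gene_id = rep(x$gene_ids, times = length(x$cell_ids)),
      cell_id = rep(x$cell_ids, each = length(x$gene_ids)),
      value = as.vector(x$values)
    )
  }
}

#' One-row summary of a recovery run
#'
#' @param x a `recovered_counts` object.
#' @param ... unused.
#' @return one-row tibble: dimensions, mode, `beta_bar`, prior scope, total
#'   recovered signal and remaining zero fraction.
#' @export
glance.recovered_counts <- function(x, ...) {
  v <- if (x$mode == "samples") x$values[, , 1L] else x$values
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_cells = length(x$cell_ids),
    mode = x$mode,
    n_samples = x$n_samples,
    beta_bar = x$beta_bar,
    prior_scope = x$prior_scope,
    total_recovered = sum(v),
    zero_fraction = mean(v == 0)
  )
}
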