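# Shared fixtures and independent oracles.

# Tiny deterministic count matrix with IDs and optional groups.
tiny_counts <- function(values = matrix(c(0, 2, 1, 3), 2, 2),
                        groups = NULL) {
  count_matrix(values,
               gene_ids = paste0("g", seq_len(nrow(values))),
               cell_ids = paste0("c", seq_len(ncol(values))),
               groups = groups)
}

# Brute-force posterior oracle: binomial likelihood x NB prior, normalized
# over a truncated support. Independent of the shifted-NB closed form.
oracle_posterior <- function(n, x, mu, phi, beta, n_max = NULL) {
  n_max <- n_max %||% (x + max(2000, ceiling(50 * mu / beta)))
  grid <- x:n_max
  logw <- dbinom(x, grid, beta, log = TRUE) +
    dnbinom(grid, size = phi, mu = mu, log = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  out <- numeric(length(n))
  hit <- n %in% grid
  out[hit] <- w[match(n[hit], grid)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 54-point (x, mu, phi, beta) grid used by the posterior checks.
posterior_grid <- function() {
  expand.grid(x = c(0, 1, 5), mu = c(1, 10), phi = c(0.5, 2, 50),
              beta = c(0.05, 0.3, 0.9))
}
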