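#' Per-cell scaling factors from column totals
#'
#' The global scaling factor of cell j is its total count, optionally computed
#' after discarding the most highly expressed genes (`method = "trimmed"`):
#' the top `trim_fraction` of genes ranked by overall mean expression is
#' removed — the same gene set for every cell — so a handful of very abundant
#' genes cannot dominate the factors.
#'
#' Cells with a zero total are an error, not silently dropped: cell filtering
#' is the caller's responsibility.
#'
#' @param cm a [count_matrix()] (or numeric genes x cells matrix).
#' @param method `"total"` (plain column sums) or `"trimmed"`.
#' @param trim_fraction fraction of top-mean genes to drop, in `[0, 0.5)`;
#'   `0` reduces to `"total"`.
#' @return numeric vector of strictly positive factors, named by cell ID.
#' @export
scaling_factors <- function(cm, method = c("total", "trimmed"),
                            trim_fraction = 0.05) {
  method <- match.arg(method)
  x <- as_base_matrix(cm)
  if (method == "trimmed") {
    if (trim_fraction < 0 || trim_fraction >= 0.5) {
      abort("`trim_fraction` must be in [0, 0.5)")
    }
    n_drop <- floor(trim_fraction * nrow(x))
    if (n_drop >= nrow(x)) abort("trimming removes all genes")
    if (n_drop > 0L) {
      keep <- rank(-rowMeans(x), ties.method = "first") > n_drop
      x <- x[keep, , drop = FALSE]
    }
  }
  s <- colSums(x)
  if (any(s == 0)) {
    bad <- colnames(cm)[s == 0] %||% which(s == 0)
    abort(paste0("cell(s) with zero total count: ",
                 paste(head(bad, 5L), collapse = ", "),
                 "; filter these cells before normalization"))
  }
  stats::setNames(s, colnames(cm))
}

#' Calibrate scaling factors into capture efficiencies
#'
#' Relative scaling factors say how deeply each cell was sampled but not what
#' fraction of its transcripts was observed. Supplying the experiment-wide
#' mean capture efficiency `beta_bar` turns them into per-cell capture
#' probabilities: `beta[j] = beta_bar * s[j] / mean(s)`, clipped into
#' `[eps, cap]` because beta is a binomial probability (values at or above 1
#' are meaningless under the capture model, and beta = 0 makes the posterior
#' improper for positive observed counts). Without clipping, `mean(beta)`
#' equals `beta_bar` exactly.
#'
#' @param s positive scaling factors, one per cell (see [scaling_factors()]).
#' @param beta_bar mean capture efficiency in (0, 1). The default 0.06
#'   reflects typical droplet-protocol sensitivity; override whenever a
#'   calibrated estimate (e.g. from smFISH) is available.
#' @param cap upper clip, in (`beta_bar`, 1).
#' @param eps lower clip.
#' @param source provenance label recorded on the result.
#' @return a `capture_efficiencies` tibble with columns `cell_id`, `s`,
#'   `beta`, and attributes `beta_bar` and `source`.
#' @examples
#' calibrate_beta(c(c1 = 100, c2 = 200, c3 = 300), beta_bar = 0.1)
#' @export
calibrate_beta <- function(s, beta_bar = 0.06, cap = 0.95, eps = 1e-4,
                           source = "user") {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0)) {
    abort("scaling factors must be finite and strictly positive")
  }
  if (beta_bar <= 0 || beta_bar >= 1) abort("`beta_bar` must be in (0, 1)")
  if (cap <= beta_bar || cap >= 1) abort("`cap` must be in (beta_bar, 1)")
  beta <- pmin(pmax(beta_bar * s / mean(s), eps), cap)
  out <- tibble::tibble(
    cell_id = names(s) %||% paste0("cell_", seq_along(s)),
    s = unname(s),
    beta = unname(beta)
  )
  structure(out, beta_bar = beta_bar, source = source,
            class = c("capture_efficiencies", class(out)))
}

#' Estimate calibrated capture efficiencies from a count matrix
#'
#' Convenience wrapper: computes scaling factors (`"total"`, `"trimmed"`, or
#' user-supplied via `s`) and calibrates them with [calibrate_beta()].
#'
#' @inheritParams scaling_factors
#' @inheritParams calibrate_beta
#' @param s optional user-supplied scaling factors (overrides `method`).
#' @return a `capture_efficiencies` tibble.
#' @export
estimate_capture <- function(cm, beta_bar = 0.06,
                             method = c("total", "trimmed"),
                             trim_fraction = 0.05, s = NULL,
                             cap = 0.95, eps = 1e-4) {
  if (is.null(s)) {
    method <- match.arg(method)
    s <- scaling_factors(cm, method = method, trim_fraction = trim_fraction)
    src <- if (method == "total") "total_count" else "trimmed"
  } else {
    if (length(s) != ncol(cm)) abort("`s` must supply one factor per cell")
    if (is.null(names(s))) names(s) <- colnames(cm)
    src <- "user"
  }
  calibrate_beta(s, beta_bar = beta_bar, cap = cap, eps = eps, source = src)
}

# accept a capture_efficiencies tibble or a bare beta vector
as_beta <- function(ce, n_cells = NULL) {
  beta <- if (is.data.frame(ce)) ce$beta else ce
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    abort("capture efficiencies must be finite numbers")
  }
  if (any(beta <= 0) || any(beta > 1)) {
    abort("capture efficiencies must lie in (0, 1]")
  }
  if (!is.null(n_cells) && length(beta) != n_cells) {
    abort("number of capture efficiencies does not match number of cells")
  }
  beta
}
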