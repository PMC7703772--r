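# Summary statistics for validating count recovery: per-gene mean/variance,
# CV, Gini coefficient and dropout rate; per-cell dropout; the
# median-of-adjusted-p differential-expression aggregation over posterior
# samples; and log2-ratio reports against ground truth.

#' Per-gene summary statistics
#'
#' For each gene across cells: mean, sample variance (denominator Q - 1),
#' coefficient of variation `sd / mean` (NA for zero-mean genes — flagged,
#' never reported as 0), Gini coefficient of expression dispersion
#' (mean-absolute-difference definition,
#' `sum_jk |v_j - v_k| / (2 Q^2 mean)`, no small-sample correction), and
#' dropout rate (fraction of zero cells).
#'
#' @param m genes x cells matrix of counts or recovered values; a 3D sample
#'   array is accepted and averaged over slices after computing statistics
#'   per slice.
#' @return tibble with columns `gene_id`, `mean`, `variance`, `cv`, `gini`,
#'   `dropout`.
#' @examples
#' gene_stats(rbind(g1 = c(0, 0, 0, 1), g2 = c(1, 1, 1, 1)))
#' @export
gene_stats <- function(m) {
  if (inherits(m, "recovered_counts")) m <- m$values
  if (length(dim(m)) == 3L) {
    per_slice <- lapply(seq_len(dim(m)[3L]), function(s) gene_stats(m[, , s]))
    out <- per_slice[[1L]]
    num <- c("mean", "variance", "cv", "gini", "dropout")
    out[num] <- Reduce(`+`, lapply(per_slice, function(d) d[num])) /
      length(per_slice)
    return(out)
  }
  m <- as_base_matrix(m)
  if (length(m) == 0L) abort("empty matrix")
  q <- ncol(m)
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  cv <- ifelse(mu > 0, sqrt(v) / mu, NA_real_)
  tibble::tibble(
    gene_id = rownames(m) %||% paste0("gene_", seq_len(nrow(m))),
    mean = unname(mu),
    variance = unname(v),
    cv = unname(cv),
    gini = unname(apply(m, 1L, gini_mad)),
    dropout = unname(rowMeans(m == 0))
  )
}

# Gini by mean absolute difference: sum_ij |v_i - v_j| / (2 Q^2 mean),
# computed from the sorted-values identity
gini_mad <- function(v) {
  q <- length(v)
  tot <- sum(v)
  if (tot == 0) return(NA_real_)
  vs <- sort(v)
  (2 * sum(seq_len(q) * vs) - (q + 1) * tot) / (q * tot)
}

#' Per-cell dropout fractions
#'
#' @param m genes x cells matrix.
#' @return tibble with columns `cell_id`, `dropout` (fraction of zero genes
#'   in that cell).
#' @export
cell_dropout <- function(m) {
  if (inherits(m, "recovered_counts")) m <- m$values
  m <- as_base_matrix(m)
  if (length(m) == 0L) abort("empty matrix")
  tibble::tibble(
    cell_id = colnames(m) %||% paste0("cell_", seq_len(ncol(m))),
    dropout = colMeans(m == 0)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), returned in input order and capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Differential expression over posterior sample arrays
#'
#' Propagates recovery uncertainty into DE calling: a two-sample test is
#' applied gene by gene to each posterior sample slice independently, the
#' resulting p-values are BH-adjusted across genes within each slice, and
#' each gene is summarized by the median of its adjusted p-values over
#' slices; a gene is called DE when that median falls below `alpha`. With a
#' single slice (or 2D point-estimate matrices, treated as one slice) this
#' reduces to test + BH + threshold.
#'
#' @param samples_a,samples_b genes x cells x samples arrays (or genes x
#'   cells matrices) for the two groups; gene dimension and slice count must
#'   match.
#' @param alpha call threshold on the median adjusted p-value.
#' @param test two-sample test returning a p-value, called as
#'   `test(values_a, values_b)`. Default: Wilcoxon rank-sum (normal
#'   approximation).
#' @return a `de_result` tibble with columns `gene_id`, `median_adj_p`,
#'   `called`; the per-slice adjusted p-value matrix is kept in attribute
#'   `adj_p` for audit.
#' @export
de_call_3d <- function(samples_a, samples_b, alpha = 0.05,
                       test = wilcox_p) {
  samples_a <- as_sample_array(samples_a)
  samples_b <- as_sample_array(samples_b)
  if (dim(samples_a)[1L] != dim(samples_b)[1L]) {
    abort("gene dimensions differ between the two groups")
  }
  if (dim(samples_a)[3L] != dim(samples_b)[3L]) {
    abort("posterior sample counts differ between the two groups")
  }
  if (dim(samples_a)[2L] < 2L || dim(samples_b)[2L] < 2L) {
    abort("each group needs at least 2 cells")
  }
  p_genes <- dim(samples_a)[1L]
  n_s <- dim(samples_a)[3L]
  adj <- matrix(NA_real_, p_genes, n_s)
  for (s in seq_len(n_s)) {
    a <- samples_a[, , s]
    b <- samples_b[, , s]
    p <- vapply(seq_len(p_genes),
                function(i) test(a[i, ], b[i, ]), numeric(1L))
    adj[, s] <- bh_adjust(p)
  }
  med <- apply(adj, 1L, median)
  gene_ids <- dimnames(samples_a)[[1L]] %||% paste0("gene_", seq_len(p_genes))
  out <- tibble::tibble(gene_id = gene_ids, median_adj_p = med,
                        called = med < alpha)
  structure(out, adj_p = adj, alpha = alpha,
            class = c("de_result", class(out)))
}

as_sample_array <- function(x) {
  if (inherits(x, "recovered_counts")) x <- x$values
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L), dimnames =
                                 c(dimnames(x), list(NULL)))
  if (length(dim(x)) != 3L) abort("expected a matrix or 3D sample array")
  x
}

# Wilcoxon rank-sum p-value; constant pooled values give p = 1
wilcox_p <- function(a, b) {
  if (length(unique(c(a, b))) < 2L) return(1)
  wilcox.test(a, b, exact = FALSE)$p.value
}

#' Log2 ratios of recovered versus ground-truth statistics
#'
#' Compares per-gene summary statistics of a recovered (or otherwise
#' normalized) matrix against matched ground truth: `log2(recovered / truth)`
#' per gene for the mean, CV and Gini coefficient. Genes where either side is
#' zero or undefined are flagged (`finite = FALSE`) rather than dropped.
#'
#' @param recovered,truth [gene_stats()] tibbles on matched gene sets.
#' @return long tibble with columns `gene_id`, `statistic`
#'   (`"mean"`/`"cv"`/`"gini"`), `log2_ratio`, `finite`.
#' @export
log_ratio_report <- function(recovered, truth) {
  if (!setequal(recovered$gene_id, truth$gene_id)) {
    abort("gene sets do not match")
  }
  truth <- truth[match(recovered$gene_id, truth$gene_id), ]
  purrr::map_dfr(c("mean", "cv", "gini"), function(st) {
    r <- recovered[[st]]
    t <- truth[[st]]
    lr <- log2(r / t)
    tibble::tibble(gene_id = recovered$gene_id, statistic = st,
                   log2_ratio = lr, finite = is.finite(lr))
  })
}

#' Area under the ROC curve for a DE score
#'
#' Rank-based (Mann-Whitney) AUC of a score against binary labels: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half. Used to score `1 - median_adj_p` (or any
#' DE evidence score) against ground-truth DE labels.
#'
#' @param score numeric evidence, higher = more likely positive.
#' @param label logical ground truth.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) abort("need both positive and negative labels")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
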