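# baycount

Bayesian recovery, imputation and normalization of single-cell RNA-seq
counts under a binomial model of mRNA capture.

## The problem

scRNA-seq observes only a small fraction of each cell's transcriptome:
for droplet UMI protocols typically 5–20% of the molecules present are
captured. The result is a count matrix that is scaled down *and* full of
dropouts — zeros for genes that were expressed but missed. Scaling
normalization (dividing each cell by a size factor) corrects depth but
cannot impute dropouts, and it distorts variability statistics (CV, Gini
coefficient) that single-cell biology cares about.

baycount is for analysts who want original-scale transcript counts with
dropouts imputed and uncertainty preserved, as input to distribution
analyses and differential expression.

## The model

For gene *i* in cell *j*, with original count x⁰ᵢⱼ and observed count xᵢⱼ:

    xᵢⱼ | x⁰ᵢⱼ ~ Binom(x⁰ᵢⱼ, βⱼ)          (capture with efficiency βⱼ)
    x⁰ᵢⱼ       ~ NB(mean = μᵢ, size = φᵢ)  (gene-specific prior)

Everything is closed form:

* marginal: xᵢⱼ ~ NB(μᵢβⱼ, φᵢ);
* posterior: x⁰ᵢⱼ = xᵢⱼ + ζᵢⱼ, a *shifted* negative binomial with lost
  count ζᵢⱼ ~ NB(mean = μᵢ(1−βⱼ)(xᵢⱼ+φᵢ)/(μᵢβⱼ+φᵢ), size = xᵢⱼ+φᵢ);
* posterior mean [xᵢⱼ(μᵢ+φᵢ) + μᵢφᵢ(1−βⱼ)]/(μᵢβⱼ+φᵢ) and variance
  (xᵢⱼ+φᵢ)μᵢ(1−βⱼ)(μᵢ+φᵢ)/(μᵢβⱼ+φᵢ)².

Capture efficiencies βⱼ are per-cell scaling factors calibrated by an
experiment-wide mean capture efficiency β̄; priors (μᵢ, φᵢ) are estimated
empirically across cells (method of moments with a thinning correction,
plus dispersion shrinkage toward a log–log mean–dispersion trend), either
globally or per cell group ("local" priors). Output is the posterior mean,
the MAP, or S posterior draws per entry (3D array) that carry recovery
uncertainty into downstream tests.

## Worked example

```r
library(baycount)

# simulate ground truth: NB counts thinned by beta ~ Gamma(mean 0.1)
spec <- sim_spec(n_genes = 400, n_cells = 300, beta_bar = 0.1, seed = 42)
sim <- simulate_dataset(spec)

ce     <- estimate_capture(sim$observed, beta_bar = 0.1)
priors <- estimate_priors(sim$observed, ce)
rec    <- recover_counts(sim$observed, ce, priors, mode = "mean")
rec
#> recovered_counts: 400 genes x 300 cells, mode = mean
#> beta_bar = 0.1, global priors

glance(rec)
#> # A tibble: 1 × 8
#>   n_genes n_cells mode  n_samples beta_bar prior_scope total_recovered
#>     <int>   <int> <chr>     <int>    <dbl> <chr>                 <dbl>
#> 1     400     300 mean          1      0.1 global              883023.

# recovered counts track the simulated truth better than plain scaling
scaled <- sweep(unclass(sim$observed), 2, ce$beta, "/")
truth  <- as.vector(unclass(sim$truth))
c(recovered = cor(log1p(as.vector(rec$values)), log1p(truth)),
  scaled    = cor(log1p(as.vector(scaled)),     log1p(truth)))
#> recovered    scaled
#> 0.8785844 0.7446561
```

The total recovered signal (~883k molecules from ~88k observed reads at
β̄ = 0.1) is the imputed original-scale transcriptome; the correlation gain
over scaling comes from imputing dropouts instead of leaving them at zero.
Single entries follow the closed forms exactly — e.g. an observed count of
1 with μ = 10, φ = 2, β = 0.1 has posterior mean `posterior_mean(1, 10, 2,
0.1)` = 10 and variance 36, and a dropout (x = 0) is imputed to 6.

Results are tidyverse-friendly: `tidy(rec)` gives a long tibble
(gene_id, cell_id, value), `gene_stats()` / `cell_dropout()` /
`de_call_3d()` return tibbles, and `plot_mean_variance()`,
`plot_dropout_mean()`, `plot_log_ratios()` and `autoplot()` give ggplots.

For differential expression, recover with `mode = "samples"` and feed the
two groups' arrays to `de_call_3d()`: each posterior draw is tested per
gene, BH-adjusted within the draw, and genes are called on the median
adjusted p-value across draws — posterior uncertainty becomes
false-positive control.

See the vignette (`vignettes/count-recovery-methods.Rmd`) for the full
model, estimation details, simulator assumptions and limitations.

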