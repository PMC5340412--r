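# gutregimes

Decomposition of dense microbiome time series into autoregressive and
non-autoregressive dynamic regimes.

Daily 16S gut surveys show taxa that fluctuate hard yet keep returning to
taxon-specific carrying capacities. Part of that variance is
*autoregressive* — the community's recent past predicts its near future
(recovery from blooms, succession) — and the rest is *non-autoregressive*,
driven by external forces like diet and host physiology. `gutregimes` is
for microbial ecologists with OTU tables sampled over days who want to
split the variance along that line and interrogate each part with the
right statistics.

## The model

Relative abundances $x_i(t)$ are first-differenced into rates
$\Delta x_i(t) = x_i(t+1) - x_i(t)$, which are stationary (checked by ADF
and KPSS tests). Rates are fit with a sparse vector autoregression:

$$\Delta x_i(t) = q_i + \sum_{k=1}^{p} \sum_{j=1}^{n} R^{(k)}_{ij}\,
\Delta x_j(t-k) + e_i(t)$$

estimated per equation by elastic net with rolling-origin (time-ordered)
cross-validation and thresholding of small coefficients. Surviving
coefficients define Granger-causal edges (Wald chi-squared on an OLS refit
of the selected support). The residuals $e_i(t)$ — the non-autoregressive
regime — are screened for phylogenetic structure: OTU–OTU Spearman
correlations binned by pairwise phylogenetic distance, with a Mantel
permutation trend test. Side branches: Dirichlet-multinomial mixture
community states under temporal subsampling (`state_decay()`), and
conditionally rare taxa flagged by Sarle's bimodality coefficient
(`detect_crt()`).

A synthetic-data module generates count tables with known truth — sparse
VAR coupling, clade-structured innovations, carrying capacities, blooms,
missing days, multinomial sampling at fixed depth — so the whole pipeline
is testable without downloads.

## Worked example

```r
library(gutregimes)

sim   <- simulate_svar_counts(n_taxa = 50, n_days = 300, seed = 42)
rates <- first_difference(relative_abundance(sim$counts))

stationarity_table(list(synthetic = relative_abundance(sim$counts)))
#> # A tibble: 2 × 5
#>   dataset   series   adf kpss_trend kpss_level
#>   <chr>     <chr>  <dbl>      <dbl>      <dbl>
#> 1 synthetic raw       80         32         62
#> 2 synthetic delta    100        100        100

fit <- fit_svar(rates, p = 1, seed = 42)
glance(fit)
#> # A tibble: 1 × 8
#>       p n_taxa n_obs n_nonzero n_cross median_r_squared max_r_squared ...
#> 1     1     50   298         7       3                0         0.458

net <- granger_tests(fit, rates)
sum(net$significant)
#> [1] 3

bin_by_distance(correlation_matrix(fit$residuals), sim$truth$phylogeny)
#> <coherence_result> 1225 pairs, trend rho = -0.259 (pairwise p = 3e-20, Mantel p = 0.001)

coefficient_coherence(fit, sim$truth$phylogeny)
#> <coherence_result> 1225 pairs, trend rho = 0.023 (pairwise p = 0.41, Mantel p = 0.559)
```

Reading the numbers: raw abundance trajectories often fail the KPSS
stationarity tests (32–62% pass) while the differenced rates always pass —
differencing is what licenses the VAR. The autoregressive model explains
up to ~46% of variance for the most predictable taxa and little for most
(the two-regime signature: most variance is non-autoregressive). The
model residuals carry a strong negative correlation-versus-phylogenetic-
distance trend (related taxa co-fluctuate; Mantel p = 0.001), while the
fitted coefficient matrix carries none (p = 0.56): external drivers are
phylogenetically structured, internal couplings are not.

`autoplot()` methods draw correlograms, coherence-by-distance profiles,
state-decay curves, CRT maps, and per-taxon variance-explained bars;
`tidy()`/`glance()` give broom-style summaries of fits.
`run_full_pipeline(pipeline_config(...))` executes every stage from one
seeded config and writes a CSV bundle plus a JSON manifest.

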