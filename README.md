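# erlangfit

Tools for modelling the age distribution of cancer incidence — in
particular the early-peaking curves of childhood and young-adulthood
cancers — as a scaled probability density, and for reading the fitted
gamma/Erlang parameters as carcinogenesis quantities.

## The problem and the model

Crude incidence rates by 5-year age group (cases per 100,000 persons per
year, the layout of a CDC WONDER export) trace a curve over age `t`. The
package models that curve as

```
y(t) ≈ A · f(t | θ)
```

with `f` one of five classical two-parameter densities: gamma/Erlang,
Weibull (both supported on `t ≥ 0`), and the extreme value (Gumbel),
logistic and normal location–scale families. The gamma/Erlang density

```
f(t) = 1/(b Γ(k)) · (t/b)^(k−1) · exp(−t/b),   t ≥ 0
```

is the waiting-time law for the k-th event of a Poisson process, which
gives its parameters a mechanistic reading: `k` is the average number of
rate-limiting driver events needed for detectable cancer, `b` the average
time between them in years, `k·b` the expected waiting time, and `A/1000`
the maximal populational susceptibility in percent.

Fitting is an exhaustive grid search — 400 values per parameter, 160,000
nodes, steps of 0.05 for `k` and `b` — with the amplitude `A` optimised at
every node by golden-section search of R² over `[area/100, area·100]`
(`area` = the sum of the observed rates), and the global R² optimum
selected. Location families whose optimum places probability mass at
negative ages are flagged biologically non-interpretable. A synthetic-data
generator emulates CDC WONDER-shaped series from known ground truth
(optionally with Poisson count noise), so the whole pipeline is testable
without downloads.

## Worked example

Simulate a retinoblastoma-like series (k = 1.3, b = 1.45 years, A = 72),
fit the gamma/Erlang family on the full grid, and interpret the optimum:

```r
library(erlangfit)
cfg <- synthetic_config(first = 1.3, second = 1.45, amplitude = 72,
                        cancer_label = "retinoblastoma-like synthetic")
series <- generate_incidence(cfg)$series
fit <- fit_distribution(series, "erlang_gamma")
fit
#> Grid fit: retinoblastoma-like synthetic ~ erlang_gamma
#>   k = 1.3, b = 1.45, A = 72
#>   R^2 = 1.000000, mass below age 0 = 0
interpret_fit(fit)
#> Carcinogenesis parameters (gamma/Erlang reading):
#>   driver events (k):            1.3
#>   inter-event interval (b):     1.45 years
#>   maximal susceptibility (A/1000): 0.072 %
#>   expected waiting time (k*b):  1.885 years
100 * hereditary_fraction_from_k(fit$best_params[["k"]])
#> [1] 70
```

The fit recovers the generating parameters exactly (R² = 1 at the true
grid node). The fractional shape `k = 1.3` is read as a two-component
mixture — hereditary cases needing one somatic driver event, sporadic
cases two — and inverting the mixture puts the hereditary fraction at
70%.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

1. `Rscript analysis/01_simulate_panel.R` — generates the ten-cancer
   synthetic panel from the published gamma/Erlang parameter sets
   (CDC WONDER-dialect TSVs plus a ground-truth JSON).
2. `Rscript analysis/02_fit_families.R` — fits all five families to an
   exponential-shaped and a bell-shaped series, writes the ranked R²
   comparison with negative-age-mass flags, and exports an R² landscape
   for heatmap rendering.
3. `Rscript analysis/03_interpret_fits.R` — fits the gamma/Erlang family
   to every panel member, writes the parameter report, and prints the
   waiting-time range (1 to 35 years across the panel) and the
   retinoblastoma mixture arithmetic.

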