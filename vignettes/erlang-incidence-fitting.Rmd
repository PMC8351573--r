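---
title: "Modelling age-incidence curves with the gamma/Erlang distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age-incidence curves with the gamma/Erlang distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erlangfit)
```

## The model

Many childhood and young-adulthood cancers show an age-incidence curve that
rises to an early peak and then declines — for some types the curve is
monotonically decreasing from infancy, resembling an exponential density.
`erlangfit` treats such a curve as a scaled probability density: the
observed crude incidence rate at age $t$ (cases per 100,000 persons per
year, one observation per 5-year age bin) is modelled as

$$ y(t) \approx A \, f(t \mid \theta), $$

where $f$ is the density of one of five classical two-parameter families
and $A$ is a free amplitude. Under a Poisson-process view of
carcinogenesis, a cancer that requires $k$ rate-limiting driver events,
arriving independently at a constant average rate $1/b$ per year, becomes
detectable at an age distributed as the waiting time for the $k$-th event —
the gamma density, and for integer $k$ the Erlang density

$$ f(t) = \frac{1}{b\,\Gamma(k)} \left(\frac{t}{b}\right)^{k-1}
   e^{-t/b}, \qquad t \ge 0 . $$

This gives the fitted parameters direct readings: $k$ is the average number
of driver events, $b$ the average interval between them in years, $k b$ the
expected waiting time, and $A/1000$ the maximal populational
susceptibility in percent (the fraction of the population that can develop
the cancer at all). Four comparison families are fitted with the same
machinery: Weibull (the other non-negative-support family), and the extreme
value (Gumbel, max convention), logistic and normal location–scale
families, whose support covers negative ages.

Non-integer $k$ is permitted throughout: a fitted $k = 1.3$ is read as a
population mixture of patients needing different integer event counts, and
`expected_k_from_mixture()` / `hereditary_fraction_from_k()` implement the
two-component linear mixture arithmetic (the combined shape is the
prevalence-weighted mean of the component counts). For retinoblastoma this
connects the fitted shape to Knudson's two-hit model: the hereditary form
needs one somatic hit, the sporadic form two.

## The fitting procedure

Maximum-likelihood or gradient fits can stall in local optima, so the fit
is an exhaustive grid search. The default lattice (`default_grid()`) uses
400 values per parameter — $k$ and $b$ from 0.05 to 20.00 in steps of 0.05
(160,000 nodes); for the location families $\mu$ runs from $-20.0$ to
$19.9$ in steps of 0.1 so that optima below age zero are representable. At
every node the amplitude is optimised by golden-section search of $R^2$
over the bracket $[\mathrm{area}/100,\ \mathrm{area} \times 100]$, where
`area` is the plain sum of the observed rates (`area_estimate()`; no
bin-width weighting — the bracket is four orders of magnitude wide, so the
crude estimate is immaterial). The model curve is evaluated at the observed
bin midpoints only, never integrated over the 5-year bins, matching how the
rates are plotted and compared. The node with the highest $R^2$ is the
global optimum on the lattice; the full $R^2$ landscape is kept for
inspection.

Goodness of fit is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the observed mean, so a
constant prediction at the mean scores 0 and worse fits go negative. This
is the standard convention; nothing in the procedure pins the alternative
($SS_{tot}$ about zero), and the mean convention is the one adopted.

Age-group labels follow the half-open integer-age convention: `"15-19
years"` covers $[15, 20)$ and has midpoint 17.5, which uniquely fixes the
convention (`(N + M)/2` would give 17.0); `"< 1 year"` maps to 0.5.
Open-ended bins (`"85+ years"`) have no defensible midpoint and are
dropped.

## Numerical choices

* **Log-space densities.** All densities are evaluated as
  $\exp(\log f)$ with `lgamma()` for the gamma function; $k = 20$ with
  small $b$ would overflow $\Gamma(k)\, b^k$ evaluated directly.
* **Density at $t = 0$.** For $k < 1$ the gamma and Weibull densities are
  unbounded at 0. No finite sentinel is returned: the fitting layer never
  evaluates at $t = 0$ (the smallest bin midpoint is 0.5 years), and
  `dist_pdf()` raises a domain error there, so no silent infinity can
  enter an $R^2$ sum. Negative ages return density 0 for these families.
* **Amplitude objective conditioning.** Maximising $R^2$ over $A$ alone is
  minimising $\sum_i (y_i - A f_i)^2 = A^2 \sum f_i^2 - 2A \sum y_i f_i +
  \sum y_i^2$. The golden-section comparisons drop the $A$-free constant
  $\sum y_i^2$: at grid nodes whose density is vanishingly small at every
  observed bin, the constant otherwise swamps the $A$-dependent terms in
  double precision and the bracketing decisions degenerate to rounding
  noise. The ordering of the objective is unchanged.
* **Golden-section tolerance.** The search stops when the bracket width
  falls below `amp_tolerance` times the initial width; the default is
  1e-8. The amplitude error enters $R^2$ quadratically, scaled by the very
  wide bracket, so this default keeps the $R^2$ error of a perfect-fit
  node around 1e-13 — comfortably below the 1e-9 at which the test suite
  certifies noiseless round-trip recovery.
* **Tie-breaking.** Equal $R^2$ at several nodes resolves to the first in
  row-major grid order (lowest first parameter, then lowest scale). In
  `compare_families()` the ranking sort is stable, so families tied to the
  last bit keep their input order. This matters in one real case: at
  $k = 1$ both the gamma/Erlang and the Weibull densities reduce to the
  exponential $e^{-t/b}/b$ (evaluated identically in floating point), so
  on exponential-shaped data they tie exactly and the canonical order
  lists gamma/Erlang first.
* **Grid sizes in the test suite.** The full 400 × 400 lattice fits one
  family in a few seconds; simulation-heavy tests (100 Poisson replicates)
  use the coarser 100 × 100 `reduced_grid()` (steps 0.2, and 0.4 for
  $\mu$), whose nodes are a subset of the default lattice. These sizes are
  the package's choice of test-suite problem size.

## The synthetic-data generator

`synthetic_config()` + `generate_incidence()` emulate the shape of a CDC
WONDER crude-rate export: 5-year age bins from `"< 1 year"` to `"35-39
years"` (midpoints 0.5 to 37.5 years — the childhood/young-adulthood
range), with the expected rate $A f(t_i)$ at each midpoint. In noisy mode
each bin's case count is Poisson with mean $A f(t_i)/10^5 \times
\mathrm{population}$ — rates are count-derived, so Poisson counts are the
natural noise model — and the observed rate is the count scaled back per
100,000. Noiseless mode (the default) returns the expected rates exactly.
The generator's default parameters ($k = 1.75$, $b = 2.2$, $A = 124$) are
a published nephroblastoma-scale parameter set; `childhood_panel()`
provides all ten published childhood/young-adulthood parameter sets for
panel-level runs.

What the generator does *not* emulate: age-varying population structure
within a bin, reporting suppression, inter-year variability, or any
misspecification of the density family itself. Passing the recovery tests
therefore certifies the *fitting machinery* — that the global-optimum
search finds known ground truth under the model's own assumptions and
realistic Poisson sampling noise — not that real incidence data follow a
gamma/Erlang law.

## Design choices where the design was open

* The location-family grids: no published range exists for $\mu$, so
  $[-20, 19.9]$ was chosen to make negative-location optima (the
  disqualification behaviour) representable while keeping 400 values.
* Fits evaluate the density at observed (positive) midpoints only, and the
  mass a location-family optimum places below age zero is reported
  diagnostically (`mass_below_zero`, flag threshold 0.05 in
  `compare_families()`); densities are never renormalised over $t \ge 0$ —
  a family needing negative ages is disqualified, not repaired.
* The `"< 1 year"` bin is included with midpoint 0.5 (the natural choice
  for $[0, 1)$).
* The amplitude is fitted by golden-section search even though the
  least-squares amplitude has a closed form; the closed form serves as an
  independent oracle in the test suite, keeping the search machinery and
  its verification separate.

## Limitations

* The scale grid stops at $b = 20$, which caps how late the Weibull and
  location families can place a peak; for bell-shaped series peaking after
  ~30 years their best on-grid $R^2$ can be poor for range reasons, not
  only shape reasons. The gamma/Erlang family, whose peak sits at
  $(k-1)b$, is not so constrained. Grids are fully configurable via
  `grid_spec()` when this matters.
* Point estimates only: no confidence intervals or bootstrap uncertainty
  on $(k, b, A)$.
* Crude rates are used as-is; age-standardised rates and cancer-taxonomy
  handling are out of scope.
* The two-component mixture arithmetic is linear in $k$; no mixture
  *density* is ever fitted.
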