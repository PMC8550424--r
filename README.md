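# dalyvol

Trend statistics and penalized-spline volatility analysis for
burden-of-disease DALY tables.

Diarrheal-disease burden, measured as disability-adjusted life-years
(DALYs) per 100,000, fell very unevenly between World Bank income groups
from 1990 to 2017. `dalyvol` is for epidemiologists working with
long-format GBD-results-style tables who want two things from them:

1. **Descriptive trend statistics** — per-year sums of member countries'
   age-standardized rates by income group, percent changes, female-vs-male
   gap percentages, the fraction of countries where one sex's rate exceeds
   the other's, and average annual percent change of a national series.
2. **A volatility analysis** of the DALY rate *Y* against the
   socio-demographic index *x* (SDI, scaled 0–1), via the penalized
   B-spline regression

   *Y* = *f*(*x*) + *ε*,  *f*(*x*) = γ₀ + Σⱼ Bⱼ(*x*) γⱼ,

   with cubic B-splines on 3 interior knots at equally spaced quantiles,
   the ridge-type closed form γ̂λ = {B′B + R\*(λ)}⁻¹B′Y where
   R\*(λ) = λP penalizes the integrated squared first derivative,
   df(λ) = tr(Sλ) from the smoother matrix, BIC-guided selection of λ\*,
   and the **volatility functional** ∫{*f*′(*x*)}² d*x* = γ̂′Pγ̂ with
   percentile-bootstrap 95% confidence intervals (pairs resampling; knots
   and λ re-selected in every replicate).

A synthetic-data generator produces burden tables (31 low-income + 58
high-income countries, 1990–2017, planted sex gaps, bimodal age profile)
and (SDI, DALY) series with closed-form true volatility, so the whole
pipeline is testable against exact ground truth.

## Worked example

```r
library(dalyvol)

# a 28-point (SDI, DALY-rate) series shaped like the global relationship:
# a decline from ~2500 to ~500 per 100,000 across the SDI range
s <- gen_sdi_daly_series("logistic",
                         list(A = -2000, k = 6, x0 = 0.5, c0 = 2500),
                         n = 28, sigma = 90, seed = 15)

fv <- fit_volatility(s$x, s$y)
fv$lambda_star
#> [1] 0.06309573
fv$volatility_unit
#> [1] 3840222
fv$volatility_literal
#> [1] 242301.6
s$true_volatility
#> [1] 3947726

bootstrap_volatility(s$x, s$y, replicates = 1000, seed = 15)
#> Volatility (unit-penalty convention): 3.84022e+06
#>   95% percentile bootstrap CI [3.47004e+06, 4.79478e+06] (B = 1000, pairs, seed 15)
```

`volatility_unit` is γ̂′Pγ̂, the estimate of ∫{*f̂*′}² in squared rate
units per SDI unit — here within 3% of the generating curve's true value
3,947,726 — and `volatility_literal` is λ\*·γ̂′Pγ̂, the quadratic form in
the λ-scaled penalty as printed in the estimator's formula; both are always
reported. The CI is the 2.5th/97.5th percentile of 1,000 replicate
volatilities.

Descriptive statistics work on burden tables read with
`read_burden_table()`:

```r
format_percent(percent_change(6400.68, 8590.04))
#> [1] "34.21"
groups <- load_income_groups()      # 31 low- + 58 high-income countries
```

The pipeline stages `cmd_simulate()`, `cmd_aggregate()`, `cmd_trend()` and
`cmd_volatility()` bind everything into file-to-file steps (CSV/JSON in,
CSV/JSON out), each embedding the seed and a config hash so identical
configurations rerun byte-identically. A thin command-line wrapper is at
`scripts/dalyvol.R`:

```sh
Rscript scripts/dalyvol.R simulate --out-dir world --seed 7
Rscript scripts/dalyvol.R aggregate --input world/burden_table.csv --out-dir world
```

See `vignettes/daly-volatility.Rmd` for the model, the identifiability
and BIC choices, the bootstrap scheme, and known limitations.

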