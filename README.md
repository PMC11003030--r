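# staft — Bayesian spatial-temporal accelerated failure time models

`staft` fits Bayesian accelerated failure time (AFT) models to
right-censored, subject-level survival data whose subjects are nested in
areal units (counties) and temporal cohorts (diagnosis years) — the
structure of population-based cancer registries.  It is aimed at
biostatisticians analysing registry survival when proportional-hazards
assumptions fail and spatial/temporal heterogeneity matters.

## The model

For subject $k$ in county $i$ and cohort $j$, with follow-up time
$Y_{ijk}=\min(T_{ijk},C_{ijk})$ and event indicator
$\delta_{ijk}=I(T_{ijk}\le C_{ijk})$:

$$\log T_{ijk} = \mu + x_{ijk}^\top \beta + (\text{temporal fixed part})
+ (\text{frailty part}) + \sigma\,\varepsilon_{ijk},$$

with $\varepsilon$ standard extreme-value ($T$ Weibull), logistic
($T$ log-logistic) or normal ($T$ log-normal).  Three nested candidates:

| model | temporal fixed part | frailty part | prior on frailties |
|-------|--------------------|--------------|--------------------|
| M1 | — | $\omega_i$ | intrinsic CAR |
| M2 | $\xi z$, $z=j-1$ | $\gamma_i z + \omega_i$ | bivariate MCAR |
| M3 | $\xi_j$ ($\xi_1\equiv 0$) | $\gamma_{ij} + \omega_i$ | $(1{+}J)$-variate MCAR |

The intrinsic CAR prior ties each county's frailty to the mean of its
neighbours' (precision kernel $D_\omega - C$ from the county adjacency
graph); the MCAR prior couples the spatial and temporal components through
a $q\times q$ precision matrix $\Lambda$ with a conjugate Wishart
hyper-prior, $\Lambda\mid\Delta \sim \mathrm{Wishart}(p+I,\,(R^{-1}+V)^{-1})$.
Estimation is Gibbs-within-Metropolis–Hastings (componentwise random-walk
MH with burn-in step-size adaptation; exact Wishart draw for $\Lambda$;
sum-to-zero frailty centering), implemented in C++ via RcppArmadillo.
Model choice uses the conditional DIC; goodness of fit uses Cox–Snell
residuals.  A simulation harness generates registry-like data under four
spatial-temporal scenarios on the shipped (reconstructed) 67-county
Pennsylvania adjacency graph and reproduces bias / SD / MSE and
DIC-selection operating characteristics.

## Worked example

Simulate one registry-like dataset under scenario S1 (linear cohort trend,
20% censoring, true $\beta = (1, 0.5)$, true $\xi = 0.5$, $\sigma = 1$)
and fit the random-slope model M2:

```r
library(staft)

pa  <- pa_county_graph()
dat <- generate_scenario(
  scenario_spec("S1", graph = pa, target_censoring = 0.20), seed = 42)

fit <- fit_staft(dat, pa, model = "M2",
                 chain = chain_control(n_burnin = 1000, n_keep = 1000,
                                       seed = 1))
tidy(fit)
#> # A tibble: 5 × 4
#>   term   estimate conf.low conf.high
#>   <chr>     <dbl>    <dbl>     <dbl>
#> 1 mu        0.516    0.422     0.611
#> 2 beta.1    1.04     0.983     1.09
#> 3 beta.2    0.539    0.439     0.637
#> 4 xi.1      0.496    0.462     0.527
#> 5 sigma     1.00     0.965     1.04
```

Every generating value sits inside its 95% credible interval:
$e^{\hat\beta_1}\approx 2.8$ says one unit of $x_1$ nearly triples
survival time.  `glance(fit)` adds the fit-level summary (here
DIC $\approx 8009$ with $p_D \approx 63$ effective parameters, all MH
acceptance rates inside the 10–60% band), `autoplot(fit, "trace")` and
`autoplot(fit, "acf")` show chain health, and
`plot_cox_snell(cox_snell_residuals(fit))` checks calibration.  Compare
candidates with `select_model(list(M1 = fit1, M2 = fit2, M3 = fit3))`
(smallest DIC wins).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/staft.R simulate --scenario S1 --graph pa67 --seed 1 --out sim/
Rscript inst/cli/staft.R fit --data sim/dataset.csv --graph pa67 \
        --model M2 --seed 1 --out fit/
```

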