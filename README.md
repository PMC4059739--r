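# poolhaz

Top-down carcinogenesis modelling for populations with **dichotomous
susceptibility to cancer**: only a small pool (fraction *p*) of individuals
can ever develop a given cancer, and everyone in that pool eventually would.
Under this assumption the familiar old-age *turnover* of age-specific cancer
incidence — rates rise, peak around 75–80 years, then fall — needs no frailty
distribution or extra biological machinery: the population hazard falls
because the susceptible pool is being used up, while the hazard faced by a
susceptible individual keeps rising with age.

The package is for cancer epidemiologists and modellers working with
age-stratified incidence tables (SEER*Stat-style exports). It decomposes
carcinogenic modelling into two solvable problems:

1. **Inverse problem** — recover the *individual* (susceptible-only) hazard
   rate θ(τᵢ) from the observed *population* hazard rate λ(τᵢ), with no
   mechanistic assumptions;
2. **Direct problem** — model θ(t) with a chosen theoretical hazard
   function, here the three-parameter Weibull (multistage) hazard.

## Model

For a susceptible individual with hazard θ(t) and cumulative hazard
Θ(t) = ∫θ, the population survival is the cure-fraction mixture
S(t) = p·e^(−Θ(t)) + (1 − p), giving the population hazard

    h(t) = p·θ(t)·e^(−Θ(t)) / (p·e^(−Θ(t)) + 1 − p)  ≈  p·θ(t)·e^(−Θ(t))   (p ≪ 1)

The overall cumulative population hazard Q = ∫ h dt over the observed
lifespan equals p to first order, so Q estimates the pool size. On a
five-year age grid with midpoint quadrature, the inversion is

    Q = Δτ·Σᵢ λ̂(τᵢ),   H(τᵢ) = Δτ·Σ_{j<i} λ̂(τⱼ) + (Δτ/2)·λ̂(τᵢ),
    θ̂(τᵢ) = λ̂(τᵢ) / (Q − H(τᵢ))

The individual hazard is then fitted by weighted nonlinear least squares
with the Weibull hazard θ(t) = r·λ·(λ(t − A))^(r−1), where *r* is read as
the number of mutations needed to transform a normal cell into a malignant
one, *λ* (per year) as the first-year clone rate, and *A* (years) as a time
shift covering pre-carcinogenesis life and tumour latency.

The package ships reference pancreatic cancer hazard tables (SEER 9,
1975–2004) for six strata — men, women, whites, blacks, and Eastern/Western
registry groups — plus a synthetic cohort simulator for end-to-end
parameter-recovery experiments.

## Worked example

```r
library(poolhaz)

pc   <- pc_hazards("men")                      # reference tables, men
pool <- cumulative_hazard(pc$population)$pool
pool
#> <pool_estimate> stratum 'men': Q = 0.003071 (SE 4.35e-05), p_exact = 0.003067
```

About 0.31% of men are in the pancreatic-cancer-susceptible pool. Inverting
the population hazard gives the hazard a susceptible individual faces:

```r
ind <- invert_hazard(pc$population)
head(as.data.frame(ind), 3)
#>   age_midpoint theta_per_100k se_per_100k final_bin_flag stratum
#> 1         32.5       23.26047    2.365143          FALSE     men
#> 2         37.5       69.55159    4.244973          FALSE     men
#> 3         42.5      171.80917    7.063308          FALSE     men
```

At 37.5 years a susceptible man's hazard is ~70 per 100,000 person-years —
over 300 times the population rate of 0.21 — and it keeps rising with age
even where the population rate falls. Fitting the shared Weibull individual
hazard across all six strata:

```r
fit <- fit_weibull(lapply(pc_strata, function(s)
  invert_hazard(pc_hazards(s)$population)))
fit
#> <weibull_params> lambda = 0.01579 /y, r = 5.286 (~5 mutations), A = 17.22 y
#>   78 points, SSE_w = 474.6, AICc = 147.2, turnover at 78.1 y
```

So pancreatic carcinogenesis looks like a ~5-stage process, shifted by
~17 years, whose predicted population hazard turns over at ~78 years.
Pool sizes differ by stratum (men vs women below, z = 12.7) while the
individual hazard does not:

```r
women <- cumulative_hazard(pc_hazards("women")$population)$pool
compare_pools(pool, women)$p_value
#> [1] 4.02e-37
```

`audit_peak_shift(fit$params)` contrasts the correct mixture log-hazard,
whose peak age is independent of *p* (78.1 years at p = 10⁻⁴ and 10⁻²
alike), with a mis-bracketed variant whose peak wrongly slides younger as
*p* shrinks — the algebraic slip that once led to the rejection of the
dichotomous-susceptibility hypothesis.

A command-line wrapper over the same functions is installed at
`system.file("cli", "poolhaz.R", package = "poolhaz")` with subcommands
`ingest`, `invert`, `fit`, `predict`, `simulate`, `audit` and
`reproduce-tables`.

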