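---
title: "Dichotomous susceptibility, hazard inversion and the Weibull individual hazard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomous susceptibility, hazard inversion and the Weibull individual hazard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolhaz)
```

## The model and its assumptions

`poolhaz` treats a population as dichotomous with respect to a given
cancer: a fraction $p$ of individuals is susceptible and would eventually
develop the cancer if nothing else intervened; the remaining $1-p$ never
will. Susceptibles share a common hazard $\theta(t)$ with cumulative hazard
$\Theta(t)$. The population survival function is then the two-component
mixture
$$S(t) = p\,e^{-\Theta(t)} + (1-p),$$
familiar from cure-fraction survival models, and the population hazard is
$$h(t) = \frac{p\,\theta(t)\,e^{-\Theta(t)}}{p\,e^{-\Theta(t)} + 1 - p}
\;\approx\; p\,\theta(t)\,e^{-\Theta(t)} \quad (p \ll 1).$$

Two consequences drive everything in the package. First, $h(t) \to 0$ at
old ages even while $\theta(t)$ grows without bound: the observed turnover
of cancer incidence around 75–80 years is explained by depletion of the
susceptible pool, with no frailty distribution required. Second, the
overall cumulative population hazard $Q = \int h\,dt$ over the observed
lifespan equals $-\log(1-p^\ast)$ where $p^\ast$ is the lifetime cumulative
incidence; to first order in $Q$ this is the pool size $p$ itself. $Q$ is
therefore both estimable directly from incidence tables and interpretable
as a probability.

The assumptions worth keeping in mind: susceptibility is all-or-none (no
graded frailty); susceptibles are homogeneous; there is no competing
mortality, migration or secular drift in the rates; and the observation
window (ages 30–100) captures essentially all of the susceptibles' hazard
mass. The last one matters quantitatively — see the simulator section.

## From incidence tables to the population hazard

Input tables hold case counts $n_{ij}$ and person-years $N_{ij}$ per
five-year age interval $i$ (default 14 intervals covering 30–99 years,
half-open $[a, a+5)$, midpoints $\tau_i = 32.5, \dots, 97.5$) and calendar
period $j$. Crude rates are $I_{ij} = n_{ij}/N_{ij}$ with Poisson errors
$\mathrm{SE}(I_{ij}) = \sqrt{n_{ij}}/N_{ij}$. Since period and cohort
effects are negligible for the cancers this model targets, periods are
collapsed by the inverse-variance weighted mean; zero-count cells carry no
weight (their SE is zero, not small), and a fully zero row pools to zero
with a warning rather than an error, because sparse young-age rows are a
data-preparation reality. Internally all rates are events per person-year;
the conventional per-100,000 scaling exists only at I/O boundaries, which
keeps the inversion denominator honest.

## Discretized inversion

With rates on the grid, the integrals are discretized as
$$\hat Q = \Delta\tau \sum_{i=1}^{m} \hat\lambda(\tau_i), \qquad
  \hat H(\tau_i) = \Delta\tau \sum_{j<i} \hat\lambda(\tau_j)
  + \tfrac{\Delta\tau}{2}\,\hat\lambda(\tau_i),$$
i.e. rectangle rule for the total and a midpoint (half-interval) convention
for the running cumulative: at its own midpoint an interval has contributed
half its mass. The first-order inversion is
$$\hat\theta(\tau_i) = \frac{\hat\lambda(\tau_i)}{\hat Q - \hat H(\tau_i)},$$
and the exact mixture inversion
$\hat\theta = \hat\lambda e^{-\hat H} / (e^{-\hat H} - 1 + p)$ with
$p = 1 - e^{-\hat Q}$ is available as `method = "exact"`; the two agree to
relative order $Q$ ($\approx 0.3\%$ for pancreatic cancer).

This quadrature pairing is not arbitrary. It guarantees
$\hat Q - \hat H(\tau_i) > 0$ on the whole grid whenever the final rate is
positive, so the inversion is defined everywhere; and it reproduces the
reference pancreatic tables' individual-hazard columns to better than
$0.5\%$ at every age index in all six strata (`reproduce_tables()` checks
this wholesale). It also has a sharp corollary: at the final interval the
denominator collapses to $(\Delta\tau/2)\hat\lambda_m$, so
$\hat\theta(\tau_m) = 2/\Delta\tau$ — 40,000 per 100,000 person-years on a
five-year grid — *independent of the data*. That value is a discretization
artifact, not an estimate; it is flagged in every output and excluded from
model fitting by default.

## Error propagation: two conventions

The default standard errors (`se_method = "published"`) use the
per-interval convention
$$\frac{\mathrm{Var}\,\hat\theta_i}{\hat\theta_i^2} =
  \Big(\frac{\mathrm{SE}_i}{\hat\lambda_i}\Big)^2 +
  \Big(\frac{(\Delta\tau/2)^2\,\mathrm{SE}_i}{D_i}\Big)^2,
  \qquad D_i = \hat Q - \hat H(\tau_i),$$
in which each interval's error budget involves only that interval's rate
error: the first term is the numerator's relative error, the second the
denominator's sensitivity weighted by the half-interval window. This is the
convention under which the reference tables' printed SE columns — including
the final, artifact interval — are reproduced to within rounding
($\le 0.5\%$ everywhere), so it is the one used for weighting downstream
fits of those tables.

The alternative (`se_method = "delta"`) is the textbook full-gradient delta
method treating $\hat\theta_i$ as a function of all $m$ independent pooled
rates: contributions of intervals before $i$ cancel between $\hat Q$ and
$\hat H_i$, the own-interval derivative is
$(D_i - \tfrac{\Delta\tau}{2}\hat\lambda_i)/D_i^2$, and every later
interval contributes $-\Delta\tau\,\hat\lambda_i/D_i^2$. Because the
denominator $D_i$ shrinks with age while its dependence on downstream rates
does not, this convention gives visibly larger errors at late ages (up to
$\sim$60% larger around 75–85 years on the reference data). Both are exact
delta methods for *different* choices of what is held fixed; the package
exposes both and is explicit about which one reproduces the reference
tables. At the final interval the full-gradient form degenerates (the
first-order $\hat\theta_m$ is a constant), and a ratio-form value is
reported there instead.

## The Weibull individual hazard and its fit

Step two models $\theta(t)$ with the three-parameter Weibull hazard
$$\theta(t) = r\lambda\,(\lambda (t-A))^{\,r-1}, \qquad
  \Theta(t) = (\lambda (t-A))^{\,r}, \qquad t > A,$$
the multistage-carcinogenesis form: $r$ counts the mutations needed to
transform a normal cell ($2 \le r \le 7$ is the biologically plausible
window — more would be hard to accumulate in a lifetime), $\lambda$ (per
year) scales the first-year clone rate, and $A$ (years) absorbs both the
pre-carcinogenesis period of life and the latency until a tumour is
clinically detectable. Any reparameterization with the same $\Theta$ would
fit identically; this one keeps the parameters in their biological units.
$r$ is fitted as a continuous parameter and reported with its nearest
integer — the plausibility check applies to the continuous estimate, since
the biology motivates a range, not integer programming.

`fit_weibull()` minimizes the weighted SSE
$\sum_i w_i (\hat\theta_i - \theta(\tau_i))^2$, $w_i = \mathrm{SE}_i^{-2}$,
on the linear hazard scale (weighting already accounts for the
heteroscedasticity that would otherwise motivate a log scale). The surface
is multi-modal in $(\lambda, r, A)$ — a too-large $A$ with a smaller $r$
mimics a larger $A$-free power law over the observed window — so the
bounded Levenberg–Marquardt optimizer (`minpack.lm::nls.lm`) is restarted
from a deterministic lattice: $A \in \{0, 10, 20, 30\}$ (capped below the
youngest fitted age), $r \in \{2,\dots,8\}$, and $\lambda$ chosen so each
start passes through the observed point nearest 62.5 years. The best
converged start by SSE wins; there are no stochastic restarts, so fits are
bit-reproducible. Parameter covariance is $s^2 (J^\top J)^{-1}$ with the
weighted Jacobian evaluated analytically at the optimum and
$s^2 = \mathrm{SSE}_w/(m-k)$; goodness of fit is the small-sample AICc
$m\log(\mathrm{SSE}_w/m) + 2k + 2k(k+1)/(m-k-1)$, undefined (reported `NA`)
when $m \le k+1$.

Passing several strata's individual hazards to one `fit_weibull()` call
pools their points under a single parameter set — the working hypothesis
that stratification by sex, race or geography changes the pool size but not
the individual hazard. On the reference tables the pooled fit gives
$\lambda \approx 0.0158$/y, $r \approx 5.3$, $A \approx 17$ y, and a
first-order population-hazard turnover at $\approx 78$ y; single-stratum
fits scatter around the same curve ($A$ between 14 and 23 y, turnover
between 76.8 and 79.2 y) while their $\hat\theta$ columns span almost three
orders of magnitude. "Nearly the same" should be read on that scale: the
published SEs are tight enough (1–3% relative at mid-ages) that formal
pointwise 95% bands do *not* contain the neighbouring strata's curves
everywhere; what the data support is agreement within a factor of
$\sim 10^{0.25}$ across the whole age range, not statistical identity.

## Peak age and the bracket audit

For the first-order model $p\,\theta e^{-\Theta}$ the turnover age is
independent of $p$ and solves $(r-1)/(t-A) = \theta(t)$, i.e.
$t_{\mathrm{peak}} = A + ((r-1)/r)^{1/r}/\lambda$; `peak_age()` locates it
by grid search at 0.1-year resolution (an independent closed form and a
root-finder back this in the tests). That $p$-independence is the crux of
the historical dispute: a mis-bracketed version of the mixture log-hazard
predicts that rarer cancers peak at younger ages, contradicting
observation, and that prediction once led to the dichotomous-susceptibility
hypothesis being rejected. The literal historical algebra is not
recoverable, so `log_population_hazard(variant = "misbracketed")`
implements a stand-in with the same qualitative defect,
$\ln\theta - \Theta + \ln(p)\,(1 - e^{-\Theta})$, and
`audit_peak_shift()` asserts only the qualitative contrast: the correct
formula's peak moves by well under 2 years as $p$ spans $10^{-4}$–$10^{-2}$,
the mis-bracketed one's decreases strictly as $p$ shrinks (by ~21 years
over that span at the pancreatic fit's parameters).

## The synthetic cohort simulator

`sim_config()`/`simulate_counts()` generate SEER-like tables from the
model itself: expected cell rates are the exact mixture hazard at interval
midpoints (quadrature averaging available via `refine = TRUE`), counts are
independent Poisson draws with mean rate × person-years — the rare-event
limit of per-individual Bernoulli trials, and exactly the error model
($\sqrt n / N$) assumed on ingestion. Periods are exchangeable by default,
mirroring the negligible-period-effect setting the pooling step assumes; a
per-period multiplier hook exists for sensitivity work.

Defaults describe one fixed, pancreatic-like study condition: $r = 6$,
$A = 17$ y, $p = 0.003$, $10^7$ person-years per cell over 6 periods, and
$\lambda = ((r-1)/r)^{1/r}/60.5 \approx 0.01604$/y, which places the
turnover exactly at 77.5 y, the centre of the $[75, 80)$ interval. The
$\lambda$ choice is doing quiet but important work: with the turnover
there, $\Theta(100) \approx 5.6$, so only $\sim 0.4\%$ of susceptibles
survive past the grid and the 30–100 y cumulative hazard genuinely
identifies $p$. A flatter hazard with the same turnover but smaller $r$
leaves 1.5–2% of the pool beyond age 100 and biases $\hat Q$ low by the
same amount — a truncation effect of the observation window, not of the
estimator. `recovery_experiment()` runs the whole pipeline per replicate
(simulate → rates → pool → invert → fit) and reports bias and spread; the
noise-free mode replaces Poisson draws by expected counts to isolate
discretization plus first-order error, which recovers $p$ within 1% and
the generating $\theta$ within a few percent mid-grid. Under the default
conditions, 50 replicates recover $p$ to within Monte-Carlo error and
$A$ to within 3 years.

What the simulator deliberately does not emulate: birth-cohort and period
drift, competing mortality (real person-years shrink at old ages — the
reference tables' final-interval SEs are an order of magnitude larger than
the simulator's), registry coding error, and over-dispersion beyond
Poisson. Passing recovery tests therefore validates the estimator chain
under the model's own assumptions, not robustness to their violation.

## Numerical choices and degenerate inputs

* Tolerances on reference-table comparisons are relative; no absolute
  epsilons below $10^{-12}$ of the working unit are asserted anywhere.
* Zero-count cells: SE 0, excluded from pooling weights; all-zero rows
  pool to 0 with a warning. An all-zero population series inverts to all
  zeros with a warning (pool undefined); a zero final rate leaves only the
  final inverted value undefined (`NA`, warned) because its denominator is
  $0/0$.
* The final-interval inverted value $2/\Delta\tau$ and its SE are
  convention artifacts; both are flagged and excluded from fits by default.
* Fit degeneracies: fewer than 5 usable points is an error; $m \le k+1$
  makes AICc `NA`; a singular Jacobian yields `NA` parameter SEs, not a
  failure. All fit failures inside `recovery_experiment()` are counted and
  excluded from summaries rather than aborting the run.
* Seeds: `simulate_counts()` uses its config's seed through an isolated
  RNG scope (the caller's `.Random.seed` is untouched); replicate $i$ of a
  recovery experiment uses `seed + i - 1`.

Problem sizes used in the shipped tests: 14×6 tables, $10^7$ person-years
per cell, 50-replicate recovery experiments, and Monte-Carlo cohorts of
$4\times10^5$ individuals for the rate oracle — comfortable on a laptop and
large enough that Monte-Carlo error does not mask the effects under test.

## Known limitations

The pool estimate $\hat Q$ inherits the observation window: hazard mass
outside 30–100 y is invisible, so $\hat Q$ is a lower bound on $p$ for
slowly-developing cancers. The SE conventions treat pooled rates as
independent across age intervals (true for registry counts, not for
overlapping-cohort designs). The inversion amplifies late-age noise by
$1/(Q-H)$, which is why everything downstream weights by the propagated
SEs and drops the final interval. And the model's identification of $p$
rests on the dichotomy itself: a continuous frailty distribution with a
heavy resistant tail can mimic the same population hazard, so goodness of
fit here supports, but cannot prove, all-or-none susceptibility.
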