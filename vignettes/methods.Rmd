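---
title: "Methods: a spatial Poisson autoregressive model for drug-court effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spatial Poisson autoregressive model for drug-court effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Drug courts divert people arrested for drug possession into supervised
treatment instead of incarceration. Whether and where they reduce illicit
opioid overdose deaths is an ecological question: the unit is the county,
the outcome a yearly death count, and the exposure a binary indicator that
switches on when a court opens and (in practice) stays on. `drugcourtr`
models a county-year panel of such counts, quantifies how the court effect
is modified by county context, and converts the fitted model into
counterfactual statements ("how many deaths if no county had a court?").

# Model

With $Y_{it}$ deaths, population $P_{it}$, court indicator $D_{it}$,
covariates $x_{it}$ and interactions $z_{it} = D_{it} x_{it}$:

$$Y_{it} \sim \mathrm{Poisson}(P_{it} \lambda_{it}), \qquad
\log \lambda_{i1} = \alpha_i,$$
$$\log \lambda_{it} = \log \lambda_{i,t-1} + \beta_0 + x_{it}'\beta +
D_{it}\delta + z_{it}'\gamma + \phi_i, \quad t \ge 2.$$

The offset is the *latent* prior-year rate $\lambda_{i,t-1}$, not the
observed rate $Y_{i,t-1}/P_{i,t-1}$: small counties routinely observe zero
deaths, for which an observed-rate offset is undefined, and the recursion
keeps the model generative. Because the recursion telescopes,
$\log \lambda_{it}$ is *linear* in all parameters — the cumulative sum of
the transition increments added to $\alpha_i$ — which the sampler exploits
(below). Exponentiated coefficients are year-over-year death-rate ratios;
the combined court effect in, say, a high-targeting county is
$\exp(\delta + \gamma_{HT})$, obtained with `linear_combination()`.

The spatial effect $\phi_i$ enters the *transition* equation: it is each
county's persistent deviation in growth rate, smoothed by the intrinsic
CAR prior $-\frac{\tau}{2}\sum_{i\sim j}(\phi_i - \phi_j)^2$ over the
county adjacency graph. The ICAR kernel is improper (constant shifts
within a connected component are free, and trade off against $\beta_0$),
so a sum-to-zero constraint per component is imposed. The baseline
intercepts $\alpha_i$ are exchangeable Normal — the spatial structure is
attributed to the *change* in rates, and a spatial baseline would be a
separate extension.

## Priors and tunable parameters

| parameter | prior | default | why |
|---|---|---|---|
| $\alpha_i$ (log baseline rate, per person) | $N(a_0, s_0^2)$ | $a_0=-8.5$, $s_0=3$ | centers on ~2 deaths per 10,000 person-years; $\pm 3 s_0$ spans 1-per-million to 1-per-200 |
| $\beta_0, \beta, \delta, \gamma$ (log rate ratios / year) | $N(0, c^2)$ | $c = 10$ | weakly informative on a scale where $|{\cdot}| > 1$ is already a >2.7x yearly change |
| $\tau$ (ICAR precision) | $\mathrm{Gamma}(a_\tau, b_\tau)$ | $(1, 0.01)$ | standard diffuse disease-mapping default |

All are configurable through `model_spec()`. Tertile cutoffs for the
targeting index use type-1 (empirical-CDF) quantiles of the pooled
county-year values; the quantile type is an argument of
`fit_tertiles()`.

## Covariate engineering

*Targeting index*: drug-possession arrests (excluding marijuana) divided
by arrests for crimes against persons or property — a measure of how
focused local enforcement is on possession, normalized for overall police
activity. A zero denominator yields a missing value with a warning; such
county-years are excluded from tertile fitting and are a hard error if
they reach a design matrix (there is no principled imputation, so the
package fails loudly). Classification: strictly below the lower tertile
cutoff is "low", strictly above the upper is "high", boundary values fall
in the reference "middle" bin. Under this boundary rule the bins are
near-thirds rather than exact thirds (the cutoff order statistic itself
lands in "middle"); the property tests assert each bin within $2/n$ of
$1/3$ for distinct values.

*Poverty and healthcare indices*: first principal components of, resp.,
{poverty, unemployment, disability, food stamps, no HS diploma} and
{uninsured, medically-underserved flag, treatment-provider count}. The
variables mix percentages, a binary flag, and a count, so the PCA is run
on the correlation scale (standardize, then decompose). Signs of
eigenvectors are arbitrary; each index is anchored so the loading of its
flagship hardship variable (`poverty_pct`, `uninsured_pct`) is positive,
making "higher = worse" true by construction. Continuous design columns
(crime rate and both indices) are standardized pooled over all
transition-year county-years; fitted transformers serialize to a JSON
sidecar (`write_transformers()`) at full double precision so
counterfactual runs reuse bit-identical training-time transforms.

# Inference

No probabilistic-programming backend is assumed: the sampler is part of
the package. Because the log rate is linear in
$(\alpha, \beta_0, \beta, \delta, \gamma, u)$ — where $\phi = V u$ with
$V$ the orthonormal eigenbasis of the graph Laplacian excluding its null
space — the posterior is a log-concave Poisson GLM with Gaussian priors.
The sampler:

1. finds the MAP by damped Newton ascent (exact gradient and Hessian, a
   handful of $d \times d$ solves);
2. runs Hamiltonian Monte Carlo in the Laplace-whitened space
   $\theta = \hat\theta + R^{-1} x$ ($R$ the Hessian Cholesky), where the
   posterior is approximately standard normal, with dual-averaging step
   size (target acceptance 0.8) and jittered leapfrog path length;
3. gives $\tau$ a conjugate Gibbs update between HMC sweeps:
   $\tau \mid u \sim \mathrm{Gamma}(a_\tau + \mathrm{rank}/2,\,
   b_\tau + \tfrac12 u' \Lambda u)$.

Sampling in the eigenbasis makes the per-component sum-to-zero constraint
hold *exactly* in every draw (the basis is orthogonal to the component
indicators), rather than approximately via soft constraints or post-hoc
centering. The dense preconditioner is what makes this model mix: the
cumulative-sum design induces strong correlations between $\beta_0$,
$\delta$, $\gamma$ and the smooth spatial modes that defeat diagonal mass
matrices. With it, split-$\hat R$ is typically < 1.01 and bulk ESS is a
large fraction of the draws. Convergence is checked with rank-normalized
split-$\hat R$ and bulk ESS (`diagnostics()`); constant parameters are
flagged `NA`, not errors. Defaults: 4 chains, 1000 warmup + 1000 kept
draws. Identical seed + config + data reproduce draws bitwise.

## Summaries

Point estimates are posterior medians (configurable to means): medians
commute with monotone transforms, so the table is the same whether
computed on the coefficient or rate-ratio scale. Credible intervals are
95% equal-tailed and use **type-1 (order statistic) quantiles**, for the
same equivariance reason — interpolating quantile estimators do not
commute with `exp` and would break the documented identity at the 1e-12
level. `percent_positive` is the fraction of draws with coefficient
strictly > 0 (ties at exactly zero count as not positive); a term is
flagged "credible" when its 95% CI excludes a rate ratio of 1.

# Counterfactuals

Scenarios may override only the exposure and the targeting dummies
("remove high targeting" reassigns those county-years to the reference
tertile; the low-targeting dummy is untouched). Interaction columns are
always rebuilt as exact products after the override. Each posterior draw
is propagated from the county baseline $\alpha_i$ through the modified
transitions — scenario effects therefore *compound* multiplicatively over
years — and the posterior-predictive mean requires no count sampling
(the mean of a Poisson mixture is the mean of its rate).

Changes are signed so that positive = protective: counterfactual minus
observed for the no-courts scenario, observed minus counterfactual for
the two adoption scenarios. Count changes sum differences over transition
years; rate changes divide each yearly difference by that year's
population, average over years, and are reported per 10,000. Statewide,
counts sum and rates average **over all counties** (even counties a
scenario cannot touch — which is why a universal-adoption scenario can
show a modest statewide count change alongside a large average rate
change: small counties dominate the rate average, populous ones the count
sum). Point estimates are posterior means, so the statewide identities
(sum / average of county values) hold exactly; intervals carry the full
per-draw statewide quantities.

Two deliberate interpretation choices. First, the default comparison is
against the *observed* death counts, matching the definition of the
counterfactual contrast; `summarize_changes(reference =)` also accepts
predicted counts under the observed design, which is the right reference
for invariance checks (an identity scenario then changes exactly nothing,
and never-treated counties change exactly zero under no-courts). Second,
the window "2018–2023" spans six transition years even where it is
colloquially called a five-year span; all sums run over all six
transitions.

# Synthetic data

`truth_config()` states the world the generator emulates: 100 counties on
a 10x10 rook lattice, years 2017–2023, populations log-uniform in
$[10^4, 10^6]$, baseline rates $\alpha_i \sim N(\log 10^{-4}, 0.4^2)$
(about 1 death per 10,000 person-years, so county-year deaths land mostly
in 0–100), drift $\beta_0 = 0.10$ (rates rising ~10%/year), a protective
court effect $\delta = -0.17$ (rate ratio 0.84) erased under high
targeting ($\gamma_{HT} = 0.19$, ratio 1.21), ICAR precision $\tau = 4$,
and 30% of counties adopting courts at staggered start years, never
closing. Socioeconomic percentages share a latent county deprivation
factor (pairwise correlation ~0.8 in the poverty block) so the PCA
machinery faces realistic collinearity; arrest counts give the targeting
index a spread straddling realistic tertile cutoffs.

What the generator does *not* emulate: real county geography (a lattice is
not North Carolina), confounded court placement (assignment is random by
default; a `confounded = TRUE` option exists to demonstrate — not fix —
sensitivity), measurement error in covariates, population change over
time, and suppressed small counts. At $\tau = 4$ the smooth Laplacian
modes give the growth field enough variance that a small tail of
county-years compounds to implausibly large counts over six years
(~15% of county-years exceed 100 deaths); this is the stated truth for
the recovery experiments, not a claim about realism of the tails. A green
recovery test therefore establishes that *the estimator recovers the
parameters of its own generative model at the study's scale* — it cannot
establish unconfoundedness or robustness to misspecification.

Parameter recovery (`recovery_experiment()`) simulates, fits Model 2, and
records 95%-CI coverage and point-estimate error for $\delta$,
$\gamma_{HT}$ and $\beta_0$. The acceptance test runs 10 replicates at the
full 100-county scale (scaled down from 20 for the test-time budget; the
coverage band $[0.8, 1]$ is the exact binomial 95% band at 10 replicates
and nominal 0.95) and requires $|\mathrm{bias}(\delta)| < 0.05$ on the
log scale.

# Numerical choices and degenerate inputs

- Zero-variance index variables, zero-denominator targeting indices
  reaching a design, covariate gaps in transition years, negative or
  non-integer counts: hard errors naming the offender.
- Non-monotone court indicators (1 back to 0) and disconnected adjacency
  graphs: warnings in the validation report; the ICAR constraint is
  applied per connected component.
- Linear predictors above 690 (overflow of `exp`) reject the HMC proposal
  rather than propagating `Inf`; the generator refuses configurations
  whose simulated means exceed 1e7.
- Tie handling in tertiles: identical values collapse both cutoffs and
  classify everything "middle".
- All randomness is seeded; chain seeds derive from the user seed below
  $2^{31}$.

# Known limitations

Ecological inference: county-level associations need not transfer to
individuals. Causal language rests on exchangeability and stable-unit
assumptions the design cannot verify; court implementation heterogeneity
is invisible to a binary indicator. The Laplace-preconditioned HMC relies
on the posterior being log-concave and unimodal, which holds for this
GLM-structured model but would not survive, e.g., a negative-binomial
extension without adaptation. WAIC/LOO model comparison,
spatio-temporally varying $\phi_{it}$, and non-Poisson likelihoods are
out of scope.
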