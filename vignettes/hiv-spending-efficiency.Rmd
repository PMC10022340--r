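---
title: "Bias-corrected DEA for national HIV spending: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected DEA for national HIV spending: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiveff)
```

## The measurement problem

A country-year observation of a national HIV programme is treated as a
decision-making unit (DMU) that converts one input — annual HIV spending
divided by the number of people living with HIV, in constant USD — into two
coverage outputs: the percentage of PLHIV on antiretroviral therapy and the
percentage of HIV-positive pregnant women receiving antiretrovirals for
PMTCT. Both outputs are bounded in (0, 100] and are kept on the percentage
scale throughout; DEA is invariant to the units of any single input or
output column, so the 0–100 versus 0–1 choice is cosmetic (and is covered by
a test).

All country-years are pooled onto a single frontier. Pooling treats the
production possibilities as stable across the study window and makes scores
comparable across years; the alternative — one frontier per year — confounds
frontier shift with efficiency change and shrinks each reference set to a
few dozen units. Records lacking the input or either output are excluded
before scoring and counted in the run manifest; covariates, by contrast, are
imputed, never the input or outputs.

## Output-oriented VRS DEA

For DMU $i$ the envelopment program is

$$\max_{\delta,\lambda}\ \delta \quad \text{s.t.}\quad
\sum_j \lambda_j x_j \le x_i,\qquad
\sum_j \lambda_j y_{jm} \ge \delta\, y_{im},\qquad
\sum_j \lambda_j = 1,\qquad \lambda \ge 0 .$$

$\delta \ge 1$ is the feasible proportional expansion of all outputs at the
observed input; efficiency is $1/\delta$. Variable returns to scale (the
convexity constraint) is the appropriate assumption for national programmes,
whose scale cannot be chosen freely; the CRS variant is retained for the
envelopment-tightness check $\delta_{VRS} \le \delta_{CRS}$. Output
orientation reflects the policy question — more coverage for the same
budget — rather than budget reduction at fixed coverage.

The program is solved in envelopment (not multiplier) form because the
bootstrap needs the intensity weights $\lambda$ and cheap rescoring against
pseudo reference sets. The solver is a dense two-phase primal simplex
written for exactly this structure: the tableau has only $m+s+1$ rows
(here four), so each pivot is linear in the number of reference DMUs and a
full 600-unit panel scores in milliseconds. Numerical choices: pivot
tolerance $10^{-9}$; Dantzig pricing with a switch to Bland's rule after a
pivot budget, which guarantees termination under degeneracy (the output
rows start with zero right-hand sides, so degenerate pivots are routine);
the phase-1 artificial variable is explicitly pivoted out of the basis when
it ends phase 1 basic at zero, since leaving it in place can silently relax
the convexity row later; and every reported solution is verified against
the original constraints before it is returned — a violation surfaces as a
solver status, never as a wrong score. Scores from a self-containing
reference set are clamped at 1 (they can undershoot only by solver noise);
rescoring against an external pseudo frontier is *not* clamped, because
super-efficient draws below 1 are legitimate there. Ties among alternate
optimal peer sets are accepted as-is; tests assert distances, never
$\lambda$ uniqueness.

A brute-force reference implementation (`dea_grid_search`) enumerates
$\lambda$ over the whole unit-simplex grid; it is independent of the
simplex code and bounds the LP optimum from below, converging to it as the
grid resolution grows. Agreement within 0.01 at resolution 1/400 on small
instances is part of the acceptance suite.

## The two-stage double bootstrap

The empirical frontier lies weakly inside the true frontier, so raw
distances $\hat\delta$ are biased toward 1 and raw efficiencies flatter the
sample. The correction follows the standard two-loop structure for
covariate-conditional inefficiency:

1. Score all units; fit the truncated regression of $\hat\delta$ on the
   covariates $z$ (maximum likelihood, normal errors left-truncated so that
   $\delta \ge 1$), giving $(\tilde\beta, \tilde\sigma)$.
2. **Loop 1** ($L_1$ replications, study default 1,000): for every unit
   draw $\varepsilon^*_i \ge 1 - z_i\tilde\beta$ from the truncated normal,
   set $\delta^*_i = z_i\tilde\beta + \varepsilon^*_i$, shrink outputs to
   $y^*_i = y_i\,\hat\delta_i/\delta^*_i$, and rescore every original unit
   against the pseudo reference set. The bias estimate is
   $\widehat{bias}_i = \overline{\hat\delta^*_i} - \hat\delta_i$ and the
   corrected distance $\hat{\hat\delta}_i = \hat\delta_i - \widehat{bias}_i$,
   clamped at 1 (clamp events are counted and reported).
3. Per-unit CIs use the percentile interval of the bootstrap distance
   distribution recentred on the corrected score: the raw quantiles sit
   around $\hat\delta_i + \widehat{bias}_i$, so the interval is shifted by
   twice the bias estimate, which centres it on $\hat{\hat\delta}_i$ (for a
   symmetric bootstrap distribution this coincides with the reflected
   "basic" interval). Intervals are clamped at 1 and mirrored to the
   efficiency scale by reciprocation.
4. Refit the truncated regression on the corrected distances, giving
   $(\hat\beta, \hat\sigma)$.
5. **Loop 2** ($L_2$, study default 3,000): simulate
   $\delta^{**}_i = z_i\hat\beta + \varepsilon^{**}_i$ from the fitted
   truncated model and refit; the refits give percentile CIs and bootstrap
   SEs for each coefficient and for $\sigma$. Reported p-values use the
   bootstrap SE with a normal reference, alongside the percentile CIs.

Units with $\hat\delta = 1$ are excluded from the truncated fits by default
(`include_boundary` reverses this): the estimator conditions on strictly
inefficient units, and frontier units carry no information about the
truncated error. Simulated loop-2 responses are almost surely above 1, so
the flag is irrelevant there.

Reproducibility: one master seed draws a vector of per-replication
substream seeds up front; each replication seeds its own stream. Results
are bit-identical for a fixed master seed and do not depend on how the
replications might be scheduled.

## Truncated-normal regression

The second-stage log-likelihood for responses $\delta_i \ge c$ (here
$c = 1$) is
$$\ell(\beta,\sigma) = \sum_i \log\phi\!\left(\tfrac{\delta_i - z_i\beta}{\sigma}\right)
- \log\sigma - \log\Phi\!\left(\tfrac{z_i\beta - c}{\sigma}\right).$$
Optimisation is over $(\beta, \log\sigma)$ to keep $\sigma$ positive:
BFGS with the analytic score from an OLS start, followed by Newton polishing
on the score until its norm is at machine level (typically $10^{-12}$; the
convergence flag requires $10^{-5}$). The inverse Mills ratio is computed on
the log scale, so fits remain stable when $z_i\beta$ sits far below the
truncation point. The returned likelihood is never below the OLS
initialiser's. Truncated-normal draws use inverse-CDF sampling on the
truncated uniform interval, with a translated-exponential rejection
proposal when the normal mass above the bound is numerically exhausted
(standardised bound beyond ~6).

The covariate scale is taken as given — coefficients are reported on
whatever units the panel carries, and per-covariate transforms are the
caller's choice. This matters when comparing magnitudes across published
analyses, which often rescale or log large-unit covariates without saying
so.

## Missing-covariate imputation

The two-step procedure imputes covariates only. Step 1 works within each
country's yearly series: interior gaps take the within-country mean of that
covariate's observed values ("between years" is read as within-series, not
cross-country), and years outside the observed span carry the earliest
value back or the latest forward. Step 2 fits a multivariate normal to the
standardized pooled covariates by EM (ridge $10^{-6}$ on the covariance for
stability, missingness-pattern grouping for speed), draws $M = 50$
completed datasets from the conditional distribution of missing given
observed, and sets each still-missing cell to the mean of its draws —
a single averaged analysis panel, not $M$ separately analysed ones with
combination rules; the averaging matches how the scores are then consumed
by a single DEA run. Observed cells are never altered, every cell carries a
provenance tag, and a covariate observed nowhere (no information at all) is
flagged and filled at the pooled centre. Whether calendar year should enter
the MVN model is genuinely open; it does not, on the argument that step 1
already absorbs smooth temporal structure within countries.

## The synthetic generator

`generate_panel()` is the test bed: a known frontier, known inefficiency
process, known missingness. Frontier family $g_m(x) = a_m x^{b_m}$ with
$0 < b_m < 1$ — the simplest monotone concave family compatible with VRS —
with $a_m$ calibrated so frontier outputs peak just under 100 at the top of
the spending range. Inefficiency follows the second-stage model itself:
$\delta = \beta_0 + z\beta + \varepsilon$, $\varepsilon$ truncated so
$\delta \ge 1$, and outputs are $y_m = g_m(x)/\delta$. Covariates come from
a Gaussian copula whose random correlation matrix is rejected until every
pairwise $|\rho| < 0.7$; covariate cells are deleted completely at random.

Default scenario: 78 countries × 9 years with 83% of country-years
retained (≈580 observations), spending per PLHIV log-normal within
[45, 3502] USD, 14 covariates (10 in the base inefficiency model with
effects between ±0.05 and ±0.30 around an intercept of 1.5, plus 4
auxiliary covariates with zero true effect so that the sensitivity models
should move nothing), $\sigma = 0.3$, 15% covariate missingness. The
frontier exponents are set to $(0.12, 0.07)$ so that the pooled
input–output Pearson correlations land in the weak-positive band
(≈0.1–0.4) characteristic of cross-country HIV spending panels — with two
orders of magnitude of spending variation, steeper exponents would make
spending alone almost determine coverage, which such panels do not show.

What the generator does **not** emulate: within-country serial correlation
of inefficiency, measurement error in the outputs, informative (non-MCAR)
missingness, real regional or policy structure, and frontier shift over
time (available only as a linear inefficiency drift via `year_effect`).
Passing recovery tests therefore demonstrate internal consistency of the
estimator chain under the model's own assumptions, not robustness to the
ways real panels violate them.

## Orchestration and reporting choices

Percentiles everywhere use linear interpolation between order statistics
(R's default type 7); the descriptive table's quartiles depend on this, so
it is stated once here and recorded in the manifest. Outlier trimming drops
observations strictly below the 5th or strictly above the 95th pooled
percentile of the input and/or either output, refusing to act if fewer than
10 observations would remain. Group summaries report mean, median, IQR and
a normal-approximation 95% CI for the mean; bootstrap CIs across countries
would also be defensible, but the normal approximation is transparent and
adequate at the observed group sizes, and singleton groups get their CI
suppressed rather than fabricated. Model comparisons use Welch's unequal-
variance t-test on the shared DMUs. The covariate registry hard-codes the
base list and the two sensitivity extensions (staffing density; financing
shares), with arbitrary lists accepted via configuration.

Scaled problem sizes used by the test and acceptance suites — the recovery
design of 120 units with $L_1 = 200$, $L_2$ of 300–500, and sensitivity
runs at $L_1 = 200$, $L_2 = 100$ — are the package's chosen simulation
sizes: large enough that sign recovery, correction direction, and
correlation bands are stable across seeds, small enough to iterate on.

## Known limitations

* **Loop-2 CI coverage at small n.** The loop-2 bootstrap conditions on the
  bias-corrected scores: it reproduces the i.i.d. truncated-regression
  sampling variability but cannot see the cross-unit-correlated frontier
  estimation noise still present in those scores. At the 120-unit recovery
  design this leaves nominal 95% coefficient CIs covering truth at roughly
  85–90% — the coefficient point estimates are essentially unbiased and
  $\hat\sigma$ matches the generating value, so the shortfall is interval
  width, and it shrinks as the panel grows. Coverage claims at a few
  hundred units should be read with this in mind.
* The DEA model has no stochastic noise term: all deviation from the
  frontier is called inefficiency, and outliers act on everyone's reference
  set — hence the trimming sensitivity analysis.
* A single pooled frontier masks group heterogeneity (no metafrontier), and
  a country's benchmark is a convex combination of observed units, not an
  existing programme.
* The imputation averages over draws, so downstream standard errors do not
  carry imputation uncertainty.
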