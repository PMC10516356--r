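---
title: "Measuring linear trends in health inequalities and the likelihood of eradication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linear trends in health inequalities and the likelihood of eradication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Trends in health inequalities are conventionally summarized as absolute
differences or relative ratios between socioeconomic groups, and the two
perspectives regularly point in opposite directions for the same data. When
the policy goal is stated as an endpoint — for instance, bringing a harmful
behaviour below 5% prevalence in *every* socioeconomic group — neither
measure answers the question actually being asked: *if the current trend
continues, will the disadvantaged group reach the target at the same time as
the advantaged group?*

`ineqtrend` implements an integrated answer for declining binary outcomes
measured in repeated cross-sectional surveys (the motivating application is
weekly smoking among 15–16-year-olds across European school surveys). The
analysis works in *prevalence space*: each survey wave contributes one point
whose coordinates are the outcome prevalence at the top and at the bottom of
a within-country socioeconomic ranking, and the trend is the line through
those points.

## The model, step by step

### Socioeconomic score

Socioeconomic status is the educational level of the most highly educated
parent, an ordinal scale (five categories by default). Because the
distribution of parental education differs strongly between countries, the
ordinal category is converted to a **fractional rank** within each country:
respondents are ranked by category, everyone in a category receives the mean
of the ranks that category occupies, and the rank is divided by the number
of scored respondents in the country. The score lies in (0, 1]; 0 represents
the lowest possible and 1 the highest possible parental education in that
country, and the country mean is exactly \((n+1)/2n\). This is the same
ranking that underlies the slope and relative indices of inequality, so the
two ends of the scale have a familiar interpretation.

Two choices here were genuinely open and are configurable:

* **Pooling waves.** By default one ranking is computed per country over all
  waves (`mode = "pooled"`), so the score means the same thing in every
  wave; `mode = "per-wave"` ranks within each country–wave instead. Pooled
  is the default because education distributions move slowly relative to
  the outcome and a common scale keeps the per-wave coefficients
  comparable.
* **Gender.** Ranking is done on the full country sample, not within
  gender: the socioeconomic position of a household does not depend on the
  gender of the adolescent answering the questionnaire.

### Per-wave estimation

For each stratum (survey wave × gender, for all countries together and per
region), the binary outcome \(y_{ij}\) of respondent \(i\) in cluster \(j\)
is modelled as

\[
\operatorname{logit} P(y_{ij}=1) = \beta_0 + \beta_1 s_{ij} + u_j,
\qquad u_j \sim N(0, \sigma_u^2),
\]

where \(s_{ij}\) is the fractional-rank score and the cluster is the
smallest sampling unit known for the respondent (class, school, or country).
A single random-intercept level is used deliberately — a parsimonious
account of within-cluster correlation that never forces records to be
dropped for missing higher-level identifiers. The likelihood is maximized
by adaptive Gauss–Hermite quadrature (`lme4::glmer`, `nAGQ = nodes`,
default 15 nodes; 1 node is the Laplace approximation). The package also
ships an independent implementation of the same marginal log-likelihood
(`marginal_loglik()`, Golub–Welsch nodes, per-cluster Newton mode search)
used to verify the fitted optimum against brute-force numerical
integration.

The quantities carried forward are the fixed effects
\((\hat\beta_0, \hat\beta_1)\) and their 2×2 variance–covariance matrix.
\(\sigma_u\) is reported for diagnostics but its uncertainty is not
propagated: the prevalence extremes are functions of the fixed effects
only,

\[
P(0) = \operatorname{logit}^{-1}(\beta_0), \qquad
P(1) = \operatorname{logit}^{-1}(\beta_0 + \beta_1),
\]

the predicted prevalence for a (hypothetical) respondent at the very bottom
and very top of the socioeconomic scale, at the centre of the cluster
distribution (\(u = 0\)). \(P(0)\) is an extrapolation to the open end of
the (0, 1] scale, exactly as in the slope-index convention.

### Propagating uncertainty

Per stratum, 10,000 coefficient vectors are drawn from
\(N\big((\hat\beta_0,\hat\beta_1), \widehat{\mathrm{Cov}}\big)\) and mapped
through the inverse logit, giving a cloud of simulated \((P(1), P(0))\)
pairs. Percentile (2.5th, 97.5th) intervals for \(P(0)\) and \(P(1)\) are
free by-products.

The 95% **confidence region** drawn around each wave's point is constructed
as the \(\chi^2_2\) level-set ellipse of the bivariate normal fitted to the
draws *in coefficient space*, discretized (360 boundary points) and mapped
pointwise through the inverse logit. The mapped curve is no longer an exact
ellipse — near zero prevalence it bends into the characteristic banana
shape — which is the honest image of symmetric coefficient uncertainty on
the probability scale. Building the ellipse on the prevalence scale instead
would have been the other defensible convention; the coefficient-space
construction was fixed because the simulation itself lives on that scale.

### Trend line, intercept interval, eradication likelihood

The per-wave points \((P(1), P(0))\) are joined by unweighted ordinary least
squares of \(P(0)\) on \(P(1)\) — four points, one per wave, with no
wave-level precision weights. The intercept estimates the low-SES
prevalence at the moment high-SES prevalence reaches zero; a negative
intercept is meaningful and says the low-SES group would reach zero first.

For the uncertainty of that statement, simulated draw \(i\) of every wave is
combined into one simulated wave-set (waves are fitted independently, so any
fixed pairing of draws is distributionally equivalent, and index pairing
keeps runs reproducible), a line is fitted to each of the 10,000 wave-sets,
and:

* the **intercept CI** is the percentile interval of the 10,000 simulated
  intercepts (a percentile CI of a nonlinear functional need not contain
  the plug-in estimate; the package flags, but does not "correct", such
  cases);
* each simulated line's **first axis crossing** is found travelling in the
  direction of declining high-SES prevalence: the y-axis at
  \((0, \text{intercept})\) if the intercept is non-negative, otherwise the
  x-axis at \((-\text{intercept}/\text{slope}, 0)\) for positive slopes;
* the **likelihood of eradication** is the fraction of simulated lines
  whose crossing coordinate lies in \([0, t)\) with \(t = 0.05\) by
  default — the line enters the corner where both groups are below the
  target. The strict upper inequality matches the "below 5%" reading of
  the target; the boundary case of a line through the origin counts as
  eradicating at coordinate 0.

Simulated lines with negative intercept and non-positive slope never reach
either axis in the feasible direction; they are counted as non-eradicating
and their frequency is reported (`n_none`). Simulated wave-sets with
identical \(P(1)\) in every wave admit no line; they are excluded but kept
in the denominator, and more than 1% of them aborts the analysis, since at
that point the simulation is telling you the waves are indistinguishable.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_sim` | 10,000 | draws per stratum | Monte-Carlo error of a 95% percentile bound is ±0.4% of the prevalence scale at this size |
| `threshold` | 0.05 | prevalence | the "<5% in both groups" eradication target; change it for outcomes with other targets |
| `quad_nodes` | 15 | nodes | adaptive quadrature accuracy; 1 = Laplace; beyond ~15 nodes changes are below reporting precision |
| `level` | 0.95 | — | all intervals and regions |
| `rank_mode` | `"pooled"` | — | see above |
| `seed` | — | integer | master seed; per-stratum substreams are derived from it by a deterministic label hash, so strata can be recomputed independently |

## The synthetic generator

Real school-survey micro-data of this kind is access-restricted, so the
package ships a generator (`new_scenario()`, `generate_microdata()`) whose
defaults emulate the structure the method targets: 10 countries × 4
quadrennial waves, 40 fresh clusters per country-wave of 50 respondents
each (about 20,000 respondents per wave — the scale at which per-wave
prevalence extremes are precise enough for a 4-point trend to be
informative), five ordinal education categories with country-specific
Dirichlet(2)-drawn distributions, a logistic SES gradient that changes per
wave, and normal cluster intercepts (σᵤ = 0.5, an intra-class correlation
of about 0.07, typical for classroom clustering of behaviours).

Two properties make the generator a usable ground truth rather than a mere
fixture. First, the SES effect is applied to the *ranked* score — computed
by the same pooled per-country fractional-rank rule the pipeline uses — so
generator truth and pipeline truth coincide by construction, and
`true_prevalences()` gives the exact per-wave \((P(1), P(0))\) in closed
form. Second, `scenario_from_line()` inverts any prevalence-space line into
per-wave coefficients, so end-to-end tests can ask the pipeline to
rediscover a known geometry (for instance, intercept 0.094 and slope 0.72,
a realistic declining-inequality shape for adolescent smoking).

What the generator does **not** emulate: school sampling frames,
nonresponse and post-stratification weights, item missingness patterns
(missing education can be injected, but is not generated by default), or
non-logistic dose–response shapes. Passing tests therefore demonstrate the
estimator chain is correct under its own assumptions, not that those
assumptions hold in any particular survey.

## Numerical choices and degenerate inputs

* Average ranks are the only tie rule offered for the fractional rank; any
  other rule would break the \((n+1)/2n\) mean identity.
* `marginal_loglik()` finds each cluster's mode by damped-free Newton
  iteration (tolerance 1e-12, ≤100 iterations) and integrates with
  physicists' Gauss–Hermite nodes scaled by the mode curvature; it agrees
  with fine trapezoid-grid integration to ~1e-8 on small clusters.
* A fitted σᵤ of exactly zero (a "boundary" fit) is a legitimate converged
  estimate and is treated as such; genuine optimizer failures and
  complete-separation strata are flagged `converged = FALSE`, excluded
  from simulation, and surfaced in the run log — never silently accepted.
* Strata with a single cluster fall back to ordinary logistic regression
  with a logged notice.
* The draw covariance is symmetrized and eigenvalue-checked before
  simulation; a non-positive-semidefinite matrix is an error that prints
  the offending matrix.
* JSON and YAML archives store doubles at 17 significant digits, so a
  pipeline re-run from archived fits reproduces downstream numbers
  bit for bit.

## Validation scale

The test suite validates the chain at sizes chosen to make Monte-Carlo
conclusions meaningful: quadrature against grid integration on 3-cluster
toys; parameter recovery over 50 replicates of 100 clusters × 100
respondents; percentile-CI calibration over 200 replicates of 30 × 50;
end-to-end geometry recovery over 20 generator-scale runs (~80,000 rows
each). These sizes are the package's validation design.

## Known limitations

* The method assumes the prevalence–prevalence relationship is linear;
  four waves cannot support curvature, and accelerating declines will make
  the eradication likelihood conservative.
* The fractional-rank regression weighs the whole SES gradient; groups in
  the middle of the distribution can deviate from the extremes without
  affecting \(P(0)\) or \(P(1)\).
* Small strata (one country, few clusters) produce very large confidence
  regions; the method is designed for pooled multi-country analysis.
* The trend is direction-blind: a rising trend produces the same line as a
  falling one, so the eradication reading is only meaningful when
  prevalence is in fact declining at both ends of the scale.

## A worked example

```{r, eval = FALSE}
library(ineqtrend)

# a scenario whose true geometry is: intercept 9.4%, slope 0.72
sc <- scenario_from_line(0.72, 0.094, c(0.22, 0.19, 0.17, 0.10), seed = 1)
data <- generate_microdata(sc)

run <- run_pipeline(data, run_config(n_sim = 10000, seed = 1))
run$summary
autoplot(run, "All countries/boy")
```
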