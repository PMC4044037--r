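---
title: "A full life-cycle state-space model for Northeast Arctic cod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A full life-cycle state-space model for Northeast Arctic cod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`codcycle` implements an age-structured Bayesian state-space model for the
full life cycle of Northeast Arctic (NEA) cod — eggs, larvae, 0-group,
demersal juveniles (ages 1--3), and fished adults (ages 4--9) — together
with a synthetic-data generator, MCMC estimation, convergence diagnostics,
and the downstream analyses that quantify how compensatory density
dependence in the juvenile stage dampens environmentally driven variability
in recruitment.

## The process model

Abundances are tracked annually. Within a year $y$:

* **Spawning stock biomass.** $SSB_y = \sum_{a=1}^{9} N_{a,y}\, w_{a,y}\,
  p_{a,y}$, with weight-at-age $w$ (kg) and maturity probability $p$.
* **Egg production.** $E_y = 10^3 f \cdot SSB_y \, e^{\epsilon_{E,y}}$,
  where $f = 235$ eggs g$^{-1}$ is mean fecundity and
  $\epsilon_E \sim N(0, \sigma_E^2)$ captures stochasticity in the spawning
  process (condition, fertilisation, pre-survey egg survival). A $\sigma_E$
  of 0.7 corresponds to roughly 2-fold variation in egg abundance.
* **Eggs to larvae.** $L_y = E_y e^{-M_{egg} t_{EL}}$ with
  $M_{egg} = 0.169$ d$^{-1}$ over the $t_{EL}$ days between the egg and
  larval surveys.
* **Larvae to 0-group.** $O_y = L_y \exp\{-(M_{larv} - \gamma T_y) t_{larv}
  - M_{juv} t_{ejuv}\}$: 60 days of larval stage at 0.075 d$^{-1}$ followed
  by 60 days of early-juvenile stage at 0.04 d$^{-1}$. The temperature
  anomaly $T_y$ (June--August, Kola section style) offsets the larval-phase
  daily mortality linearly through $\gamma$; realized survival is capped at
  1. At $\gamma = 0$ baseline survival is $e^{-6.9} \approx 0.101\%$.

Between years, with all rates annual:

* **0-group to age 1 (cannibalism).**
  $N_{1,y+1} = O_y \cdot \min\!\big(1,\; e^{-M_0 + \epsilon_{O,y}} /
  (1 + \beta_0 (N_{3,y} + N_{4,y}))\big)$: Beverton-Holt style intercohort
  density dependence driven by the same-year abundance of cannibalistic cod
  of ages 3--4, with a lognormal survival shock
  $\epsilon_O \sim N(0, \sigma_O^2)$.
* **Juveniles (ages 1--3), intracohort compensation.**
  $N_{a+1,y+1} = N_{a,y} e^{-M_J} / (1 + \beta_a N_{a,y})$ — survival falls
  with the cohort's own abundance, saturating at $e^{-M_J}/\beta_a$
  (compensation, no overcompensation).
* **Adults (ages 5--9).** $N_{a+1,y+1} = N_{a,y} e^{-(M_A + F_{a,y})}$ with
  natural mortality fixed at $M_A = 0.2$ yr$^{-1}$. Fish leave the model
  after age 9; there is no plus group.
* **Fishing.** Cod recruit to the fishery at age 4 ($F = 0$ below).
  $F_{a,y} = e^{s_a + U_y}$ is separable into a fixed log selectivity
  $s_a < 0$ and a log-effort year effect following a random walk
  $U_y \sim N(U_{y-1}, \sigma_U^2)$ with $U_{1} = 0$ for identifiability.
  True catch follows the Baranov equation
  $C_{a,y} = N_{a,y} \frac{F}{F + M_A} (1 - e^{-(F + M_A)})$.

## The observation model

All series are lognormal around the latent states. Reported landings get a
mean-one multiplicative error,
$C^{obs} = C \exp(\epsilon - \sigma_C^2/2)$, so landings are unbiased for
the true catch. Winter bottom-trawl indices for ages 1--9 are
$I_{a,y} = q_{a,y} N_{a,y} \exp(\delta_y + \epsilon_{a,y})$ with
age-specific error SDs and a shared year effect $\delta_y \sim
N(0, \sigma_{yr}^2)$ capturing correlated within-year survey errors; the
within-year residual correlation between two ages is
$\sigma_{yr}^2 / (\sigma_{yr}^2 + \sigma_I^2)$. Because the survey's
sampling area and codend mesh changed in 1993/1994, ages 1--2 have separate
catchabilities before and after the regime year (1994 by default; ages 3+
indices are assumed corrected upstream). Egg, larval and 0-group indices
have their own catchabilities and error SDs and no shared year effect (they
come from different surveys). Survey indices carry no mean-one correction —
it would only rescale the catchability estimates. Missing cells are encoded
as absent observations (never zeros); the CSV loader rejects non-positive
index values outright.

## Priors and estimation

Fixed constants: $f$, $M_{egg}$, the larval/early-juvenile daily mortalities
and durations, and $M_A = 0.2$. Priors on the estimated parameters:

| Parameter | Prior | Notes |
|---|---|---|
| $M_0$ | LogNormal(median 0.425, log-var 0.5) | informative; confounded with 0-group catchability |
| $M_J$ | LogNormal(median 0.2, log-var 0.5) | informative |
| $\log q$ (ages, 0-group) | Normal(0, var 1000) | vague |
| $\log q$ (eggs, larvae) | Normal(-25, var 1000) | vague, scale-informed mean |
| $s_a$ | Normal(-1.6, var 1000), $s_a < 0$ | truncated to negative |
| $\gamma$ | Normal(0, var 1000) | sign-unconstrained |
| $\beta_0$, $\beta_{1..3}$, all SDs | Uniform(0, upper) | uppers audited post fit |

The "variance 0.5" of the mortality priors is taken on the log scale (the
variance of the underlying normal), standard state-space practice. The
uniform upper limits are configuration, not science: defaults (1e-8 for
$\beta_0$, 2e-9 for $\beta_{1..3}$, 1--3 for the SDs) are set from the scale
of the biology, and `audit_uniform_uppers()` warns whenever any posterior
draw comes within 5% of its bound, in which case the limit should be raised
and the model refit. No prior for $\gamma$ is biologically established, so
it gets the same vague normal as the other unconstrained parameters.

Estimation is by Gibbs/slice sampling through JAGS (`rjags`). The joint
density — observation likelihood, process-error terms ($\epsilon_E$,
$\epsilon_O$, effort innovations, survey year effects, first-year abundance
priors) and parameter priors — is also exposed directly as
`log_posterior()` for testing and diagnostics. Two sampler profiles exist:

* **desk** (default): 3 chains, 400 adaptation + 800 burn-in iterations,
  1200 kept draws per chain. Runs in minutes on one core and recovers the
  well-identified parameters; diagnostics typically still flag the weakly
  identified, prior-dominated ones (notably $M_0$ and the catchabilities it
  trades off against), which is expected at this chain length.
* **paper**: 3 chains, 250 000 burn-in, 250 000 sampling iterations thinned
  by 1000 (750 kept draws) — the full-scale published configuration; budget
  hours rather than minutes.

Starting values matter for a state-space model of this depth: chains are
initialized from the prior medians with each catchability matched
empirically to the mean log-ratio of its observed indices to a
deterministic mean-path simulation, then jittered per chain. Chains get
distinct Mersenne-Twister streams derived from the configuration seed, so
fits are exactly reproducible.

`convergence_report()` computes split-chain potential scale reduction
(flag at $\hat R < 1.05$), Geweke z-scores (flag at $|z| < 2$), lag-1
autocorrelation of the kept chains (flag at $< 0.2$), effective sample
sizes, and the posterior cross-correlation matrix. Non-convergence is
recorded in the fit metadata and warned about, never silent.

## The synthetic-data generator

`generate_dataset()` emulates the study system end to end so every stage of
the pipeline is testable without any survey data:

* **Truth.** The reported posterior medians are the generating values:
  $M_0 = 0.35$, $M_J = 0.15$, $\beta_0 = 1.82 \times 10^{-9}$,
  $\beta_{1..3} = (0.95, 1.69, 2.27) \times 10^{-10}$,
  $\sigma_E = \sigma_O = 0.7$, plus the fixed constants above.
* **Covariates.** Weight-at-age follows a cubed von Bertalanffy curve with
  smooth year-to-year condition variation; maturity is a logistic ogive
  centred near age 6.8 (NEA cod mature at 6--8 years), below 1% at age 1
  and above 95% by age 9; temperature is a centred AR(1) anomaly with
  stationary SD 0.5 deg C.
* **Effort history.** Mean log effort follows a piecewise path (gradual
  rise to the late 1980s, sharp drop, recovery in the late 1990s, steady
  decline) with random-walk innovations on top, mimicking the qualitative
  history of fishing pressure on this stock.
* **Missingness.** Egg/larval indices 1959--1990 only, 0-group from 1966,
  winter ages 1--9 from 1981, landings from 1959.
* **Burn-in.** The initial age vector is spun forward for twice the maximum
  age (18 years) before the first output year; a doubling of the seed
  abundances leaves the output years essentially unchanged.
* **Calibration.** Selectivities put fishing mortality in the historically
  realistic 0.4--1.0 range, which sets equilibrium age-1 abundance near
  $1.25 \times 10^9$ so that $\beta_a N_a$ is order 0.1--0.3 — the
  density-dependence strength the reported coefficients and survivals
  imply. The reported means (0-group survival 0.41 alongside ages-1--3
  survivals of 0.75--0.77 and cannibal abundance near $4\times10^8$) cannot
  all hold simultaneously at the model's own equilibrium, so the generator
  prioritises the intracohort strength; realized mean survivals fall
  roughly in 0.35--0.6 (0-group) and 0.75--0.85 (ages 1--3) depending on
  the realized trajectory.

What the generator does **not** emulate: real Kola temperatures or ICES
landings values, time-varying selectivity, spatial structure, survey
zero-inflation, or multispecies effects. Passing tests therefore demonstrate
that the estimation machinery is correct and calibrated under the model's
own assumptions — not that those assumptions hold for the Barents Sea.

## Numerical and design choices

* Temperature enters as a linear offset to the larval-phase *daily*
  mortality over the 60-day larval window only — the simplest form
  consistent with warm years surviving better and with a baseline survival
  inside the published 0.08--0.12% range.
* $M_0$ and $M_J$ are annual rates applied over one-year transitions; the
  informative priors and the reported survivals are only coherent on that
  scale.
* In the Beverton-Holt compositions the lognormal shock multiplies survival
  *before* the cap at 1, keeping the density-independent limit exact and
  survival inside (0, 1].
* $t_{EL}$ (egg-to-larval-survey gap) is a configuration parameter, 20 days
  by default, which makes the deterministic egg-to-recruit chain
  scale-consistent with realistic absolute abundances.
* The cannibalism covariate uses same-year abundances of ages 3--4 at the
  start of the 0-group-to-age-1 transition.
* Interannual variances are *sample* variances (n-1 denominator) of natural
  logs.
* The abundance-survival correlation (the density-dependence screen applied
  to raw indices) is Pearson on logs. The survival index for age $a$ spans
  the previous to the subsequent age class,
  $s_y = \log I_{a+1,y+1} - \log I_{a-1,y-1}$, deliberately excluding
  $I_{a,y}$ so its observation error is independent of the abundance axis;
  for age 1 the previous class is the 0-group index. Two caveats the
  synthetic experiments make explicit: a catchability regime change that
  enters both axes as a shared step can fake density dependence (use
  regime-free or corrected indices), and the age-1 statistic is diluted by
  the 0-group process shock $\sigma_O$, which is survival variation, not
  observation error, and therefore appears on both axes.
* Percentile summaries (credible bands for survival and age-class curves)
  are computed draw by draw so posterior parameter correlations propagate;
  they are invariant to draw order.

## Problem sizes used by the tests

The test suite runs the full 52-year scenario for the desk-profile recovery
check (one fit, minutes), a reduced 6-age/15-year scenario for the
20-replicate coverage study (each fit seconds), 100 paired simulations for
the variance-dampening contrast, 10 000 bootstrap resamples for the Fig-2
style correlations, and a prior-only MCMC run (all observations masked)
whose marginals must match the priors to Kolmogorov-Smirnov distance < 0.1.

## Known limitations

* $M_0$, $M_J$ and the stage catchabilities are mutually confounded; only
  the informative mortality priors keep them identified, and their
  posteriors move little from those priors. This mirrors the original
  analysis, which fixed $M_A$ outright for the same reason.
* Desk-profile chains are far too short for full convergence of the weakly
  identified block; rely on the paper profile (or longer) for final
  inference and treat desk fits as calibrated point/interval summaries of
  the well-identified parameters.
* The no-plus-group choice truncates cohorts at age 9; for stocks with
  substantial survival past the maximum age a plus group would be needed.
* A supplementary age-by-year stochastic error on fishing mortality and a
  Ricker (overcompensatory) alternative to the Beverton-Holt form are
  deliberately out of scope; the published analysis found the former
  immaterial and rejected the latter.
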