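---
title: "Incarceration as a network contagion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incarceration as a network contagion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incarcsim)
```

## The model

`incarcsim` implements a susceptible–incarcerated–susceptible (SIS)
contagion on a synthetic influence network. An incarcerated agent *i*
"transmits" to each susceptible network neighbour *j* independently each
month with probability $p(i \to j)$; over an $s$-month sentence the
cumulative probability is $1-(1-p)^s$. Release returns the agent to the
susceptible state, with no immunity and no residual infectivity — the whole
mechanism lives in the sentence (the infectious period) and the
relationship-typed monthly rates.

Three ingredients are held fixed across the two race scenarios: the
network, the monthly rates, and the initial conditions. Only the
sentence-length distribution differs (mean 14 / median 10 months for the
White scenario, 17 / 12 for the Black scenario, reflecting reported
sentences served for drug offences). Any divergence between the scenarios
is therefore attributable to sentencing alone. The random-mixing reduction
of the same model shows why small sentencing differences can matter so
much: with transmission rate $p$ and sentence $s$, the steady-state
prevalence is

$$I = \begin{cases} 0 & s \le 1/p \\ 1 - 1/(ps) & s > 1/p,\end{cases}$$

so a critical sentence $s_c = 1/p$ separates extinction from an endemic
state, and the two scenario means are intended to straddle it.

## Monthly transmission rates

The packaged survey table gives the probability that an inmate's mother,
father, sister, brother, spouse or adult child is also incarcerated,
by the inmate's sex. Rates are derived by inverting the cumulative formula
at a calibration sentence of $s = 14$ months (between the two scenario
means): $p = 1-(1-P)^{1/s}$. Full precision is kept internally; the
round trip back to the survey values is exact to machine precision.

Row resolution for a susceptible neighbour of an inmate:

* a susceptible **parent** takes the mother/father row by the parent's own
  sex;
* a **sibling** — and a close **friend**, treated as a sibling — takes the
  sister/brother row by the susceptible's sex;
* a **spouse** takes the spouse row;
* the inmate's own **child** takes the adult-child row once aged 18 or
  older, and is not a transmission target before that (no rate is surveyed
  for minor children; the threshold is configurable).

Columns are always the inmate's sex. Sentence-marginalised transmission
probabilities $\sum_s \pi(s)\,[1-(1-p)^s]$ are available both as a
Monte-Carlo estimate and as an exact truncated summation (tail mass below
$10^{-10}$), used as mutual cross-checks in the tests.

## Sentence-length distributions

Sentences are $S = 1 + X$, $X \sim \mathrm{NB}(r, q)$ on $\{0,1,\dots\}$.
The +1 shift guarantees a non-empty infectious period (a zero-month
sentence would make the rate derivation ill-defined). The fit scans the
dispersion $r$ over a fixed grid $(0.055, 50]$ in steps of $0.005$; for
each $r$ the success probability is solved exactly from the mean
constraint, so every grid point matches the target mean to machine
precision, and the smallest $r$ whose CDF-based integer median equals the
target is selected. This is deterministic, requires no optimiser, and the
fitted parameters are serialised into run provenance. Infeasible targets
fail with the nearest attainable median named.

## The synthetic population

The generator emulates a closed, multi-generational US-like population on a
yearly clock:

* **Founders** (default 1500) with sex Bernoulli(0.5), birth years uniform
  over the 60 years before iteration 0, locations uniform on the unit
  square.
* **Mortality** from sex-specific annual life tables. The packaged default
  is a Gompertz–Makeham hazard calibrated by bisection to life expectancies
  of 81 (female) and 76 (male) years, absorbing at age 119; an official
  table can be supplied as CSV.
* **Age at first birth** $h = 15 + r$ with $r \sim$ Poisson(10.6), giving
  the reported mean of 25.6 years. Only the mean is documented for the
  source distribution; Poisson is the maximum-entropy-style single-parameter
  choice on the offset and is configurable.
* **Completed fertility** from a PMF on 0–5 children with mean exactly
  2.07. The source distribution is not published; the default
  {0: .15, 1: .17, 2: .33, 3: .21, 4: .09, 5: .05} reproduces the
  documented mean with a realistic spread.
* **Friendships** form on an agent's 10th birthday: a friend count drawn
  from a PMF on 0–5 (default mean 1.46, a close-discussion-network scale),
  then the nearest non-sibling candidates aged 9–11 by Euclidean distance.
* **Partnering** happens in the year of a female's first birth: the
  nearest alive male 0–9 years older who is not a friend and not related
  within two generations, monogamously (a male already in a spouse tie is
  ineligible — the spousal transmission row presumes a single spouse).
  If no candidate exists she remains a single mother.
* **Children**: the first is born in the partnering year; later birth
  years add independent Poisson(4.5) offsets. Child locations are the
  parents' midpoint plus uniform ±0.05 noise per axis, clipped to the unit
  square. All of a mother's children are scheduled at her first-birth
  year. Founder females whose first-birth age precedes iteration 0 start
  their families at iteration 0: the recorded growth of the seed
  population into a five-figure total requires every founding lineage to
  reproduce.
* **Clock and retention**: 200 yearly iterations with events ordered
  births → friendships → partnerships → deaths (fixed for
  reproducibility); the first 150 years are discarded as burn-in and
  agents alive at any later time are retained with all ties among them.

With the defaults this yields a population of roughly nine thousand
retained agents and tens of thousands of ties from a single realisation
(sizes vary by seed; the spatial "communities" are emergent, not
parameterised).

What the generator deliberately does **not** emulate: divorce and
re-partnering, same-sex partnerships, migration, race-specific demography
(the network is intentionally identical across scenarios), and any
dependence of mortality on incarceration. Passing tests on this synthetic
population demonstrate properties of the *mechanism*, not forecasts for any
real population.

## The epidemic engine

The epidemic clock is monthly; population year $Y$ maps to month
$(Y-150)\times 12$, so the 50-year retained window exactly covers a
600-month horizon. Within a month: releases due, then spell activations,
then deaths (truncating open spells), then new infections drawn from the
set infectious during that month. Infections detected in month $m$ begin
their spell at $m+1$ — newly infected agents do not transmit in the month
of infection, which removes any within-month order dependence. A spell
with sentence $s$ starting at $\sigma$ is infectious during
$\sigma,\dots,\sigma+s-1$ exactly.

Initialisation seeds $\mathrm{round}(\pi_0 \times \text{alive})$ agents —
so month-0 prevalence over the whole alive population equals the nominal
initial prevalence, the scale on which results are reported — drawn
uniformly among alive agents of incarcerable age, each serving a fresh
full sentence from month 0. The minimum incarcerable age defaults to 15
years (configurable; nothing younger is ever seeded, infected or counted
as at-risk). Prevalence is incarcerated / alive, over all ages.

Ensembles run replicate $r$ with seed $\texttt{rng\_seed} + r$ on one
shared network; summaries are the per-month mean and the empirical
2.5/97.5 percentile band. Per-month scenario comparisons use Welch
two-sample tests across replicates, with zero-variance months flagged
rather than failed.

The non-contagious control shares every line of the bookkeeping and
differs in exactly one place: infections arise as independent
Bernoulli(rate) draws per eligible susceptible per month instead of
through edges. Its rate is tuned by bisection on the ensemble-mean final
prevalence (25 replicates per step, common random numbers across steps),
bracketing the flow-balance analytic guess
$\pi_0 = t/\big((1-t)\,E[s]\big)$ for target $t$; the closed-form
equilibrium $\pi_0 E[s]/(1+\pi_0 E[s])$ doubles as a test oracle (for
$\pi_0 = 0.00182$ and $E[s] = 17$ it gives 3.0%).

## Recidivism statistics

One release record per spell ending in release. A release is a recidivism
event if the agent's next spell starts within 36 months ("return within
three years"). Releases without 36 fully observable months — the horizon
ends, or the agent dies, inside the window — are censored and excluded
from denominators (the source reports do not state their rule; censoring
is the conservative choice). Rates are tabulated by prior-incarceration
count (1, 2, 3, 4, 5+), age at release (5-year bins from 15, 60+ open),
and sentence length (12-month bins, 97+ open); the cumulative return curve
is normalised over returners. Everything is computed per replicate, then
summarised as the cross-replicate mean with 2.5/97.5 percentiles (linear
interpolation between order statistics, `quantile` type 7). Empty bins are
reported missing, not zero.

## The calibrated mean transmission rate

The population-wide mean rate feeding the steady-state analysis is
estimated as contact infections divided by incarcerated person-months,
pooled over replicates (and by default over both scenarios' ensembles).
The source procedure is not documented; this estimator is the direct
empirical-rate reading and is exactly testable on hand-built logs
(2 infections over 40 person-months → 0.05).

## Numerical and testing choices

* All randomness flows through R's generator from a single seed per run;
  identical (configuration, seed) reproduce byte-identical event logs and
  CSVs.
* Lifespans are sampled from the exact pmf implied by sequential survival
  (identical in distribution, one draw per agent).
* Table reproduction uses half-up rounding to 3 decimals; internal
  computation never rounds.
* Test problem sizes are chosen to keep the default suite desk-scale:
  ensembles of 50 replicates for prevalence levels (the study design used
  250), 25 for the control model and recidivism structure, $10^5$ draws
  for distributional checks, and exhaustive Markov-chain enumeration on a
  3-agent line as the engine's independent oracle (one-month sentences
  make the infectious set a Markov state).

## Known limitations

* **Levels near the bifurcation are fragile by design.** The two scenarios
  sit close to $ps = 1$, where the endemic level $1-1/(ps)$ has unbounded
  sensitivity to the effective transmission intensity. That intensity
  depends on network features (friend- and children-count distributions,
  founder age structure, life tables) for which only means are documented;
  the generator fixes defaults a priori. Qualitative structure — the
  extinction/endemic contrast between the scenarios, the calibrated rate
  straddled by the two mean sentences, recidivism patterns — is robust
  across seeds; ensemble prevalence *levels*, and anything within a few
  tens of percent of them, are not. Different population realisations
  (seeds) shift final levels substantially, as the single-realisation
  design implies.
* **The null model's cumulative return curve cannot be convex at
  equilibrium.** With a constant spontaneous hazard $r$ the normalised
  curve among returners is $(1-(1-r)^k)/(1-(1-r)^{36})$ — slightly concave,
  near-linear. Convexity can only appear transiently while prevalence is
  still rising. The model's distinguishing fact is the *contrast*: strongly
  concave under contagion, near-linear without it.
* The contagious decline of recidivism with sentence length weakens when
  the epidemic is well above threshold (saturated family clusters make the
  hazard at release insensitive to how long the agent was away), so that
  gradient is regime-dependent.
* Agents' lifespans are independent of incarceration, so simulated
  releases at advanced ages are more common than in real data; the
  age-at-release profile is correspondingly stretched.
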