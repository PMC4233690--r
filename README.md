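# incarcsim

An agent-based susceptible–incarcerated–susceptible (SIS) model of
incarceration as a social contagion, for quantitative criminologists and
epidemiological modellers studying how sentencing policy interacts with
social-network feedback.

## The model

Incarceration behaves like an infectious process: the close relations of an
inmate face elevated incarceration risk, through economic strain, exposure to
criminal networks, and official bias. `incarcsim` treats this as an SIS
epidemic on an *influence network* of kinship and close-friendship ties:

- While agent *i* is incarcerated it "transmits" to a network neighbour *j*
  each month with probability *p(i → j)* that depends on the relationship
  type (mother, father, sister, brother, spouse, adult child — close friends
  are treated as siblings) and the inmate's sex. Over an *s*-month sentence
  the cumulative transmission probability is 1 − (1 − *p*)<sup>*s*</sup>.
- The infectious period is the sentence length, drawn from a race-specific
  shifted negative binomial fitted to a target mean and median (Whites:
  mean 14 / median 10 months; Blacks: 17 / 12, for drug offences).
  Released agents return to the susceptible state.
- Monthly rates are derived by inverting the cumulative formula at a
  14-month calibration sentence from surveyed co-incarceration marginals,
  *p* = 1 − (1 − *P*)<sup>1/*s*</sup>.
- The network is a synthetic multi-generational population (founders,
  life-table mortality, fertility and partnering rules, spatially matched
  friendships) generated with a 150-year burn-in.

Because the two race scenarios share the *same* network, the *same*
transmission rates and the *same* initial conditions, any divergence between
them is attributable to the three-month difference in mean sentence alone.
The random-mixing reduction of the model makes the amplification explicit:
the steady-state prevalence is *I* = 0 for *s* < 1/*p* and 1 − 1/(*ps*)
otherwise, so a critical sentence length *s*<sub>c</sub> = 1/*p* separates
extinction from an endemic state, and sentences on opposite sides of
*s*<sub>c</sub> produce categorically different epidemics.

A non-contagious control (spontaneous incarceration at a flat tuned rate)
and recidivism statistics (rates by prior incarcerations, age at release,
sentence length, and the cumulative return curve, with cross-replicate
simulation intervals) complete the toolkit: the contagious model reproduces
the structural patterns of real recidivism data, while the control does not.

## Worked example

```r
library(incarcsim)

white <- fit_sentence_nb(14, 10, label = "white")
black <- fit_sentence_nb(17, 12, label = "black")
white
#> Sentence-length distribution (white)
#>   shifted negative binomial: size = 0.91  prob = 0.0654206
#>   mean = 14 months; median = 10 months

monthly_rate_table()     # monthly p(i -> j), columns = inmate's sex
#>      relation female   male
#> 1      mother 0.0009 0.0035
#> 2      father 0.0113 0.0114
#> 3      sister 0.0081 0.0043
#> 4     brother 0.0332 0.0302
#> 5      spouse 0.0043 0.0008
#> 6 adult_child 0.0170 0.0063

pop <- generate_population(population_config(seed_size = 400,
                                             total_iterations = 150,
                                             burn_in = 100), seed = 7)
pop
#> Synthetic population
#>   retained agents: 1740
#>   ties: 6490 (friend 1754, parent_child 2659, sibling 1550, spouse 527)
#>   clock: years 100 to 150 retained (burn-in 100 years)

cfg <- epidemic_config(black, monthly_rate_table(), init_prevalence = 0.01,
                       horizon = 300, n_replicates = 20, rng_seed = 7)
ens <- run_ensemble(pop, cfg)
ens
#> SIS ensemble: 20 replicates, 300 months, scenario 'black', mechanism contact
#>   final prevalence: mean 3.439% (95% band 0.000% - 9.468%)
```

Starting from 1% incarcerated, the long-sentence scenario grows to a mean
3.4% after 25 years on this small network (the wide band reflects the small
population: single replicates range from extinction to saturation of the
susceptible clusters). Recidivism rates rise with the number of prior
incarcerations — an emergent property, since the model gives ex-inmates no
intrinsic elevated risk; their *local network* has become infectious:

```r
rec <- compute_recidivism_tables(extract_release_records(ens))
round(rec$by_prior$mean, 3)
#> [1] 0.355 0.540 0.635 0.685 0.686

p_hat <- calibrate_mean_rate(ens)        # transmissions / inmate-month
sprintf("p = %.4f, critical sentence = %.1f months", p_hat,
        critical_sentence(p_hat))
#> [1] "p = 0.0636, critical sentence = 15.7 months"
100 * steady_state_prevalence(0.0612, 17)   # endemic level for s > s_c
#> [1] 3.88...  (about 3.9%)
```

With the calibrated rate the two mean sentences (14 and 17 months) fall on
opposite sides of the critical sentence — short sentences die out, long ones
sustain an endemic prison population.

`run_experiment()` chains the full pipeline (population → ensembles →
recidivism → CSV/JSON/PDF outputs) from a JSON config; a thin command-line
dispatcher over the same functions is installed at
`inst/cli/incarcsim.R` (verbs: `generate-population`, `simulate`,
`simulate-null`, `recidivism`, `ode`, `ode-calibrate`, `run-experiment`).

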