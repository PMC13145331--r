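# immeta

Integrated metapopulation models (IMMs) for stage-structured migratory
birds that winter in discrete subpopulations connected by dispersal.

Population dynamics of strongly site-faithful migrants — the motivating
system is Arctic-nesting geese wintering at traditional sites in Britain
and Ireland — cannot be understood from any single site: local abundance
trends mix local survival and fecundity with immigration and emigration
among sites. `immeta` is for quantitative population ecologists who want
to fit such systems jointly: it combines three data streams in one
hierarchical Bayesian model across four subpopulation groups (three focal
groups with individually marked birds plus a pooled "Elsewhere" group),

* annual counts, `y[i,t] ~ logNormal(log Ntot[i,t], tau_y)`,
* juvenile counts from age-ratio sampling, `Jobs[i,t] ~ Poisson(J[i,t])`,
* multistate capture–resighting m-arrays with multinomial rows,

on top of the stage-structured process model

```
J[i,t]   ~ Poisson(A[i,t] * gamma[i,t])
N1[i,t]  ~ Binomial(J[i,t-1],  phiJ[i,t-1] * (1 - sum_j psiJ[i->j,t-1]))
Nad[i,t] ~ Binomial(A[i,t-1],  phiA[i,t-1] * (1 - sum_j psiA[i->j,t-1]))
I[i,t]   ~ Poisson(sum_s phiJ[s] psiJ[s->i] J[s,t-1] + phiA[s] psiA[s->i] A[s,t-1])
A = N1 + Nad + I,   Ntot = J + A
```

with log-linear environmental effects (growing degree days on wintering,
staging and breeding ranges; cumulative snowfall) on fecundity,
logit-linear storm and hunting-period effects on survival with Laplace
shrinkage across groups, and logit-scale random year effects on all rates.
Inference is a compiled adaptive Metropolis-within-Gibbs sampler with
discrete latent-state updates; post-fit tools provide transient life-table
response experiment (tLTRE) decompositions of realised growth, net adult
immigration rates for source–sink classification, and movement-scenario
projections. A synthetic-data generator with exactly the model's
statistical structure makes the whole pipeline testable end to end. The
methods vignette (`vignettes/immeta-methods.Rmd`) documents the model,
priors, sampler and design choices.

## Worked example

```r
library(immeta)

# simulate a 39-winter synthetic study at the default field magnitudes
sim <- simulate_dataset(sim_config(seed = 42))

# fit the integrated metapopulation model (short desk-scale schedule)
fit <- fit_mcmc(sim$data, imm_spec(),
                mcmc_config(n_chains = 2, n_iter = 8000, n_burn = 3000,
                            thin = 5, seeds = c(1, 2)))

sm <- summarize_draws(fit)
subset(sm, grepl("alpha_phiA|alpha_p\\[", parameter))
#>         parameter median lower90 upper90
#> 34  alpha_phiA[W]   0.80    0.78    0.81
#> 35 alpha_phiA[Is]   0.86    0.84    0.87
#> 36 alpha_phiA[LK]   0.86    0.84    0.87
#> 37  alpha_phiA[E]   0.89    0.87    0.90
#> 86     alpha_p[W]   0.88    0.87    0.89
#> 87    alpha_p[Is]   0.89    0.88    0.90
#> 88    alpha_p[LK]   0.91    0.91    0.92
#> 89     alpha_p[E]   0.28    0.26    0.30
```

The among-year mean adult survival (`alpha_phiA`) and resighting
probabilities (`alpha_p`) recover the generating values (0.79, 0.86, 0.86,
0.89 and 0.90, 0.89, 0.92, 0.28): high detection at focal sites, low
detection in the pooled group.

```r
max(gelman_rubin(fit))
#> [1] 1.29
```

At this short schedule a few weakly identified hunting-period and storm
effects still sit above the 1.1 rule of thumb; the full-length schedule
(`mcmc_config(3, 270000, 10000, 10)`, 78,000 retained draws) is
configuration-selectable.

```r
net_immigration(fit, n_draws = 200)$overall
#>   group   inet lower90 upper90                   class
#> 1     W  0.079   0.071   0.086  sink (net immigration)
#> 2    Is -0.017  -0.021  -0.011 source (net emigration)
#> 3    LK  0.045   0.033   0.056  sink (net immigration)
#> 4     E -0.043  -0.049  -0.037 source (net emigration)
```

About 8% of the `W` group's adults each year are net immigrants — a sink
maintained by the pooled source group — mirroring the generating dispersal
pattern.

```r
lt <- tltre_decompose(fit, "W", n_draws = 200)
head(lt$summary[order(-lt$summary$pct), c("parameter", "pct")], 4)
#>   parameter  pct
#> 3      phiA 54.2
#> 1     gamma 23.0
#> 8    iota_E 14.5
#> 6   iota_Is  4.9
```

Temporal variance in `W`'s realised growth is attributed mostly to adult
survival, fecundity and immigration from the pooled group, with credible
intervals from the posterior.

A command-line pipeline wrapping the same functions ships in
`inst/cli/immeta` (`simulate`, `fit`, `diagnose`, `ltre`, `project`, `all`
subcommands, one YAML configuration, fully seeded).

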