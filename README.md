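# netdbt

Global inconsistency assessment for network meta-analysis (NMA) of
dichotomous outcomes, built around the design-by-treatment interaction
(DBT) model and its Wald chi-squared test.

## The problem

NMA pools randomised trials comparing different subsets of interventions,
so every pooled effect mixes direct head-to-head evidence with indirect
evidence routed through shared comparators. That mixing is only valid under
*consistency*: studies of different *designs* (sets of compared treatments)
must agree about the same contrasts up to heterogeneity and sampling error.
`netdbt` is for methodologists and systematic reviewers who need to test
that assumption globally, and to study how often it fails across
collections of published networks.

## The model

Study-level baseline contrasts of log odds ratios are modelled as

    y_i ~ N(X_i beta, S_i + tau^2 P_i)

with exact within-study covariance `S_i` (multi-arm studies give correlated
blocks), a common between-study variance `tau^2`, and compound-symmetry
structure `P_i` (correlation 0.5). The DBT model gives every design its own
relative-effect parameters `theta`; consistency restricts `theta = A beta`.
The inconsistency parameters `omega = C theta` (rows of `C` spanning the
left null space of `A`) are tested jointly:

    Q_inc = omega' (C V C')^+ omega  ~  chi^2 on df = sum_d (t_d - 1) - (T - 1)

with the within-design `tau^2` estimated (REML or DerSimonian–Laird) under
the DBT model and plugged in. The package also provides Cochran's Q with
its exact within-/between-design decomposition, I², structural network
metrics (designs, loops, inconsistency df), a batch survey pipeline
(prevalence of evidence of inconsistency, correlations with network
structure, multivariable regression, subgroup and year-trend summaries),
and a synthetic trial-network generator with Monte-Carlo harnesses for
type-I error, power and heterogeneity recovery.

## Worked example

Simulate a three-treatment loop network with heterogeneity `tau = 0.1` and
a planted 0.9 log-odds-ratio shift on the B:C design, then test it:

```r
library(netdbt)

cfg <- sim_config_triangle(studies_per_design = 4, n_per_arm = 1000,
                           tau = 0.1,
                           inconsistency = list("B:C" = c(C = 0.9)))
ds <- simulate_network(cfg, seed = 42)
structure_metrics(ds)
#> Structure of network 'sim-seed42'
#>   studies 12 | treatments 3 | direct comparisons 3 | designs 3
#>   multi-arm studies 0 | independent loops 1 | df(inconsistency) 1
#>   single-study comparison present: no

nma_fit(ds, model = "consistency", estimator = "reml")
#> Network meta-analysis fit: consistency model (REML)
#>   contrasts: 12 | parameters: 2 (rank 2)
#>   tau^2 = 0.1513 (tau = 0.3890) | Q = 143.8487 on 10 df | I^2 = 93.0%
#>   estimate     se
#> B  -0.0068 0.1645
#> C   0.8045 0.1643

dbt_test(ds, estimator = "reml")
#> Design-by-treatment interaction test for 'sim-seed42'
#>   Q_inc = 43.4114 on 1 df, p = 4.436e-11 (REML, tau^2_within = 0.0197)
```

The planted design conflict is flagged decisively (p ≈ 4e-11). Note the
signature of inconsistency in the heterogeneity estimates: the consistency
model absorbs the design disagreement as heterogeneity (tau ≈ 0.39), while
the within-design variance under the DBT model stays near the generating
value (tau² ≈ 0.02).

Batch analysis of a directory of long-format CSVs (columns
`study,treatment,events,n`, one row per arm):

```r
sv <- survey_networks("networks/", estimators = c("reml", "dl"))
prevalence(sv$records)                     # % with evidence of inconsistency
characteristic_correlations(sv$records)    # p-value vs log(structure)
multivariable_regression(sv$records)       # p ~ studies + treatments + edges + loops
```

A thin command-line front end lives at `inst/cli/netdbt.R`
(`fit`, `survey`, `simulate` subcommands).

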