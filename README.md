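# pumba

Multivariate hierarchical Bayesian analysis of PET pharmacokinetic
parameters.

## What it is for

Quantitative PET studies fit a pharmacokinetic model to each region's time
activity curve (TAC) and obtain several parameters per fit — blood delivery,
distribution volumes, rate constants, binding potentials. Conventional group
analysis keeps the binding parameter and throws the rest away. But the
discarded parameters are correlated with binding across subjects, and a
model that analyses them *jointly* can exploit those correlations to sharpen
the group contrast of interest: the conditional uncertainty of a parameter
given its correlated companions is smaller than its marginal uncertainty.

This package implements PuMBA (Parameters undergoing Multivariate Bayesian
Analysis) for users of kinetic modelling pipelines who want more statistical
power out of the data they already have: a joint model of all `m` log-scale
PK parameters over subjects `j` and regions `k`,

    theta[i,j,k] = alpha[i] + X[i,j]' beta[i] + tau[i,j] + upsilon[i,k]
                   + epsilon[i,j,k]

where the subject deviations `tau[j]`, pooled region deviations
`upsilon[k]` and residuals `epsilon[j,k]` are each m-dimensional
multivariate normal, and binding/delivery parameters get per-region fixed
effects instead of pooling. The group difference is the `beta` coefficient
of the binding parameter (`BP_P` for the two-tissue model, `V_T` for the
one-tissue model, `BP_ND` for the reference-tissue model); a log-scale
difference `d` is `100*(exp(d)-1)` percent.

Around the core model the package provides the full working environment:

* forward kinetic models (2TC, 1TC, SRTM) with exact analytic convolution,
* kinfitr-style count-based frame weighting and weighted multi-start
  bounded NLS with condition-number identifiability diagnostics,
* univariate comparators (lme4 mixed model, per-region Welch t-tests),
* synthetic-data generators for parameter-level and TAC-level simulation
  studies with reproducible seed ledgers,
* study-level evaluation: density-based power and false-positive-rate
  estimation, bias, precision, correlation-matrix recovery,
* CSV/YAML I/O and a command-line script
  (`system.file("scripts", "pumba", package = "pumba")`).

MCMC runs on JAGS via rjags.

## Worked example

Simulate a patient–control study (20 subjects per group, nine regions, a
true 0.1 log-unit ≈ 10.5% group difference in `BP_P`), fit PuMBA, and
compare with the univariate mixed model:

```r
library(pumba)

cfg <- generative_config("2tc", mode = "parameter", delta = 0.1,
                         n_per_group = 20)
set.seed(7)
tab <- generate_parameter_dataset(cfg)

pf <- cfg$profile
spec <- pumba_spec(pf$parameters, formulas = list(BPP = ~ group),
                   binding = "BPP", delivery = "K1",
                   priors = default_priors(pf$central_values))
fit <- fit_pumba(build_pumba(spec, tab), chains = 4, warmup = 500,
                 sampling = 500, seed = 11)
extract_group_difference(fit)
#> $estimate
#> [1] 0.0949...
#> $se
#> [1] 0.0479...
#> $ci_low
#> [1] 0.000301...
#> $ci_high
#> [1] 0.189...
#> $percent
#> [1] 9.95...

fit_lme(tab, "BPP")[, c("estimate", "se", "ci_low", "ci_high")]
#>   estimate     se  ci_low ci_high
#> 1   0.0703 0.0727 -0.0722   0.213
```

Both methods see the simulated 10.5% difference, but the multivariate model
estimates it with a substantially smaller standard error (0.048 vs 0.073)
— its 95% credible interval excludes zero while the univariate confidence
interval does not. That precision is borrowed from the other PK parameters
through the subject-level correlation structure (here the strong
delivery–binding correlation in the generative profile), not from
anti-conservative intervals: at `delta = 0` the false-positive rate stays
at or below the nominal 5% (see the evaluation tests).

The methods vignette (`vignettes/pumba-methods.Rmd`) documents the model,
priors, the inference backend, the generators and their limitations.

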