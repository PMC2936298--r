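# bwmort

Mixture-based modeling of birthweight-specific fetal-infant mortality.

Birthweight categories (ELBW, VLBW, ...) discretize a continuous
phenomenon, and infants of identical weight need not share a risk:
compromised and uncompromised pregnancies can both produce a 2500 g
infant. `bwmort` models a birthweight distribution as a k-component normal
mixture,

    f(x) = sum_j w_j * phi(x; mu_j, sigma_j),

and then, conditional on that fit, estimates a separate birthweight-specific
mortality curve inside each component (generalized parametric mixtures of
logistic regressions, PMLR):

    r_j(x) = logit^-1[ p_j(z_j) ],   z_j = (x - mu_j)/sigma_j,

with `p_j` a degree-4 polynomial, so each curve can be U-shaped with up to
two convexity changes. The population curve is the posterior-weighted
combination `R(x) = sum_j tau_j(x) r_j(x)`. Because single-sample curve
estimates are noisy, inference combines `N_rep` (possibly overlapping)
samples on the logit scale and forms intervals

    theta_bar +/- { B_hat + C * S_theta / sqrt(N_rep) },

with a simulation-based bias adjustment `B_hat`, a constant `C` calibrated
by a coverage study, and an overlap correction
`C_phi = C0 * phi * N_rep / (1 - (1-phi)^N_rep)` when each sample is a
fraction `phi` of a finite population. Within- and between-population
mortality odds ratios and covariate-within-component probabilities round
out the toolkit. Intended users: perinatal epidemiologists and
biostatisticians analyzing vital-statistics birth cohorts.

## Worked example

```r
library(bwmort)

spec <- reference_scenario(Inf)          # built-in 4-component scenario
rec  <- simulate_records(spec$mixture, spec$risk, 50000, seed = 42)
mix  <- fit_mixture_em(rec, k = 4, seed = 7)
mix
#> 4-component normal mixture (birthweight, g)
#>         weight mean_g  sd_g
#>   comp1 0.0077  825.9 229.4
#>   comp2 0.1729 2741.1 713.3
#>   comp3 0.7807 3179.9 424.5
#>   comp4 0.0387 3858.8 449.2
#> log-likelihood -385831.588 (n = 50000, converged after 19 EM iterations)

fit <- fit_pmlr(rec, mix, seed = 1)
risk_eval(fit, 3, 3170)                  # risk at 3170 g inside component 3
#> [1] 0.004130434
population_risk(fit, 2500)               # model-implied population risk
#> [1] 0.3777705
```

The mixture recovers the generating structure (weights 0.8/17/78/4%,
means 826/2741/3180/3859 g against true 832/2772/3170/3804 g). The
component-3 central risk of ~4.1 per 1,000 sits near the generating value
of 3.2 per 1,000, while the population risk at 2500 g is high (~0.38)
because the reference scenario's broad shoulder component carries a
steeply rising left limb — the crude rate in the [2400, 2500) bin of this
draw is 0.436, so the model-implied curve is tracking the data it was
given. Multi-sample inference combines several such fits:

```r
fits <- lapply(1:5, function(s) {
  r <- simulate_records(spec$mixture, spec$risk, 5000, seed = s)
  m <- fit_mixture_em(r, 4, seed = s)
  fit_pmlr(r, m, seed = s)
})
meta <- combine_risk_estimates(fits, j = 3, x = 3170)
risk_interval(meta, c = 4.0)             # C0 = 4, non-overlapping samples
or   <- odds_ratio_within(fits, 2, 3, 3000, c = 4.0)
```

A thin command-line interface (`inst/cli/bwmort`) exposes the same
pipeline as `simulate`, `fit`, `meta`, `coverage`, and `calibrate`
subcommands.

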