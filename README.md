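# colonydisp

Detection-corrected estimation of natal dispersal between two breeding
colonies from long-term tag-resight records.

## The problem

Colonial animals such as elephant seals breed at discrete sites, so natal
dispersal — a female breeding for the first time at a colony other than
her birthplace — is a binomial event that can, in principle, be counted
directly from resightings of animals tagged as pups. In practice the two
colonies are rarely searched with equal success. If lifetime detection
differs between sites, the observed emigrant fraction is biased: dispersal
*toward* the well-observed colony is overestimated and dispersal toward
the poorly observed colony is underestimated. `colonydisp` implements the
full correction chain and its error propagation for a two-colony system,
for population ecologists working with mark–resight data.

## The model

For each colony, three observable rates are chained together
(suppressing colony subscripts):

- **Reappearance** `pi = D_{t+1} / D_t`: the fraction of breeding females
  observed in year *t* that are observed again at the same colony in year
  *t+1*. Posterior: `pi ~ Beta(successes + 1, failures + 1)`.
- **Return** `tau`: the probability a tagged female is alive and still
  tagged a year later (survival × tag retention; only the product is
  identified). Estimated from the log-linear decay of the pooled age
  distribution of observed breeders, `tau = exp(slope)`, with a Normal
  posterior from the regression error.
- **Annual detection** `delta = pi / tau`, and **lifetime detection**

  ```
  Delta = delta / (1 - tau (1 - delta)),
  ```

  the probability that a female who ever breeds is ever observed
  (annual detection times the expected number of seasons to detection).

The observed per-cohort dispersal ratio `mu = b_emig / (b_emig + b_res)`
is corrected using only the destination/origin ratio of lifetime
detections, `D_ji = Delta_j / Delta_i`:

```
mu_hat = b_emig / (b_emig + b_res * D_ji)
```

Per-cohort corrected rates are fitted jointly in a hierarchical Bayesian
model: the observed emigrant count is Poisson with mean
`B mu_hat D_ji / (1 - mu_hat (1 - D_ji))`, annual rates share a Normal
hyper-distribution `mu_hat ~ N(theta, Sigma)` (optionally with a linear
year trend `theta = nu t + eta`), and a Metropolis sampler draws the
joint posterior, refreshing `D_ji` from its stored Monte-Carlo prior
sample at every step so detection uncertainty propagates without being
informed by the count data.

An individual-based simulator (`sim_truth()`, `simulate_population()`,
`recovery_experiment()`) generates two-colony populations with known
survival, tag retention, detection, and dispersal, so the whole pipeline
can be validated by parameter recovery.

## Worked example

The package bundles the published count tables of a 17-cohort two-colony
elephant seal study (Año Nuevo `AN` and Piedras Blancas `PB`,
1994–2010 birth cohorts): `seal_cohorts()`, `seal_reappearance()`,
`seal_return_rate()`.

```r
library(colonydisp)

rr <- seal_return_rate()
se <- (rr$upper - rr$lower) / (2 * qnorm(0.975))
tau_fits <- setNames(Map(return_rate_fit, rr$estimate, se), rr$colony)
det <- estimate_detection(seal_reappearance(), tau_fits, M = 1e5, seed = 1)
det
#> Detection posterior (1e+05 draws)
#>    colony   parameter  mean lower upper
#> 1      AN          pi 0.563 0.542 0.583
#> 2      AN         tau 0.799 0.789 0.809
#> 3      AN       delta 0.704 0.678 0.731
#> 4      AN       Delta 0.922 0.913 0.931
#> 5      PB          pi 0.165 0.138 0.194
#> 6      PB         tau 0.783 0.753 0.813
#> 7      PB       delta 0.211 0.175 0.249
#> 8      PB       Delta 0.551 0.492 0.608
#> 9   AN/PB Delta_ratio 1.678 1.516 1.873
#> 10  PB/AN Delta_ratio 0.598 0.534 0.659
```

A female breeding at `PB` is only 55% likely to ever be recorded, versus
92% at `AN`, so raw emigrant counts toward `AN` overstate northward
dispersal. Fitting the corrected hierarchical model for that direction:

```r
fit <- fit_dispersal(seal_cohorts(), det, from = "PB", to = "AN",
                     config = dispersal_config(seed = 1))
subset(summarize_posterior(fit),
       parameter %in% c("theta", "sigma", "mu_1995", "mu_2000"))
#>    parameter  mean lower upper
#> 2    mu_1995 0.255 0.159  0.39
#> 7    mu_2000 0.296 0.188  0.45
#> 18     theta 0.180 0.126  0.24
#> 19     sigma 0.087 0.038  0.15
```

`theta` is the mean corrected natal dispersal rate from `PB` to `AN`
across cohorts: about 18% of `PB`-born females that survived to breed
did so at `AN`, well below the raw pooled emigrant fraction of 26.5%
(`naive_dispersal(124, 344)`). The `mu_<year>` rows are per-cohort rates
with 95% credible intervals; small cohorts are shrunk toward `theta`.
Adult movement, by contrast, is rare:

```r
adult <- tally_adult_dispersal(seal_reappearance())
#> adult dispersal: 10 of 1413 pairs (0.7%)
```

which justifies treating natal dispersal as permanent.

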