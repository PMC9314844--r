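# breedprop

Integrated population modelling of breeding propensity, immigration and
spatial habitat quality in a long-lived colonial seabird.

## The scientific problem

In kittiwake-like seabirds, sexually mature birds often do not breed in a
given year: pre-breeders delay recruitment and established breeders may
"skip". If individuals are attracted to, and compete for, high-quality nest
sites, breeding propensity should (1) rise after years of high population
breeding success — provided good years reflect high quality across many
patches, i.e. low spatial heterogeneity — and (2) fall when the number of
competitors grows (negative density dependence). Testing this needs annual
estimates of quantities no field protocol observes directly: numbers of
pre-breeders, skippers and immigrants, and status-specific breeding
probabilities.

`breedprop` provides the full analysis chain for this problem:

* **Heterogeneity prerequisite** — per-year weighted Gini coefficient
  `G = Σᵢⱼ wᵢwⱼ|vᵢ − vⱼ| / (2 (Σw)² v̄)` of patch mean breeding success
  (weights = occupied nests), and its across-year correlation with
  population mean success.
* **Integrated population model (IPM)** — a nine-state pre-breeding-census
  life cycle (yearlings, pre-breeders of ages 2–6, first-time breeders
  including an annual immigrant pulse *I·t*, experienced breeders,
  skippers) with binomial/Poisson demographic stochasticity, fitted jointly
  to three data streams: log-normally noised breeder counts
  (`log C_t ~ N(log B_t, σ)`), individual capture–resighting histories
  (multistate likelihood marginalized by the hidden-Markov forward
  algorithm), and Poisson reproduction data per pair-experience category.
  Estimation is by an adaptive Metropolis-within-Gibbs sampler (C++ core)
  with vague bounded priors, including Uniform(−5, 1000) immigrant numbers
  so that "no immigration" remains testable.
* **Derived analyses** — per-draw growth rate λ_t = B_t/B_{t−1}, breeder
  composition by origin, integrative recruitment rate, immigration rate
  and present non-breeders; posterior partial correlations between breeding
  propensity at *t* and population features at *t − 1*, summarized by the
  sign-support statistic *P* (fraction of the posterior sharing the sign of
  its mean).
* **Synthetic data** — an individual-based generator for all four input
  streams with known truth, used throughout the tests.

## Worked example

A 28-year synthetic study at the documented study conditions (stationary
population of ~1700 breeders, 13% immigrants, annual rate variation):

```r
library(breedprop)
study <- generate_study(synthetic_config(seed = 42, rate_sd = 0.3,
                                         imm_log_sd = 0.4))
study
#> Synthetic study: 28 years
#>   counts: 1430..2196 breeders
#>   histories: 2160 ringed individuals
#>   reproduction: 24414 nests in total
#>   patches: 840 patch-years

prerequisite_check(study$patches)
#> Spatial-heterogeneity prerequisite: 28 years
#>   mean success 0.312 .. 1.149; Gini 0.070 .. 0.553
#>   Pearson r(mean success, Gini) = -0.866

fit <- run_mcmc(study, config = mcmc_config(n_chains = 2, n_iter = 2500,
                                            n_burnin = 1000, thin = 3,
                                            seed = 7, time_varying = TRUE))
summary(fit, pattern = "^(p_r|sigma_obs)$")
#>   parameter   mean      sd    q2.5  q97.5
#> 1       p_r 0.9966 0.00172 0.99258 0.9990
#> 2 sigma_obs 0.0268 0.01253 0.00874 0.0502

analysis_tables(fit)
#> Partial correlations with breeding population growth rate:
#>   survival      0.73 [ 0.51,  0.86] (P = 1.00)
#>   psi_b         0.68 [ 0.50,  0.83] (P = 1.00)
#>   psi_s         0.27 [-0.22,  0.61] (P = 0.78)
#>   int_recruit   0.34 [ 0.06,  0.57] (P = 0.99)
#>   imm_rate      0.95 [ 0.93,  0.97] (P = 1.00)
#> ...
```

Reading the output: the strong negative mean-success–Gini correlation says
good years are good *across* patches (the prerequisite holds by
construction in the generator); the growth-rate table says annual variation
in immigration and in the breeding rate of former breeders are leading
drivers of breeder-count fluctuations in this realization. The full output
also prints the 4 x 3 propensity-versus-features table; its
`immigrant ~ n_breeders` cell illustrates the mechanical negative coupling
of a rate to its denominator's scale. Posterior means of the demographic
rates recover the generating values (e.g. resighting of recruited birds
0.997 vs. 0.998 generated; count-error SD 0.027 vs. 0.05, the usual mild
underestimate when latent states can track the counts).

The pipeline driver runs the same stages from configuration lists:
`run_pipeline("simulate", ...)`, `"fit"`, `"derive"`, `"check-prereq"`,
`"ppc"`, each writing CSV/YAML outputs plus a log with seed and config
hash.

## Data file schemas

Bundles written by `write_bundle()` (and accepted by `read_bundle()`) are
plain CSVs with one-line headers:

* `counts.csv` — `year, count` (breeder equivalents, two per nest; years
  contiguous).
* `histories.csv` — long form `id, ring_year, year, code` with codes
  `0` not seen, `1` pre-breeder, `2` breeder, `3` skipper; the loader
  rejects structurally impossible histories (e.g. a breeder code before
  age 3).
* `reproduction.csv` — `year, category, n_nests, n_fledglings` with
  categories `FF` (both mates first-time breeders, both ringed), `EE`
  (both experienced, both ringed), `MIX` (mixed or unknown).
* `patches.csv` — `year, patch, n_nests, n_fledglings` for the
  heterogeneity analysis.
* `meta.yaml` — year range, generating seed and configuration hash.

## Package layout

* `R/` — projection and simulation (`project.R`, `synthetic.R`),
  likelihoods (`likelihood.R`), inference (`inference.R`), derived
  quantities and partial correlations (`derived.R`), heterogeneity
  (`gini.R`), I/O and pipeline (`io.R`).
* `src/` — the forward algorithm and the MCMC kernel (Rcpp).
* `vignettes/ipm-breeding-propensity.Rmd` — the methods vignette: model,
  priors, sampler design, generator assumptions, numerical choices and
  limitations.
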