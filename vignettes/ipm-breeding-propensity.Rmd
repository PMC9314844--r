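---
title: "An integrated population model for breeding propensity in a long-lived seabird"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated population model for breeding propensity in a long-lived seabird}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(breedprop)
```

## The problem

In long-lived colonial seabirds such as kittiwakes, sexually mature birds
often do not breed: pre-breeders delay recruitment, and established breeders
may skip a season. If high-quality nest sites are limited and birds compete
for them, breeding propensity should rise when habitat quality improves
across the population (more good sites to go around) and fall when the number
of competitors grows. Testing those predictions requires annual estimates of
quantities that cannot be counted in the field: the numbers of pre-breeders,
skippers and immigrants, and the status-specific probabilities of breeding.

`breedprop` implements the full chain of analysis: a weighted-Gini check that
good years are years of low spatial heterogeneity in breeding success (the
prerequisite for reading population breeding success as site availability);
an integrated population model (IPM) that estimates all demographic rates and
latent abundances from three data streams; and posterior partial-correlation
analyses of how breeding propensity responds to population features.

## The demographic model

The population is described on a pre-breeding census with nine classes:
yearlings `Y`, pre-breeders `P2`--`P6` by age, first-time breeders `F`
(locals plus immigrants), experienced breeders `E` and skippers `S`.
Transitions from year `t` to `t + 1` are governed by:

* `phi0`, survival over each of the first two years of life (fledgling to
  yearling and yearling to age 2); `phi2`, survival from age 2 for every
  older class;
* `rho3 .. rho6`, age-specific recruitment probabilities conditional on
  survival; recruitment is impossible before age 3 and forced at age 7
  (cases outside ages 3--7 are rare enough in this system to ignore);
* `psi_b`, `psi_s`, the probabilities that a surviving breeder or skipper
  breeds the next year;
* `pi_f`, `pi_e`, per-capita fledgling production of first-time and
  experienced breeders (half the per-nest number, two adults per nest);
* an annual immigrant pulse `I[t]` entering `F`.

Demographic stochasticity follows the standard binomial/Poisson scheme:
yearling recruitment is Poisson around the expected surviving local
production, and every survival/recruitment/breeding transition is a nested
binomial from its source class, so destination counts can never exceed their
sources. `project_expectation()` gives the deterministic expectation,
`simulate_transition()` one stochastic step, and `simulate_trajectory()` a
full individual-level realization whose aggregation reproduces the class
counts exactly (the individual paths are what the capture-history generator
consumes).

One reconstruction choice deserves note: `phi0` is applied to *both* the
fledgling-to-yearling and the yearling-to-age-2 transitions, reading
"survival at ages 0 and 1" literally; the alternative (applying `phi2` from
the yearling transition onwards) would change little at the estimates'
scale but is not what the life-cycle definition says.

Immigration is continuous and may be negative a priori (so the data can
place posterior mass on "no immigration"); the state projection uses the
clamped, rounded pulse `round(max(I, 0))`, while the raw value is kept for
inference and for the immigration rate `I[t] / B[t]`.

## The three likelihood components

**Counts.** Annual breeder counts (twice the number of nests) are treated as
log-normal around the latent breeder total `B = F + E` with time-constant
log-scale SD `sigma_obs`; `loglik_counts()` includes the `1/C` Jacobian so
the density is for the count itself.

**Capture-resighting histories.** Chicks are ringed at age 0 and resighted
in later years as pre-breeder, breeder or skipper, with no status
misassignment. Yearlings and older pre-breeders have year-specific
resighting probabilities; breeders and skippers share one constant, nearly
unit probability. Instead of sampling latent individual states in the MCMC,
`forward_loglik()` marginalizes them with the hidden-Markov forward
recursion over {pre-breeder (age-implicit), F, E, S, dead}. This is exactly
the same likelihood, but removes thousands of discrete latent variables from
the sampler. Identical histories are pooled with multiplicity weights.
Birds ringed before the study window are handled by conditioning on their
first in-window resighting (at which the status, age and survival are
known), so their pre-window years contribute nothing. Structurally
impossible histories evaluate to `-Inf` rather than raising errors; the data
loader, by contrast, rejects them.

**Reproduction.** Annual fledgling totals per pair category are Poisson:
per-nest rate `2 pi_f` for both-ringed first-time pairs, `2 pi_e` for
both-ringed experienced pairs, and for mixed/unknown pairs the population
rate `2 (F pi_f + E pi_e) / (F + E)` -- the experience-weighted mean, using
the latent breeder composition.

The joint log-likelihood is the sum of the three components plus the
state-process log-probability, assuming conditional independence of the
streams given the shared demographic process. In truth the streams observe
the same individuals, so the assumption is mildly violated -- a known and
deliberately accepted property of this model class.

## Priors, sampler, initialization

Priors are vague with reasonable bounds: Uniform(0, 1) for all
probabilities, Uniform(-5, 1000) per year for immigrant numbers,
Uniform(0, 1.5) for the per-capita productivity rates, discrete uniform
ranges (scaled to the first count) for the initial class sizes, and
Uniform(0.001, 0.25) for `sigma_obs`. The `sigma_obs` upper bound is worth a
comment: it is still five times the generating value and far above any
plausible error for counts of this quality, but a much looser bound creates
a funnel in which the latent breeder series drifts off the counts while
`sigma_obs` inflates to cover the gap, and finite chains mix through it very
slowly. Bounding the SD at a generous but finite value removes the
pathology without informing the estimate in the region that matters.

The initial class sizes deserve the same care. With generic wide ranges the
first-year latent structure is nearly unidentified (the data say little
about year-1 pre-breeder stocks), and in a reduced constant-rate fit the
resulting posterior transient -- implausible initial cohorts dying off over
the first few years -- leaks into the shared rates. For a near-stationary
population, `prior_spec(init_structure = ...)` lets the ranges be centred on
the stable class structure implied by the population's long-run rates, a
standard informative-prior choice in integrated population models; the
default band spans 0.6 to 1.6 times the structure values.

`run_mcmc()` is an adaptive Metropolis-within-Gibbs sampler written in C++:

* demographic rate families are updated as blocked reflected random-walk
  proposals shaped by the running posterior spread of each coordinate
  (adaptive Metropolis, acceptance target 0.234), so the capture-recapture
  forward pass -- the expensive term -- runs once per family per iteration.
  In the constant-rate model the eight rates form one merged block whose
  proposals use the full running covariance (the rates are strongly
  correlated through the latent states);
* detection probabilities are blocked the same way; `sigma_obs` and the
  productivity rates are cheap single-site updates (no forward pass);
* the latent structure (annual immigrant numbers, initial class sizes and
  the per-interval branch counts of the demographic process) is updated by
  single-site integer/continuous Metropolis moves with targeted likelihood
  neighbourhoods: each branch count touches only the handful of pmf terms
  that condition on it. Two further move types fight the slow mixing
  typical of state-space models: *interval refreshes* redraw all branch
  counts of one interval from the state-process prior (the proposal cancels
  the interval's own pmf terms, so only downstream terms enter the ratio,
  and an accepted refresh regenerates the interval wholesale); and
  *attribution swaps* change paired branch counts (e.g. breeding former
  breeders against breeding former skippers) in ways that leave every class
  count unchanged, decorrelating the latent attribution from `psi_b`,
  `psi_s` and `phi2`. Because latent moves are orders of magnitude cheaper
  than parameter moves, each iteration runs several latent sweeps
  (`latent_sweeps`). All targeted neighbourhoods are verified against full
  likelihood recomputation in the test suite (the `BP_VALIDATE_DELTAS`
  path, which cross-checks every Metropolis delta).

Proposal scales adapt with a diminishing Robbins-Monro step during burn-in
(targets 0.44 single-site, 0.234 blocked) and are frozen afterwards, so the
recorded chain is Markov. Initial values put the latent breeder series at
the observed counts (with the immigrant pulse absorbing each year's gap) and
start the well-identified rates at crude moment estimates -- year-to-year
observed transitions of recruited birds for `phi2`, `psi_b`, `psi_s`
(resighting of recruited birds is near-certain, so these are nearly direct
estimates) and category-specific fledglings-per-nest for `pi_f`, `pi_e`.
Starting from prior midpoints instead is supported but wasteful: the wrong
rates drag the latent states off the counts before burn-in recovers.

`convergence_report()` returns a potential scale reduction factor (ratio of
total to mean within-chain variance, an exact decomposition so duplicated
chains give exactly 1) and Geyer initial-positive-sequence effective sample
sizes. `posterior_predictive_check()` simulates replicate count and
reproduction data per draw and compares sums of squared Pearson residuals;
note that this discrepancy has limited power against a single corrupted
year, because the free observation SD partly absorbs it.

## Derived quantities and the association analyses

All derived quantities are computed per posterior draw, never from posterior
means:

* growth rate `lambda[t] = B[t] / B[t-1]`;
* breeder composition from the latent transition counts (former breeders,
  former skippers, local first-time breeders, immigrants -- summing to one
  exactly);
* the integrative recruitment rate: local recruits over local recruits plus
  surviving never-bred pre-breeders of ages 3--6 (immigrants excluded);
* the immigration rate `I[t] / B[t]`, with the raw `I`;
* present non-breeders: pre-breeders of ages 2--6 discounted by their
  resighting probability plus skippers discounted by the recruited-bird
  resighting probability. Yearlings are excluded: they are essentially
  absent from the colonies and their inclusion at a 5% detection rate would
  only add noise.

`analysis_tables()` assembles the two headline tables. Rates governing the
interval `(t-1, t]` are paired with `lambda[t]` (the natural pairing; the
alternative off-by-one pairing has no mechanistic reading). The propensity
table relates status-specific breeding propensity at `t` to population
breeding success, the latent number of breeders, and present non-breeders at
`t - 1`, each cell controlling for the other two features. All windows start
at the third study year, so nothing estimated for the poorly informed first
year enters a correlation. Partial correlations are computed by residual
regression (and tested against the precision-matrix formula); draws in which
a correlation is undefined are dropped and the dropped fraction reported.
Evidence is summarized by the sign-support statistic `P`, the fraction of
the posterior sample sharing the sign of its mean (exact zeros match
neither sign; a zero mean gives 0.5).

The covariate "population breeding success" is the per-draw weighted
per-nest rate `2 (F pi_f + E pi_e) / (F + E)`, consistent with the
mixed-pair reproduction rate; "number of breeders" is the latent `B`, not
the noisy count.

## Spatial heterogeneity of habitat quality

`weighted_gini()` implements the weighted mean-absolute-difference form
`G = sum w_i w_j |v_i - v_j| / (2 (sum w)^2 vbar)` with nest-count weights;
no small-sample correction factor `n/(n-1)` is applied (the correction is a
constant inflation that cannot change the sign or strength of the
across-year correlation, and the uncorrected form is the one with the
population-level interpretation). `prerequisite_check()` computes, per year,
the nest-weighted mean success and the weighted Gini across occupied patches
(zero-nest patches are excluded; years need at least two occupied patches),
then their product-moment correlation with a linear fit for plotting. The
default analysis scale is one patch per cliff; the patch identifier column
is scale-agnostic, so re-running at cove or colony scale is a relabelling.

## What the synthetic generator emulates -- and what it does not

`generate_study()` simulates the population at the individual level and
derives all four observable streams from one latent truth. The default
configuration *is* the documented study condition set: 28 years, mean rates
at the study population's long-run values (`phi0` 0.65, `phi2` 0.81,
`rho3..6` 0.13/0.41/0.53/0.67, `psi_b` 0.90, `psi_s` 0.69, `pi_f` 0.16,
`pi_e` 0.36), a constant immigrant pulse of 230 birds per year that balances
the local growth deficit (the local-only dominant eigenvalue is about 0.91,
immigrants make up ~13% of the ~1700 breeders at the resulting stationary
state, matching the reported scale), log-normal count error with SD 0.05,
resighting probabilities 0.05 / 0.81 / 0.998, 80 chicks ringed per year and
30% of breeders ringed. Annual variation is off by default and switched on
via `rate_sd` (logit scale for probabilities, log scale for productivity)
and `imm_log_sd`; an optional `dd_psi_b` coefficient makes `psi_b` respond
logit-linearly to the realized scaled breeder total, for testing the
density-dependence machinery.

By default all four streams observe the *same* simulated population, as in
a real study. `independent_streams = TRUE` instead draws the count and
reproduction streams from their own population realizations (same rates and
immigration), making the likelihood's between-stream independence assumption
hold exactly -- the appropriate design when the question is whether the
estimator is calibrated under its own assumptions, as in the coverage tests.

Features of real data the generator does not emulate: individual
heterogeneity in any rate (the spiral of failure, age effects beyond the
modelled classes), state misassignment, tag loss, non-independence of the
three streams beyond what sharing one latent population induces, dispersal
structure between patches (the patch table is generated from a separate
two-component failure mixture, coupled to year quality only through the
failure fraction), and pairs: mates are assigned ringed status and
experience independently with an optional assortment knob, because only the
category sizes and rates enter the likelihood. Passing tests on synthetic
data therefore shows the estimation machinery is self-consistent at the
study's scale -- not that the model is robust to these real-data
complications.

## Numerical choices and degenerate inputs

* Immigrant pulses are rounded to integers after clamping at zero; the raw
  continuous value feeds the immigration rate.
* Latent counts derived by subtraction (`P3..P6`, `S`) are guarded against
  negativity inside the kernel; proposals that would produce them are
  rejected.
* `weighted_gini()` returns `NA` when the weighted mean is zero; years with
  all-zero success propagate as missing and `prerequisite_check()` warns
  when the correlation is undefined.
* `partial_correlation()` errors on collinear controls and returns `NA` on
  zero residual variance; per-draw `NA`s are dropped with the fraction
  logged in the result.
* Empty data streams are allowed everywhere (a data-free run reproduces the
  priors), and an empty history set short-circuits the forward pass.

## Problem sizes used by the test suite

The suite runs the full pipeline at deliberately chosen scales: parameter
recovery uses 20 replicates of the default 28-year, 80-chicks-per-year
study, each fitted with three pooled chains of 3,000 iterations under the
calibration design (independent stream realizations, so the likelihood's
independence assumption holds exactly) and the stable-structure
initial-size prior; the null-calibration and
density-dependence checks use time-varying fits of ~3,000--4,000 iterations;
the hidden-Markov oracle enumerates all observation sequences of length up
to five against brute-force path sums; the projection oracle uses 100,000
Monte-Carlo replicates per configuration. These sizes give stable
pass/fail behaviour on a single CPU; larger runs sharpen the posteriors but
do not change what the tests demonstrate.

## Known limitations

* Desk-scale capture-recapture data (tens of ringed chicks per year) leave
  annual rate estimates wide; the annual series are honest but dominated by
  their priors in poor years, and partial correlations computed from them
  carry estimation-noise couplings that only more data can remove.
* The count-observation SD is weakly identified and typically
  underestimated when the latent series can track the counts; rate
  estimates remain nearly unaffected, but `sigma_obs` itself should not be
  over-interpreted.
* The sampler is a random-walk scheme: effective sample sizes per iteration
  are modest for `phi2` and `psi_b` (which are strongly coupled to the
  latent states), and long chains are the remedy.
* The immigration estimate inherits the usual IPM caveat: it is the
  population-balance residual, so any unmodelled loss process masquerades
  as reduced immigration.
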