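# morphdisp

Analysis of natal dispersal distances in color-polymorphic birds breeding on
finite nest-box networks — built for tawny-owl-style long-term studies in
which a heritable gray/brown plumage polymorphism (one locus, two alleles,
brown dominant) may interact with winter severity to shape how far juveniles
settle from their natal box.

The package is aimed at population ecologists working with ringing/recapture
data from nest-box networks: a box registry with coordinates and deployment
years, a recruit table linking natal and first-breeding boxes, a winter
climate series, and an annual prey-trapping record.

## What it computes

**Covariates.** The winter temperature anomaly for a cohort hatched in year
*Y* is the mean temperature over Dec 1 *Y* – Feb 28 *Y+1* minus the mean of
those winter means over a fixed 1981–2010 baseline (negative = colder than
average; Feb 29 excluded). Prey abundance is captures per 100 trap nights.

**The finite-area randomization null.** Observed dispersal is bounded by
the study area, so the package compares the observed median dispersal
distance against settlement drawn uniformly at random over each recruit's
*detectable* boxes (availability follows the network's enlargement year).
With `m` repetitions (default 999), the randomized P value is

&nbsp;&nbsp;&nbsp;&nbsp;p = (#{null medians ≤ observed median} + 1) / (m + 1),

so the smallest attainable value at m = 999 is 1/1000 ("P < 0.001").
Morph-stratified tests run the identical procedure within each morph.

**Morph-by-environment models.** Dispersal distance is fit by REML as

&nbsp;&nbsp;&nbsp;&nbsp;dispersal ~ morph × anomaly + prey + sex + mass_z (+ age) +
(1|year) + (1|brood) + (1|natal box),

with Type III F tests and Satterthwaite denominator degrees of freedom
(df = 2v²/(gᵀWg) from the contrast variance v, its gradient g in the
variance components, and their asymptotic covariance W). A binomial GLM
tests whether the yearly proportion of brown recruits depends on the winter
anomaly. Broom-style `tidy()`/`glance()` and `autoplot()` methods cover all
result objects.

**Synthetic populations.** `simulate_population()` generates the whole data
structure — boxes, Mendelian morph inheritance, environment, recruitment,
and settlement by a latent dispersal kernel or uniformly at random — so
calibration, power, and parameter-recovery experiments run without field
data.

## Worked example

```r
library(morphdisp)

params <- sim_params(seed = 2024)      # study-scale defaults
bundle <- simulate_population(params)
bundle
#> Synthetic population bundle (kernel settlement)
#>   boxes: 360   cohorts: 40   ringed: 2983   recruits: 171
#>   seed used: 2024

report <- run_dispersal_pipeline(bundle, reps = 999, seed = 1)
report
#> Dispersal analysis report
#>   recruits: 171 (171 complete cases)
#>   dispersal: mean 10.8 km (SD 6.3), range 0.3-27.3 km
#>   morph-proportion GLM slope: 0.114 +/- 0.116 (P = 0.322)
#>   LMM all_ages (n = 171): interaction F1,157.8 = 2.75, P = 0.0993
#>   LMM one_year_olds (n = 66): interaction F1,59.0 = 6.26, P = 0.0151
#>   randomization [all]: observed 11.1 vs expected 13.2 km, P = 0.019
#>   randomization [gray]: observed 11.1 vs expected 13.2 km, P = 0.033
#>   randomization [brown]: observed 11.2 vs expected 13.1 km, P = 0.156
```

Reading this: ~6% of ~3,000 ringed offspring recruited locally; mean
dispersal is ~10.8 km. The generator builds in a +2.4 km/°C morph-by-anomaly
interaction (brown disperses farther than gray in mild winters, shorter in
cold ones); in this replicate the estimate is positive in both analysis
sets and significant among one-year-olds (single replicates at n ≈ 170 have
roughly coin-flip power for this effect size — the recovery experiment in
`scripts/acceptance.R` quantifies that across replicates). The
randomization block shows the philopatry signal: the observed median
(11.1 km) sits below the 13.2 km median expected if settlement were random
over the detectable boxes (P = 0.019 overall; the small brown stratum is
noisier). The GLM finds no effect of winter anomaly on the morph
composition of recruits — none is simulated.

Individual stages are ordinary functions over data frames:

```r
sets <- candidate_distances(bundle$recruits, bundle$registry)
null <- randomization_test(bundle$recruits$dispersal_km, sets, m = 999, seed = 1)
tidy(null)
autoplot(null)                 # null-median histogram with observed line

ing <- ingest_bundle(bundle$registry, bundle$recruits, bundle$winters, bundle$prey)
fit <- fit_dispersal_lmm(ing$recruits, set = "all_ages")
tidy(fit, effects = "terms")   # Type III F table
autoplot(marginal_effects(fit))
```

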