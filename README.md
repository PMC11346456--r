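# abxdyn

Models of the class-level history of antibacterial drugs: how fast new
drug classes are discovered, how fast clinical resistance to them is first
detected, and how large the repertoire of classes *without* detected
resistance is at any point in time.

The package is aimed at quantitative epidemiologists and drug-discovery
analysts working with timeline tables of drug classes — one row per class
with a discovery year, an optional first-clinical-use year, and an
optional first-resistance year (missing = not yet detected, i.e.
right-censored).

## The models

**Time to resistance.** The interval from discovery of a class to first
detection of clinical resistance is modelled as exponential with constant
hazard λ per year. The clinical *half-life* is the median,
t<sub>1/2</sub> = ln 2 / λ. With right-censoring, the maximum-likelihood
estimate has the closed form

&nbsp;&nbsp;&nbsp;&nbsp;λ̂ = (number of events) / (total exposure years),

and a binned Poisson variant fits the histogram of observed intervals:
bin counts are Poisson with mean
μ<sub>i</sub> = N·(e<sup>−λa<sub>i</sub></sup> − e<sup>−λb<sub>i</sub></sup>).
Confidence intervals come from a seeded percentile bootstrap.

**Discovery.** Class discovery is a coupon-collector process: screening
draws arrive as a Poisson process at rate *n* per year, starting
t<sub>lag</sub> years after an origin year t<sub>0</sub>, and each draw
lands uniformly on one of *k* discoverable classes. The expected number of
distinct classes discovered by time t is

&nbsp;&nbsp;&nbsp;&nbsp;E[D(t)] = k·(1 − e<sup>−n·τ/k</sup>),&nbsp; τ = max(0, t − t<sub>0</sub> − t<sub>lag</sub>),

fitted by Poisson maximum likelihood on yearly new-class counts over an
integer grid of (k, t<sub>lag</sub>) with *n* profiled out numerically.

**The not-yet-resistant repertoire.** Classes with detected resistance
accrue as the convolution of the discovery intensity with the per-class
exponential resistance law, E[R(t)] = ∫ D′(s)·(1 − e<sup>−λ(t−s)</sup>) ds,
and the headline curve is U(t) = E[D(t)] − E[R(t)] — the number of classes
discovered but still without detected resistance. A literal
exponential-growth reading of R(t) is available as an alternative mode.

A seeded generative simulator (`simulate_timelines()`) produces synthetic
timeline tables with exactly this structure, so every fitting stage is
validated by parameter recovery in the test suite.

## Worked example

Fit the resistance half-life on the small illustrative table shipped with
the package (synthetic, not curated history):

```r
library(abxdyn)
tab <- read_timelines(system.file("extdata", "synthetic_timelines.csv",
                                  package = "abxdyn"))
iv  <- compute_intervals(tab, observation_year = 2020)
fit_exponential_mle(iv)
#> Exponential time-to-resistance fit (censored ML)
#>   hazard:    0.04762 per year
#>   half-life: 14.56 years
#>   events: 7   censored: 1   log-likelihood: -28.31
```

Seven of the eight classes have detected resistance; the eighth
contributes 33 censored exposure years. The fitted hazard 0.048/year means
roughly a 5% chance per year that a discovered class has resistance
detected; the 14.6-year half-life is the median wait.

Run the full pipeline on a simulated 1900–2020 history (pool of 30
classes, 1.5 draws/year after a 28-year lag, true half-life 15 years):

```r
cfg <- simulation_config(discovery_params(k = 30, n = 1.5, t_lag = 28, t0 = 1900),
                         half_life = 15, horizon_year = 2020, seed = 7)
rep <- run_pipeline(sim = cfg, seed = 7, include_censored = TRUE)
#> abxdyn: half_life = 17.97 y, k = 30, n = 1.609 /y, t_lag = 28 y (seed 7)
rep$dfit
#> Coupon-collector discovery fit (Poisson ML on yearly counts)
#>   pool size k:      30 classes
#>   sampling rate n:  1.609 draws/year
#>   lag phase t_lag:  28 years (origin t0 = 1900)
#>   log-likelihood:   -53.05   (converged)
rep$curves
#> Dynamics curve (per_class_hazard): 121 years [1900, 2020], half-life 20.0418 years
#>   peak not-yet-resistant repertoire: 13.52 classes in 1951
```

The fit recovers the generating truth (k = 30, t_lag = 28, n ≈ 1.6 vs
1.5; half-life 18 vs 15 with a 95% CI of [11.7, 25.7] from 30 classes):
sampling spread at this cohort size is the dominant uncertainty, which is
what the bootstrap interval expresses. `plot(rep)` draws the three panels
(scatter of discovery year vs time to resistance, interval histogram with
the fitted exponential, and the D/R/U curves).

A thin command-line wrapper with `validate`, `intervals`, `simulate`,
`fit-resistance`, `fit-discovery`, `curves` and `report` subcommands is
installed at `system.file("scripts", "abxdyn.R", package = "abxdyn")`.

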