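# aldasplit

When is a coarse binary label a *better* research target than the
continuous score it came from?

The Alda score rates lithium responsiveness in bipolar disorder on an
integer 0–10 scale and is usually dichotomized at τ = 7 into "responders"
(≥ 7) and "non-responders". The folk statistical rule says dichotomization
throws information away. But the scale's reliability is asymmetric: only
79 of its 2673 item combinations can produce a total ≥ 7, against 2159
for a total ≤ 3, so raters agree tightly at the top of the scale and
diffusely at the bottom. `aldasplit` provides the machinery to show that,
under such asymmetric reliability plus observation noise, the dichotomized
representation can retain **more** mutual information about the ground
truth — and more statistical power — than the raw scale.

## What is inside

* **Scale combinatorics** — exhaustive enumeration of the A/B item
  structure (`alda_total_score()`, `count_combinations()`,
  `b_sum_distribution()`).
* **Empirical rating model** — a Dirichlet–multinomial model of observed
  ratings given consensus gold standards. For prior concentration α
  (a priori observation noise), the smoothed conditional is the posterior
  mode θ̂ᵢ ∝ max(0, α + nᵢ − 1); the dichotomized scale gets ξ = 11α/2 so
  both representations carry equal total prior mass. `mi_curves()` traces
  I_α(observed; gold) for both representations and `crossover_alpha()`
  finds where the binary curve overtakes the raw one
  (`read_ratings()` ingests rater-by-vignette CSVs).
* **Synthetic reliability generator** — seeded (x, y) pairs on [0, 10]
  with uniform background noise fraction 1 − ω, diagonal spread σ, and an
  optional logistic heteroscedastic profile that makes the *low* tail
  reliable (`sample_dataset()`, `grid_dataset()`,
  `generate_rating_fixture()`).
* **MI estimators** — exact 2×2 histogram MI at a threshold
  (`dichotomized_mi()`) and continuous MI by Gaussian-KDE with Scott
  bandwidths and Monte-Carlo integration (`continuous_mi_kde()`), plus
  `threshold_sweep()` for the dichotomized-vs-continuous comparison.
* **Analytic power** — Fisher-Z power of the Pearson correlation test,
  power_ρ = Φ(√(n−3)·|ζ(ρ̂)| − z₁₋α/₂), and exact power of Fisher's exact
  test via Fisher's noncentral hypergeometric distribution
  (`pearson_power()`, `fisher_exact_power()`, `fnch_pmf()`,
  `power_experiment()`).
* **CLI** — `alda_cli()` / `inst/cli/aldasplit` with subcommands
  `alda-combos`, `make-fixture`, `empirical-mi`, `simulate`,
  `mi-experiment`, `power-experiment`, `reproduce`; CSV outputs with JSON
  provenance sidecars.

## Worked example

```r
library(aldasplit)

count_combinations(7, 10)   # ways to score >= 7
#> [1] 79
count_combinations(0, 3)    # ways to score <= 3
#> [1] 2159

# a synthetic 59-rater matrix with the study's gold standards and
# tighter agreement on responder vignettes (sd 0.8 vs 2.0)
fx <- generate_rating_fixture(seed = 1)
tabs <- impute_missing_counts(build_count_tables(fx))
curve <- mi_curves(tabs, alpha_grid = c(1, 2, 5, 10, 50))
round(as.data.frame(curve), 4)
#>   alpha    xi mi_raw mi_binary
#> 1     1   5.5 0.7551    0.3966
#> 2     2  11.0 0.5562    0.3791
#> 3     5  27.5 0.3204    0.3340
#> 4    10  55.0 0.1796    0.2766
#> 5    50 275.0 0.0257    0.0978
curve
#> MI curves over 5 concentrations, alpha in [ 1 , 50 ]
#>   dichotomized MI overtakes raw MI at alpha ~ 4.618
```

With little prior noise (α = 1) the raw 11-point scale carries almost
twice the mutual information of the binary split (0.755 vs 0.397 nats).
As the assumed observation noise grows the raw representation decays much
faster, and beyond α ≈ 4.6 the dichotomized scale is the more informative
one (at α = 50: 0.098 vs 0.026 nats).

The same reversal shows up in test power under asymmetric reliability and
heavy background noise (70% of observations pure noise, spread σ = 15):

```r
pw <- power_experiment(betas = 1, omegas = 0.3, sigmas = 15,
                       taus = c(3, 5), runs = 25, seed = 1)
subset(pw$summary, select = c(method, tau, mean_power, ci_low, ci_high))
#>    method tau mean_power    ci_low   ci_high
#> 1  fisher   3  0.9687098 0.9353808 1.0000000
#> 2  fisher   5  0.7525489 0.6533931 0.8517048
#> 3 pearson  NA  0.8683307 0.8022528 0.9344086
```

The "tail split" at τ = 3 (cutting at the reliable low tail) keeps 97%
power where the continuous Pearson test keeps 87% and the conventional
median split only 75%.

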