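# mprisk

Probabilistic human-health risk assessment of plasticizer-bearing
microplastics (MPs) in groundwater.

Groundwater increasingly carries polyvinyl chloride (PVC) microplastic
particles, and PVC is plasticised with di(2-ethylhexyl) phthalate (DEHP) —
an endocrine disruptor with established oral toxicity values — at mass
fractions up to ~30 %. Anyone drinking that water takes in DEHP by two
routes: the fraction already leached into the water, and the fraction
released from the ingested particles during digestion. `mprisk` quantifies
the resulting carcinogenic and non-carcinogenic risk for exposure
scientists and risk assessors, with the diversity of particle size *and
shape* treated probabilistically rather than by a single average particle.

The model, end to end:

- **Size spectrum.** Survey abundance tables (`%` per size class) are
  fitted to a power law `y = b·x^(−α)` by log–log OLS; per-site indices α
  are pooled, and a continuous truncated power-law spectrum on 20–5000 µm
  is sampled by exact inverse-CDF.
- **Shape → volume.** Particle size L maps to volume per morphology:
  fragments are ellipsoids (4πabc/3), fibers cylinders (π(W/2)²L), films
  boxes (LWH), spheres 4π(L/2)³/3, with width/height set by L:W:H
  aspect-ratio bounds.
- **Exposure.** `C_w = C_mp·ρV·R·(L1 + L2)` mg/L, then
  `ADD = C_w·CR_w·EF·ED/(BW·AT)`, `HQ = ADD/RfD0`, `ECR = SF0·ADD`.
- **Monte Carlo.** 50,000 seeded iterations over the full input set
  (triangular, truncated-normal, Gumbel-minimum, power-law families),
  summarised by percentiles, threshold-exceedance probabilities, and
  contribution-to-variance sensitivity (normalised squared Spearman rank
  correlations).

A synthetic survey generator provides every input with known ground truth,
so the whole pipeline is testable without any external download. See the
vignette (`vignettes/risk-model.Rmd`) for the model's assumptions and the
design choices, including the density-unit convention.

## Worked example

```r
library(mprisk)

# 1. a five-site survey with known per-site indices, then fit and pool
survey <- generate_survey(c(1.97, 1.81, 0.99, 2.28, 1.62),
                          noise_sd = 0.1, seed = 42)
fits <- fit_power_laws(survey)
fits
#> # A tibble: 5 × 5
#>   site   alpha       b r_squared n_points
#>   <chr>  <dbl>   <dbl>     <dbl>    <int>
#> 1 site_1  1.97 142864.     1.000        5
#> 2 site_2  1.81  82782.     0.999        5
#> 3 site_3  1.04   3285.     0.997        5
#> 4 site_4  2.28 455743.     0.998        5
#> 5 site_5  1.56  26834.     0.999        5
aggregate_alpha(fits)
#> # A tibble: 1 × 3
#>   mean_alpha sd_alpha n_sites
#>        <dbl>    <dbl>   <int>
#> 1       1.73    0.469       5

# 2. the bundled groundwater PVC/DEHP scenario, uniform-envelope volume
res <- run_simulation(default_scenario(), seed = 1)
risk_percentile(res, "ECR", "adult", 0.95)   # 8.69e-07
risk_percentile(res, "ECR", "child", 0.95)   # 2.82e-06
risk_percentile(res, "HQ",  "child", 0.95)   # 0.0101
exceedance_probability(res, "ECR", "child", 1e-6)  # 0.229

sensitivity_analysis(res, "adult")
#> # A tibble: 9 × 4
#>   receptor input spearman_rho contribution_pct
#>   <chr>    <chr>        <dbl>            <dbl>
#> 1 adult    C_mp         0.630            47.6
#> 2 adult    V            0.536            34.5
#> 3 adult    R            0.265             8.39
#> 4 adult    CR_w         0.227             6.20
#> # … 5 more rows
```

Reading these numbers: the 95th-percentile excess cancer risk is below the
10⁻⁶–10⁻⁴ regulatory band for adults and just above its floor for children
(ECR > 10⁻⁶ in ~23 % of iterations), while the hazard quotient stays far
below 1 for both receptors — no expected non-carcinogenic effect. Particle
concentration and particle volume dominate the output variance, which is
why shape (which drives volume) matters: rerunning with
`default_scenario(volume = "fragment")`, `"fiber"` or `"film"` gives
per-shape 95th-percentile ECRs spanning a factor of ~50.

Plotting and tidying follow the usual conventions: `autoplot(res)` (ECDF
per receptor), `autoplot(sensitivity_analysis(res, "adult"))` (tornado
chart), `autoplot(fit_power_law(...))` (log–log fit), `tidy(res)` /
`glance(res)` for tabular summaries. `write_report(res, dir)` writes
percentile, exceedance and sensitivity CSVs plus a run-metadata YAML;
`write_scenario()` / `read_scenario()` round-trip scenario configurations
as YAML. A thin command-line wrapper with `fit-sizes`, `simulate` and
`sensitivity` subcommands ships in `inst/scripts/mprisk.R`.

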