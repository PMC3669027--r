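# skatedemog

Probabilistic Leslie matrix demography for data-poor skates.

Skates on the eastern Bering Sea slope are long-lived, late-maturing,
oviparous elasmobranchs caught mainly as bycatch, and no catch-at-age data
exist for them. `skatedemog` estimates their productivity from
life-history parameters alone, and propagates the uncertainty in those
parameters into every reported quantity. The package ships the
life-history records of five deepwater *Bathyraja* species
(*B. lindbergi*, *B. maculata*, *B. minispinosa*, *B. taranetzi*,
*B. trachura*) and a comparative table of 14 high-latitude skates, and
provides:

* the six standard indirect natural-mortality estimators (two Hoenig
  longevity regressions, Jensen's maturity form `M = 1.65/α` and growth
  forms `M = 1.5k`, `M = 1.6k`, and the age-specific Chen–Watanabe
  curve), plus the survival range they span;
* Monte Carlo draws of complete vital-rate sets from per-parameter PDFs —
  triangular longevity ω, truncated-logistic age at maturity α, uniform
  annual survival S<sub>x</sub> and fecundity m<sub>x</sub>, triangular
  egg-case survival l<sub>e</sub> — in independent (`iid`) or perfectly
  `correlated` across-age modes;
* birth-flow Leslie matrix assembly,
  `P_i = (l_i + l_{i+1}) / (l_{i-1} + l_i)` and
  `F_i = sqrt(l_e) (m_i + P_i m_{i+1}) / 2`, eigen-analysis
  (λ, stable age distribution **w**, reproductive value **v**),
  derived statistics (R₀, rT = log R₀, generation times μ₁ and Ā) and
  elasticities with fertility / juvenile-survival / adult-survival sums;
* 5,000-replicate simulation summaries (means and 2.5/97.5 percentiles),
  univariate sensitivity of λ to α and ω, and Pearson-with-t-test
  correlates of λ against life-history traits across assemblages;
* synthetic-data generators (species records, assemblages with a known
  maturity gradient, observer-style length frequencies) so the whole
  pipeline is testable without external data.

## Worked example

```r
library(skatedemog)

records <- load_species_records(
  skatedemog_example("bering_sea_skates.csv"))

estimate_mortality("hoenig_all_taxa", records[["Bathyraja taranetzi"]])
#> <mortality_estimate hoenig_all_taxa>
#>   M = 0.2996 yr^-1,  S = 0.7411 yr^-1

run_replicates(records[["Bathyraja taranetzi"]],
               n_reps = 5000, mode = "iid", seed = 1)
#> <simulation_summary> Bathyraja taranetzi (iid, n = 5000, seed = 1, rejected = 0)
#>    statistic     mean     p2_5   p97_5
#>       lambda  1.14700  1.05800  1.2350
#>           r0  4.65900  1.86000  9.3230
#>           rt  1.45600  0.62040  2.2320
#>          mu1 10.95000 10.15000 12.0400
#>         abar 10.47000  9.82600 11.5700
#>  e_fertility  0.09568  0.08643  0.1018
#>   e_juvenile  0.76220  0.71610  0.8044
#>      e_adult  0.14210  0.09813  0.1932
```

Read: under independently drawn vital rates, *B. taranetzi* grows about
15% per year at the stable age distribution (95% interval 1.06–1.24), a
female recruit leaves ~4.7 female offspring over her life, and λ is driven
overwhelmingly by juvenile survival (elasticity 0.76) rather than
fertility (0.10) — so a given proportional change in juvenile survival
moves λ about eight times as much as the same proportional change in
fertility or egg-case survival.

```r
comp <- load_comparative_table(
  skatedemog_example("high_latitude_skates.csv"))
run_correlate_suite(comp, "all")
#>               trait         r_p  n      t_stat    p_value
#> 1 alpha_omega_ratio -0.64481165 14 -2.92237574 0.01278378
#> 2         tl_max_cm  0.36939410 14  1.37701075 0.19365402
#> 3       depth_mid_m  0.02518669 14  0.08727695 0.93189087
```

Across 14 high-latitude skates, growth rate falls significantly as
maturation occupies more of the lifespan (r = −0.64, P = 0.01), while
body size and depth are not significant predictors.

`run_full_analysis()` executes every stage for all packaged species and
writes one CSV per stage plus a JSON manifest (seed, versions, checksums).
The methods vignette (`vignettes/skate-demography.Rmd`) documents the
model, the PDFs, the numerical choices and the known limitations.

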