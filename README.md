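# easidemand

Demand-system estimation for household scanner panels, built around the
implicit-utility (exact affine Stone index, EASI) share model. The package
targets the setting of at-home food and beverage purchase data — 13 demand
groups (8 beverage groups split at 4 g of sugar per 100 ml, 4 food groups,
and a residual numeraire), household-quarter observations, demographic
demand shifters, and a socioeconomic (LSM) stratification — and ships a
synthetic scanner-panel generator with known ground truth so that every
stage of the analysis can be validated end to end.

## The model

Budget shares `w` of J groups for a household-quarter with log price vector
`ln p` (relative to the numeraire, whose log price is 0), log total
expenditure `ln x` and demographics `z` follow, for j = 1..J−1,

```
w_j = b_j0 + Σ_r b_jr y^r + γ_j' z + Σ_k a_jk ln p_k + y Σ_k b*_jk ln p_k + ε_j
  y = (ln x − Σ_j w_j ln p_j + ½ ln p' A ln p) / (1 − ½ ln p' B ln p)
```

`y` is the implicit utility: Stone-index-deflated log expenditure with an
affine price correction. Engel curves are polynomials of any order R, so the
system accommodates arbitrary rank. The numeraire equation is implied by
adding-up. Prices are household-quarter Fisher indices over group-brand
elements (base prices and quantities at sample means), with unit values
missing through non-purchase imputed from group-level regressions on
quarter, province, LSM and brand.

Equations are estimated separately by Gaussian maximum likelihood (least
squares given `y`), iterating the closed-form `y` update against the
estimated price matrices, with cluster-robust (by household) covariances.
From the fitted system the package computes expenditure elasticities,
compensated (Hicksian) and uncompensated (Marshallian) price elasticity
matrices linked by the Slutsky identity `e^M_ij = e^H_ij − e_i w_j`, and
delta-method standard errors for their sample averages.

## Worked example

Simulate a 13-group panel calibrated to published budget-share descriptives,
run the full ingest → price-index → estimation chain, and average the
elasticities:

```r
library(easidemand)

dgp    <- dgp_table2(seed = 1)                       # known ground truth
panel  <- simulate_panel(dgp, n_households = 800, n_quarters = 13, seed = 7)
clean  <- apply_exclusions(panel$records)            # the documented filters
shares <- compute_budget_shares(clean$records)
prices <- fisher_index(impute_missing_prices(compute_unit_values(clean$records)))
fit    <- fit_easi(shares, prices, easi_config())
average_elasticities(fit, se = TRUE)
```

```
Elasticity table (13 groups; per_observation)
  bottled water                              own-price  -0.90 (1.64)  expenditure  1.20
  100% juice                                 own-price  -0.43 (0.65)  expenditure  1.31
  LS soft drinks                             own-price  -2.34 (1.18)  expenditure  1.25
  HS soft drinks                             own-price  -0.92 (0.09)  expenditure  0.98
  coffee and tea                             own-price  -0.85 (0.16)  expenditure  1.04
  milk and LS dairy drinks and alternatives  own-price  -0.95 (0.14)  expenditure  0.96
  HS dairy drinks and alternatives           own-price  -1.29 (1.54)  expenditure  1.24
  alcoholic beverages                        own-price  -0.54 (0.80)  expenditure  1.55
  chocolate and candy                        own-price  -1.13 (0.29)  expenditure  1.12
  desserts                                   own-price  -0.76 (0.16)  expenditure  1.07
  snacks                                     own-price  -1.05 (0.16)  expenditure  0.97
  FVNS                                       own-price  -0.93 (0.10)  expenditure  1.02
  numeraire                                  own-price  -0.89 (0.18)  expenditure  0.94
```

Own-price elasticities are negative throughout and expenditure elasticities
sit close to the generator's targets (e.g. 1.55 for alcoholic beverages);
standard errors are large exactly where the data are thin (bottled water is
bought in under 30% of household-quarters). Price coefficients estimated
through the record-level chain are attenuated toward zero by unit-value
noise in the reconstructed Fisher indices — the methods vignette quantifies
this and shows the model-level recovery checks that bypass it.

`run_pipeline()` drives the same chain overall and stratified by LSM and
writes per-stratum tables, fit reports and a checksummed manifest;
`render_tables()` formats elasticity tables with standard errors in
parentheses and significance stars.

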