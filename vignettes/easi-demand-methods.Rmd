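---
title: "Methods: an implicit-utility demand system for scanner panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an implicit-utility demand system for scanner panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easidemand)
```

## The model and its assumptions

Demand is modelled conditional on total at-home food and beverage
expenditure: shares of that budget over J = 13 groups (eight beverage
groups split at 4 g of sugar per 100 ml, four food groups, one residual
numeraire) respond to relative prices, expenditure and demographics, while
the allocation between this budget and everything else a household does is
outside the model. For the non-numeraire groups j = 1..J−1,

$$w_j = b_{j0} + \sum_{r=1}^R b_{jr}\,y^r + \gamma_j'z
  + \sum_k a_{jk}\ln p_k + y \sum_k b^{*}_{jk}\ln p_k + \varepsilon_j,$$

with implicit utility

$$y = \frac{\ln x - \sum_j w_j \ln p_j + \tfrac12 \ln p' A \ln p}
           {1 - \tfrac12 \ln p' B \ln p}.$$

The Stone deflator $\sum_j w_j \ln p_j$ runs over the J−1 non-numeraire
groups because the numeraire's log price is the normalisation (identically
zero; all prices are relative to it). With $A = B = 0$, $y$ is
Stone-deflated log expenditure. Because Engel curves are polynomials of any
order in $y$, the system can have any rank — the flexibility that motivates
this model class over AIDS-type systems, where rank is capped and Engel
curves are linear in log expenditure. The numeraire equation is never
estimated: adding-up implies its coefficients are the negatives of the
column sums of the others (`recover_numeraire()`), and homogeneity extends
the price matrices by a numeraire row and column the same way.

Assumptions worth keeping in view: shares may be zero (non-purchase) but the
model is linear, not censored — zeros attenuate coefficients of rarely
bought groups; $\varepsilon$ is treated as mean-independent of prices and
expenditure (no endogeneity correction); and shares respond to a single
group price index, so quantity/quality substitution within groups is folded
into the price response.

## Estimation

`fit_easi()` estimates the J−1 equations separately. Given $y$, every
equation is linear, and Gaussian maximum likelihood per equation is
numerically identical to least squares — this is the weakest reading of
"separate maximum likelihood" estimation and the one implemented. The
catch is that $y$ depends on $A$ and $B$. The fit therefore iterates:

1. initialise $y$ with the Stone approximation ($A = B = 0$);
2. fit all equations by least squares on the design
   (intercept, $y, \dots, y^R$, shifters, log prices, optional interactions);
3. recompute $y$ from the updated $A$, $B$ — using *observed* shares, which
   keeps $y$ a closed form and the estimator linear given $y$;
4. repeat until the largest change in $y$ is below `tol` (default 1e-8).

Convergence is fast (two to four passes) because the price-correction terms
in $y$ are second order. The coefficient covariance is assembled
block-diagonally from per-equation cluster-robust covariances
(`sandwich::vcovCL`, clustered on household). Setting the cross-equation
blocks to zero is an explicit approximation that comes with separate
estimation; it is recorded in the fit log. Survey-weighted estimation is
available but off by default.

Symmetry of $A$ cannot be imposed during separate estimation, so
`impose_symmetry = TRUE` applies a post-hoc minimum-distance projection of
the stacked price coefficients onto the symmetric subspace, weighting by the
inverse of their estimated covariance, then refits the remaining
coefficients with the symmetrised price term as an offset and replaces the
price-coefficient covariance block accordingly. On symmetric-truth
simulations the projection reduces the error in $A$ on average; it is off by
default because the default estimator mirrors the unconstrained
equation-by-equation fit.

## Elasticities

At an evaluation point $(w, \ln p, y)$ with $\Gamma = A + yB$ (compensated
share semi-elasticities, extended to the numeraire row and column by
adding-up and homogeneity) and $\mu_j = \partial w_j/\partial y$:

* expenditure: $e_i = 1 + \mu_i\,(dy/d\ln x)/w_i$,
* Hicksian: $e^H_{ij} = \Gamma_{ij}/w_i + w_j - \delta_{ij}$,
* Marshallian via Slutsky: $e^M_{ij} = e^H_{ij} - e_i w_j$.

The derivative of implicit utility is computed exactly. Differentiating the
identity $y\,(1-\tfrac12 p'Bp) = \ln x - w'p + \tfrac12 p'Ap$ at fixed
prices, and letting the shares feed back through the Stone deflator, gives

$$\frac{dy}{d\ln x} = \frac{1}{1 - \tfrac12 \ln p'B\ln p + \mu'\ln p}.$$

The feedback term $\mu'\ln p$ is absent from the usual shorthand
$1/(1-\tfrac12 p'Bp)$ (the two coincide at the base point $\ln p = 0$). It
is retained here because it is what makes the analytic formulas agree with a
finite-difference oracle that perturbs prices and expenditure and re-solves
the share fixed point (`fd_oracle_elasticities()`): with the exact form the
two routes agree to ~1e-8; with the shorthand they differ at the order of
$\mu'\ln p$, far above discretisation error. All aggregation identities —
Engel $\sum_i w_i e_i = 1$, Cournot $\sum_i w_i e^M_{ij} = -w_j$,
homogeneity $\sum_j e^M_{ij} + e_i = 0$, Slutsky — hold exactly for any
scalar $dy/d\ln x$, so they are tested as machine-precision invariants
independently of this choice.

Both compensated and uncompensated matrices are always computed and stored
side by side, with the Marshallian matrix as the headline (demand responses
at fixed total expenditure are what a levy simulation needs).

`average_elasticities()` averages point elasticities over household-quarters
(default) or evaluates once at weighted means. A household-quarter enters
group i's average only if its *observed* share of i is positive — a zero
share admits no finite quantity elasticity — while the shares entering the
formulas are the *fitted* shares by default: near-zero observed shares put
$1/w_i$ on explosive footing, fitted shares do not. Exclusion counts are
reported in `eval_info`. Observed-share evaluation is available via
`share_source = "observed"`.

Standard errors come from the delta method: the gradient of each averaged
elasticity with respect to the stacked coefficient vector is taken by
central finite differences (relative step 1e-6), with the averaging mode
applied inside the differentiated functional, so the SEs correspond exactly
to the reported averages. Against a 200-replicate household-cluster
bootstrap the delta SEs for averaged own-price elasticities agree within a
factor of two. In Monte-Carlo recovery runs the 95% intervals cover the
generator truth at close to nominal rates.

## Price indices

Unit values (spend over quantity, aggregated to household-quarter × brand by
total spend over total quantity) are the observed prices. Missing cells —
a household-quarter bought none of a brand — are imputed per group by a
linear regression of *log* unit value on quarter, province, LSM and brand
indicators over observed cells, with collinear columns dropped; predictions
are exponentiated into the gaps and observed cells are never altered. Log
rather than level scale is a package choice (multiplicative price variation;
a `log_scale` switch exposes the alternative). With no usable covariates the
prediction degenerates to the geometric mean.

`fisher_index()` then builds, per household-quarter and group, Laspeyres and
Paasche indices over the group's brands with base prices and quantities at
their sample means (unweighted means over observed cells, computed once and
stored with the table), and takes their geometric mean. For a
household-quarter with no purchase in the group the Paasche weights fall
back to the base quantities, so the index reduces to its Laspeyres form —
this keeps a price defined for every observation, which the demand system
requires. Brands never purchased in-sample have no base quantity and are
excluded. The kernel satisfies the textbook identities (base identity,
λ-homogeneity, mean-value bounds, time reversal) to machine precision.

## The synthetic generator

`make_dgp()` builds a ground-truth system anchored so that at the reference
point (log prices 0, reference log expenditure, reference demographics) the
shares equal the requested means, and — when the price matrix is not
supplied — the own-price and expenditure elasticities at that point hit the
requested targets, with symmetric random off-diagonals. `dgp_table2()`
calibrates the 13-group version to published full-sample descriptives:
unconditional mean budget shares of roughly (0.4, 1.2, 0.7, 6.5, 3.7, 4.0,
0.6, 5.0, 2.0, 3.2, 3.0, 5.5, 64)% and non-purchase rates of roughly (74,
60, 71, 15, 28, 24, 76, 67, 43, 26, 24, 17, 0.5)%. Because non-purchase is
imposed by thinning *after* share generation (zeroed share moved into the
numeraire), the preset anchors the conditional-on-purchase shares at
$w/(1-P(w=0))$; the identity $w = (1-P(w{=}0))\,E[w|w>0]$ then lands the
unconditional means on the published column mechanically, and the package
verifies it to 1e-12 on every simulated panel.

`simulate_panel()` draws demographics matching the published sample
composition (LSM split, five life-cycle stages, eight provinces, household
size), an unbalanced presence pattern (Bernoulli presence per quarter,
default 0.4 — the median household contributes roughly 5 of 13 quarters),
brand-level log prices as base + quarter + province + quarter×province +
idiosyncratic components (SDs 0.05/0.05/0.04/0.1), expenditure around
ZAR 3000 per quarter, and solves the share fixed point per household-quarter
(damped iteration, damping 0.5, tolerance 1e-10, maximum 500 iterations).
Share noise is additive Gaussian on the J−1 equations (numeraire absorbs the
negative sum), clipped at zero and renormalised. Records are expanded per
positive group share with one or two brand draws and quantities implied by
spend over price; small fractions of Northern Cape households and
children-exceed-size anomalies exist purely to exercise the exclusion
filters.

Two generator choices deserve flags. First, the quarter×province price
component exists because a purely additive quarter + province price process
makes the model-level group indices *exactly* collinear with the quarter and
province fixed effects in the demand design — price coefficients would be
unidentified in the very specification the package defaults to.
Region-by-time price shocks are also what scanner data shows. Second, the
brand-level lognormal price model is a stand-in: nothing is known here about
the true empirical price distribution or brand granularity beyond
"group-brand elements", so record-level realism claims stop at the group
level.

What the generator does *not* emulate: censored (corner-solution) demand —
zeros come from thinning, not from a utility threshold, matching a linear
estimator applied to observed shares; panel recruitment and survey-weight
raking (weights are simple positive lognormal scalars); within-brand pack
heterogeneity. Passing tests therefore show the pipeline recovers the truth
*of this generating process*, not that the linear share model is correct for
real censored scanner data.

## Validation design and problem sizes

The test suite distinguishes two study systems, both fixed once:

* The 13-group preset exercises ingestion, descriptives, price indices and
  the end-to-end pipeline at 150–900 households over 4–13 quarters.
  Through the record-level chain, unit-value noise (SD 0.1) attenuates the
  price coefficients of thin groups; the preset is therefore validated on
  structure (audit conservation, share identities, round trips to 1e-8 or
  better) rather than sharp parameter recovery.
* Recovery, bias and interval-calibration checks use a 5-group system
  (shares 0.12–0.40, quadratic Engel curves, household-size and LSM
  shifters, share noise SD 0.02, no thinning) at about 5,000
  household-quarters and 20 Monte-Carlo seeds. The smallest mean share is
  six noise SDs above zero, so clipping is absent and the checks measure
  estimator properties, not censoring artefacts. Averaged own-price
  elasticity estimates are unbiased within Monte-Carlo resolution and
  delta-method intervals cover truth at roughly nominal rates.
* The stratified qualitative check scales the lower-LSM price matrix by 1.2
  and runs the two-stratum pipeline at 12,000 households (about 62,000
  household-quarters): the per-stratum own-price contrast of roughly 0.1 is
  then several estimation SEs wide, so the recovered ordering (lower-LSM
  more price-elastic) is stable rather than a coin flip.

Numerical edge handling, in one place: the share solver raises a singularity
error when the implicit-utility denominator comes within 1e-6 of zero and a
convergence error (with the residual trace) beyond 500 iterations; design
columns that collapse in a subsample (an absent dummy level, or a saturated
one collinear with the intercept) are pruned before fitting, and any
remaining rank deficiency is an error naming the columns; zero-total-spend
household-quarters are dropped with a count; the 5-SD unit-value filter uses
one-pass statistics computed before any dropping, so it is order-independent
but deliberately conservative in tiny samples (a single wild cell inflates
its own group SD — with k well-behaved cells the largest attainable
deviation is $k/\sqrt{k+1}$ SDs, so external statistics are the only way to
flag outliers in toy-sized groups).

## Known limitations

Zeros are thinned, not censored, so the package cannot speak to selection
into purchase; the block-diagonal system covariance understates
cross-equation dependence (though with a common design per equation the
point estimates are unaffected); `y` is recomputed from observed shares,
whose noise enters the Stone deflator — with the noise levels studied here
no detectable bias results, but the interaction is not corrected for; and
record-level price measurement error attenuates price coefficients, which is
visible in the 13-group worked example and intrinsic to unit-value-based
indices rather than to this implementation.
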