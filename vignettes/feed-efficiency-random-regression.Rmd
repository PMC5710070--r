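---
title: "Random-regression models for residual feed intake: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression models for residual feed intake: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Feed is the dominant cost of pig production, and residual feed intake (RFI)
— the deviation of an animal's feed intake from the intake predicted by its
production and maintenance needs — is the classic criterion for selecting
more efficient animals. The classic RFI model corrects feed intake for needs
estimated *at the group level*: fixed regressions of weekly feed intake (FI,
g/d) on standardized metabolic weight (MW, a maintenance proxy equal to body
weight^0.75), weight gain (WG) and backfat gain (FG), nested within week.

`rrfi` implements a family of random-regression animal models that extend
this definition with *animal-specific* needs: each animal carries additive
genetic and permanent environmental regressions on MW, WG and FG, in
addition to genetic and permanent intercepts. The intercept then measures
unspecific efficiency (consumption beyond individual needs), while the
slopes measure the feed cost per standard-deviation unit of each biological
function — maintenance, growth, fat deposition — for that animal.

## The eight models

For the feed intake `y` of animal `i` in week `j`, batch `k`, pen `l`:

```
y_ijkl = BA_jk + MW*beta1_j + WG*beta2_j + FG*beta3_j        (fixed)
       + b_l + MW*g1_jk + WG*g2_jk + FG*g3_jk                (pen, batch-week)
       + a_1i [+ MW*a_2i] [+ WG*a_3i] [+ FG*a_4i]            (genetic)
       + p_1i [+ MW*p_2i] [+ WG*p_3i] [+ FG*p_4i]            (permanent)
       + e_ijkl
```

Model codes 1–8 select which bracketed animal slopes are present
(`model_spec()`): 1 none (classic RFI), 2 MW, 3 WG, 4 FG, 5 MW+WG, 6 MW+FG,
7 WG+FG, 8 all three. The `k` animal effects are correlated: the genetic
vector has covariance `G0 (x) A` (A the pedigree numerator relationship
matrix), the permanent vector `P0 (x) I` over animals with records. Pen,
batch-week regressions and the residual are homoscedastic and independent.
Covariates are standardized to mean 0, sd 1 *within week-by-batch cells*
(sample sd, divisor n-1), so slopes are comparable across functions and
evaluated "at the mean" means at zero.

## Estimation

`gibbs_sample()` draws all location effects from univariate normal full
conditionals (single-site updates with residual bookkeeping, in C++),
scalar variances from scaled inverse chi-square full conditionals, and
`G0`/`P0` from the inverse-Wishart full conditionals implied by flat
(bounded uniform) priors, with degrees of freedom `q - k - 1` so that the
prior density over the matrix is constant; draws beyond the prior bound
(`var_max`, default very wide) are rejected and redrawn. With flat priors
this requires at least three levels per scalar variance and `q > 2k` levels
for the matrices, which every realistic layout satisfies.

The default chain protocol is a desk-scale one — 50,000 iterations, 10,000
burn-in, thinning 10, 2 chains — chosen so a full fit of Model 8 to roughly
20,000 weekly records runs in a few minutes on one core; the protocol used
for a full analysis (10^6 iterations, 10^5 burn-in, thinning 100, 4–5
chains) is available through `chain_config()`. Methods and results sections
of analyses with this model family have used both four and five chains; the
chain count is a free parameter here and all summaries merge chains
(effective sample size is summed per chain, by the initial-positive-sequence
autocorrelation estimator, which is assumption-light for reversible chains).
Highest-posterior-density intervals are the shortest interval containing the
stated mass.

`dic()` uses the *conditional* deviance (normal likelihood of the data given
all location effects and the residual variance), the convention of the
Gibbs-sampling software family this analysis style comes from, so the
penalty `p_D` counts the effective number of location parameters. Model
comparison contrasts DIC differences with the across-chain DIC range.

`em_reml()` implements expectation–maximization REML on the mixed-model
equations (effect solutions plus blocks of the inverse coefficient matrix
drive the variance updates); the coefficient matrix is inverted densely, so
it is intended for desk-scale systems (a warning is issued above 4000
equations). Its REML log-likelihood trace is non-decreasing, which the test
suite checks, and on balanced one-way layouts it reproduces the closed-form
REML estimates exactly. `predict_breeding_values()` solves the same
equations by sparse Cholesky at fixed components, which scales to the
simulator's nucleus (tens of thousands of equations).

## Derived genetic parameters

With slopes evaluated at the covariate means (zero), the intercept
heritability is `G0[1,1] / (G0[1,1] + P0[1,1] + var_pen + var_e)`; slope
"heritabilities" are additive-to-(additive+permanent) ratios, the
convention for these allocation components. `h2_at_covariate()` moves along
one covariate: genetic variance `G0[1,1] + 2x G0[1,j] + x^2 G0[j,j]`, the
permanent analogue, and a phenotypic denominator that adds pen and residual
variances. The batch-week regression variances are treated as environmental
context and excluded from the denominator at all `x`, matching the
intercept definition (which lists additive, permanent, pen and residual
only); whether a published phenotypic variance at `x != 0` includes them is
not documented, and this is the conservative, internally consistent choice.
Draw-wise summaries (`posterior_genetic_summary()`) apply the functional to
every retained draw and then summarize, so differences such as
`h2(-0.75) - h2(+0.75)` are posterior summaries of differences.

## Reconstructing the Model 8 generating components

The published record of this model family prints ratios and sums, not full
matrices: the intercept additive+permanent sum (21,010 (g/d)^2 under the
full model, 33,531 under the classic one), the intercept heritabilities
(0.12 full, 0.18 classic), slope ratios (0.44, 0.39, 0.55), the genetic
correlation matrix, and the permanent intercept–slope correlations (0.48,
-0.79, -0.74). `reconstruct_model8_components()` resolves a complete,
positive-definite `G0`/`P0`/`var_pen`/`var_e` satisfying all of them
simultaneously:

* the total slope variance is the 12,521 (g/d)^2 drop between the two
  models' intercept sums, split across MW/WG/FG by an allocation rule. The
  default is an **equal split**: weights proportional to the squared mean
  fixed regressions (235^2, 64^2, 33^2) would put 91% of the slope variance
  on MW and 2% on FG, which contradicts the model-comparison evidence that
  the WG component is the strongest single animal-specific term and would
  make the WG/FG slopes numerically unidentifiable at test scale. The
  `beta2` and `gamma`-weighted alternatives remain selectable, and the
  resolved numbers are recorded in the `provenance` attribute (and a file on
  request).
* the residual is solved, not guessed: with `var_pen = 0.05 var_e`, the
  pen+residual sum is the unique value making the intercept heritability
  0.12 under the full model *and* the implied classic-model heritability
  0.18 (slope additive variance absorbed into the intercept at unit
  covariate variance). This gives `var_e ~ 35,639`, `var_pen ~ 1,782`,
  `G0[1,1] ~ 7,012` (g/d)^2.
* permanent slope–slope correlations are completed by a one-factor rule
  `r(j,l) = r(1,j) r(1,l)`, which is provably positive definite for the
  given loadings; the genetic correlation matrix is positive definite as
  printed. Any marginally indefinite input (the printed pen covariance of
  the covariate traits, determinant ~ -2e-5, is one) is repaired by
  eigenvalue clipping and flagged.

## The selection simulator

`run_scenario()` emulates a small selection nucleus: 120 sows and 30 boars;
matings avoid pairs with additive relationship >= 0.25; litter sizes are
N(9, 6) rounded and truncated at zero; juvenile mortality/culling removes
20% before the end of growing; sows farrow up to six parities with Weibull
stochastic culling (shape 2, scale 3.667, making ~80% of sows survive each
early parity transition — the Weibull family is given, its parameters are a
package choice). Offspring of parities 1–2 are selection candidates;
later-parity offspring contribute records to the next generation's
evaluation, so each evaluation uses the roughly 2,000 animals whose records
became available that generation. Survivors are penned in groups of 10
filled in litter order (litter mates stay together, as at weaning), pen
effects drawn fresh per pen.

Feed intake is generated from the Model 8 structure with mean 3,000 g/d and
overall regressions (235, 64, 33) g/d per sd unit, ignoring batch and age
patterns; the weekly standardized covariates come from a three-trait
pen + additive + permanent + weekly-residual decomposition with the printed
covariance matrices. Offspring breeding values follow the Mendelian rule
`0.5(a_s + a_d) + N(0, 0.5 G0)`; parental inbreeding is ignored in the
sampling variance because three-generation pedigrees from a base of 150
founders accumulate very little of it.

Six selection indexes rank candidates by negative predicted breeding
values: raw feed intake (animal model without the covariate regressions),
classic RFI (Model 1), animal-specific RFI (Model 8 intercept), and the
three Model 8 slopes; a `random` scenario is a null control. The best 120
females are truncation-selected; the single best male per sire family is
kept. Selection intensity is realized on the predicted-breeding-value scale
(negative when selecting to decrease) and reported per sex; the headline
intensity of a scenario is the female-pathway value, which carries 120 of
the 150 selections — the published male-candidate accounting is not fully
specified, and the literal best-per-sire-family rule selects only ~4% of
males. Evaluation accuracy is the correlation between true and predicted
index values over all candidates. Responses are per-generation changes in
cohort mean true breeding values. Scenario-level selection metrics average
over the generations after the first: the first evaluation sits on an
unselected founder base without ancestral records, so its accuracy is a
start-up transient, and the later rounds reflect the scheme's operating
accuracy under ongoing selection.

Evaluation modes: `true_components` (BLUP at the generating components;
fast, and the default for structure statistics), `gibbs_reestimate`
(components re-estimated each generation and replicate from a short Gibbs
run, emulating per-generation re-estimation at a scale where dense EM-REML
is impractical), and `reml_reestimate` (EM-REML; desk-scale configurations
only). With true components the evaluation is free of
component-estimation error, so accuracies sit somewhat above what
re-estimated analyses report.

## Synthetic observational data

`simulate_weekly_dataset()` generates litter-structured pedigrees (sires by
dams by litter size per batch), weekly standardized covariates from the
same three-trait decomposition, and feed intake from the full model with
week-varying fixed regressions (the published weekly posterior means are
the defaults), batch-week random regressions at the printed variances
(2,329, 1,166, 328), and batch-level shifts. The raw-scale columns
(`mw_raw` etc.) de-standardize the latent covariates with week-level means
and sds patterned on the descriptive statistics of real 15–25-week records.

`generate_observational_dataset()` then disaggregates to the raw inputs the
preparation pipeline consumes: daily intake is the weekly mean plus
zero-sum daily noise (preparation only uses weekly means, so the daily
dialect is immaterial; the zero-sum choice makes the round trip exact when
no days are missing), with a configurable fraction of days knocked out;
weight and backfat events sit on a per-week linear schedule whose midpoints
and endpoint differences are pinned to the weekly raw covariates. With
events on every weekly boundary day the preparation pipeline recovers the
weekly records exactly; with 4–11 randomly placed events (the realistic
density) recovery is approximate, which is what the tests assert. These
fixtures emulate the *structure* of observational data — they do not
emulate feeder-level meal validation, diet changes, or drop-out patterns,
so passing recovery tests demonstrates correctness of the pipeline and
estimators, not robustness to real-data artefacts.

The central recovery property — generate from known components, run the
pipeline, fit Model 8, recover the generating ratios — is exercised at
fixtures of 2 batches x 30–45 sires x 5 dams x 5 offspring with phenotyped
founders (1,860 animals in the test suite, 2,790 in the reproduction
script), sizes chosen from pilot precision runs so that the posterior-mean
intercept heritability has a standard error near 0.01 and the backfat
slope ratio near 0.03–0.05 across fixture realizations, while two
50,000-iteration chains complete in a few minutes.

## Numerical choices and degenerate inputs

* Age axes for Legendre trajectory fits are rescaled to the animal's own
  observed range (fits are animal-nested); evaluation outside that range
  returns missing (no extrapolation). Fewer distinct ages than coefficients
  is an error naming the animal.
* Standardization cells need at least two records and nonzero sd; both are
  errors, since a silent fallback would leak raw scales into the design.
* "Seven or more pen mates" is read literally as group size >= 8 (the
  animal plus seven others); the threshold is an argument.
* Metabolic weight uses the mean of the weekly endpoint weights before the
  0.75 power (the weekly summaries label MW the mean metabolic weight of
  the week); the endpoint alternative is a one-line change in
  `derive_weekly_covariates()`.
* Ties in truncation selection break by animal id, making selection
  deterministic given the index.
* EM-REML adds a floor of 1e-10 relative units to the covariance diagonals
  per iteration so boundary estimates (a true zero variance) converge to
  the boundary without singular factorizations.

## Known limitations

Genetic groups for unknown parents, heterogeneous residuals, maternal
effects, marginal-likelihood model comparison and genomic relationship
matrices are out of scope. EM-REML is dense and desk-scale by design. The
simulator's unspecified corners (Weibull parameters, pen size, the close-
relative threshold, full boar replacement each generation) are package
choices, configurable and logged, and the male selected-proportion
accounting of published tables is not reproducible from the stated rules
alone.
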