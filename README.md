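# rrfi — random-regression models for residual feed intake

Feed is the largest variable cost of pig production, and residual feed
intake (RFI) — observed feed intake minus the intake predicted from an
animal's maintenance and production needs — is the classic selection
criterion for feed efficiency. The classic RFI model estimates those needs
at the *group* level, through fixed regressions of weekly feed intake on
standardized metabolic weight (MW = BW^0.75), weight gain (WG) and backfat
gain (FG). `rrfi` implements a family of eight nested random-regression
animal models that make the needs *animal-specific*: every animal carries
additive-genetic and permanent-environmental intercepts **and** regressions
on MW, WG and FG,

    y = BA_jk + MW b1_j + WG b2_j + FG b3_j            (fixed, week-nested)
      + pen + MW g1_jk + WG g2_jk + FG g3_jk           (batch-week random)
      + a_1 + MW a_2 + WG a_3 + FG a_4                 (genetic,   cov G0 ⊗ A)
      + p_1 + MW p_2 + WG p_3 + FG p_4                 (permanent, cov P0 ⊗ I)
      + e,

so the intercept measures unspecific efficiency (feed beyond individual
needs) and each slope the feed cost per sd unit of one biological function.
The package is aimed at quantitative geneticists working on feed
efficiency: it covers pedigree relationship algebra (A, its sparse inverse,
inbreeding), weekly phenotype preparation from raw daily feed intake and
weighing events, Bayesian estimation by Gibbs sampling with DIC model
comparison, EM-REML and BLUP, derived genetic parameters (heritabilities,
slope variance ratios, conditional heritability along a covariate), a
stochastic breeding-program simulator comparing six selection indexes, and
a synthetic-data generator with known truth.

## Worked example

Generate a synthetic observational dataset, prepare weekly records, and fit
the full model:

```r
library(rrfi)

cfg <- fixture_config(seed = 7)              # 2 batches x 160 pigs, weeks 15-25
obs <- generate_observational_dataset(cfg)
weekly <- prep_weekly(obs$daily, obs$events, obs$assignments)

sys <- build_design_system(weekly, model_spec(8), pedigree = obs$weekly$pedigree)
fit <- gibbs_sample(sys, chain_config(n_iter = 50000, burn_in = 10000,
                                      thin = 10, n_chains = 2, seed = 1))
posterior_genetic_summary(fit, heritability_intercept)
```

```
mean 0.1145  median 0.1084  sd 0.047  HPD95 [0.02971, 0.208]  Pr(>0) 1.00  ESS 153
```

The fixture was generated with an intercept heritability of 0.12, so the
posterior concentrates in the right place: the mean of
`G0[1,1] / (G0[1,1] + P0[1,1] + var_pen + var_e)` across retained draws is
0.114 with a 95% highest-posterior-density interval of (0.03, 0.21) — 320
phenotyped animals is a small dataset, hence the width. `dic(fit)` compares
models: on this dataset, generated under the full model, Model 8 scores
47164 against 47402 for the classic Model 1 refitted to the same records.
`genetic_parameter_table(fit)` mirrors the usual summary layout (mean,
median, sd, HPD, Pr(>0), ESS per parameter).

The selection simulator reproduces the published nucleus structure (120
sows, 30 boars, N(9,6) litters, 20% juvenile loss, candidates from the
first two parities):

```r
res <- run_scenario(sim_config(n_replicates = 5, scenario = "RFI", seed = 1))
res$metrics[c("intensity_f", "proportion_f", "accuracy")]
```

```
intensity_f proportion_f     accuracy
 -1.5390959    0.1553204    0.6832263
```

Selecting against the Model 8 intercept reduces true RFI and total feed
intake per generation (`res$response`), with favourable correlated
responses in feed per unit of growth and backfat gain and an unfavourable
one in feed per unit of maintenance — the signature pattern of this model
family.

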