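# hdtvpp

Decision-making processes behind *how much* children eat: `hdtvpp`
implements the computational core of a study design linking
reinforcement-learning parameters of the Hungry Donkey Task (HDT, the
child-friendly Iowa Gambling Task) to laboratory energy intake and weight
status (BMI-z) in middle childhood. It is aimed at researchers in eating
behaviour and developmental decision-making who want to simulate,
estimate and analyse this pipeline end-to-end, or run its analysis stages
on their own trial-level and phenotype tables.

## What it computes

**Task.** Four doors; A/B pay 4 apples with heavy scheduled losses (−1
apple/trial in expectation), C/D pay 2 with light losses (+1
apple/trial). `canonical_schedule()` fixes the within-block loss
positions reproducibly.

**Model.** The Value-Plus-Perseveration (VPP) model values door *j* as

    V_j = w * EV_j + (1 - w) * P_j,      P(choose j) ∝ exp((3^c - 1) V_j)

where the expected-value term learns by a delta rule with rate ø on the
prospect-style utility `u = x^α` (gains) / `-λ|x|^α` (losses), and the
perseveration term decays by *k* each trial and is incremented by ε_pos
after net gains and ε_neg after net losses. Per-subject parameters are
estimated by MAP over an unconstrained parameterisation with a
cohort-calibrated empirical-Bayes prior (the single-subject analogue of
hierarchical shrinkage); `recovery_experiment()` quantifies how well
truth is recovered.

**Behavioural metrics.** Netscore `(C+D) − (A+B)`, win-stay and
lose-shift with "win" defined on the net outcome (net ≥ 0).

**Statistics.** Spearman/Pearson matrices, Mann-Whitney-Wilcoxon,
Kruskal-Wallis, and Benjamini-Hochberg adjustment within test families.

**Path models.** Six recursive two-equation systems (expected-value and
perseveration parameter sets × standard meal / eating-in-the-absence-of-
hunger / buffet): intake (kcal/100) on standardised parameters (log-λ;
optional k×ε_neg interaction and covariates), BMI-z on intake. Indirect
effects as coefficient products with Sobel SEs and bootstrap percentile
intervals; T/RMSEA/CFI/SRMR fit indices; simple-slope moderation probes;
exclusion filters with audit logs.

**Synthetic cohorts.** `draw_params()` matches published parameter
quartiles; `simulate_phenotypes()` generates intake and BMI-z from the
published path coefficients with residual SDs matched to the published
R²; `simulate_hdt_cohort()` plays full 200-trial sessions.

## Worked example

Simulate a 70-child cohort, fit the standard-meal perseveration path
model, and extract the indirect effect of the gain-perseveration
increment on BMI-z through intake:

```r
library(hdtvpp)

pars   <- draw_params(70, seed = 42)
trials <- simulate_hdt_cohort(pars, n_trials = 200, seed = 43)
pheno  <- simulate_phenotypes(pars, seed = 44)

summary(behavior_metrics(trials)$netscore)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -198.000  -59.000  -14.000   -6.457   19.000  178.000

spec <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
mm   <- preprocess(merge(pars, pheno, by = "subject_id"), spec)
fit  <- fit_path_model(mm, spec)
fit
#> Recursive path model (n = 70)
#>              equation                 term estimate    se        p
#>  intake_standard_kcal          (Intercept)    6.262 0.280 8.01e-33
#>  intake_standard_kcal              eps_pos    1.109 0.283 2.07e-04
#>  intake_standard_kcal                    k    0.094 0.283 7.41e-01
#>                 bmi_z          (Intercept)   -0.307 0.280 2.78e-01
#>                 bmi_z intake_standard_kcal    0.219 0.041 1.49e-06
#> R-squared: intake_standard_kcal = 0.191, bmi_z = 0.290

indirect_effect(fit, c("eps_pos", "intake_standard_kcal"),
                c("intake_standard_kcal", "bmi_z"))[c("estimate", "se", "p")]
#> $estimate [1] 0.2425  $se [1] 0.0774  $p [1] 0.00172
```

Reading the output: a 1 SD increase in the gain-perseveration increment
predicts a 111 kcal increase in standard-meal intake in this particular
simulated cohort (the generating value is 88 kcal; n = 70 estimates
scatter around it), each 100 kcal of intake predicts a 0.22 higher BMI-z,
and the product — the mediated association of ε_pos with weight status —
is 0.24 BMI-z units per SD. Fit indices (`fit_indices(fit, mm)`) show the
model is consistent with the simulated covariance structure (here T =
0.29 on 2 df, RMSEA = 0, CFI = 1, SRMR = 0.016). The whole chain,
including MAP fitting of the simulated sessions and sensitivity variants,
runs via `run_pipeline(pipeline_config(n_subjects = 70, seed = 1))`.

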