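---
title: "Modelling Hungry Donkey Task decision processes and their relation to intake and weight status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Hungry Donkey Task decision processes and their relation to intake and weight status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdtvpp)
```

## Scope

`hdtvpp` implements a complete analysis chain for studying decision-making
processes in children's choice behaviour on the Hungry Donkey Task (HDT)
and their downstream relations to laboratory energy intake and weight
status (BMI-z):

1. the HDT payoff environment (four doors, scheduled losses);
2. the Value-Plus-Perseveration (VPP) reinforcement-learning model —
   simulation, sequence likelihood, per-subject MAP estimation, and
   parameter-recovery experiments;
3. classical behavioural metrics (netscore, win-stay, lose-shift);
4. nonparametric association statistics with Benjamini–Hochberg
   adjustment;
5. a synthetic cohort generator (decision parameters, HDT sessions,
   intake/BMI-z phenotypes);
6. recursive path models with product-of-coefficients indirect effects,
   moderation probing, bootstrap uncertainty, and covariance-based fit
   indices.

Everything runs on synthetic cohorts by default but every analysis
function accepts user-supplied tables in the documented CSV layouts.

## The task environment

Each HDT trial opens one of four doors. Doors A and B pay 4 apples on
every selection, C and D pay 2. Losses are scheduled per door: over any
10 selections of a door, A loses 50 apples in magnitudes {8, 10, 10, 10,
12}, B loses 50 in a single hit, C loses 10 in magnitudes {1, 2, 2, 2, 3},
and D loses 10 in a single hit. Expected net yield is therefore −1
apple/trial on A and B and +1 on C and D, which is what makes A/B
"disadvantageous" and C/D "advantageous". Only the loss *magnitudes* are
fixed by the task description; the positions of losses within a block are
a pseudo-random permutation frozen at schedule construction
(`canonical_schedule(schedule_seed = 101)`), and outcomes are indexed by
the per-door selection count (deck-indexed), following the Iowa Gambling
Task convention. Both choices are configurable, and all schedule-level
facts above are asserted by the test suite.

## The Value-Plus-Perseveration model

The model values each door $j$ as a weighted average of an expected-value
learner and a perseveration heuristic,

$$V_j(t) = w\,EV_j(t) + (1 - w)\,P_j(t),$$

and chooses by softmax with sensitivity $\theta = 3^{c} - 1$:

$$\Pr(\text{choose } j \mid t) =
  \frac{e^{\theta V_j(t)}}{\sum_m e^{\theta V_m(t)}}.$$

The EV term learns from the utility of the net outcome $x(t)$,

$$u(t) = \begin{cases} x(t)^{\alpha} & x(t) \ge 0 \\
  -\lambda\,|x(t)|^{\alpha} & x(t) < 0 \end{cases},
  \qquad EV_j(t{+}1) = EV_j(t) + \phi\,(u(t) - EV_j(t))$$

for the chosen door only. The perseveration term decays every door by $k$
each trial and then increments the chosen door by $\varepsilon_{pos}$
after a net gain ($x \ge 0$) or $\varepsilon_{neg}$ after a net loss
($x < 0$):

$$P_j(t{+}1) = k\,P_j(t) + \mathbb{1}[j = \text{chosen}]\,
  (\varepsilon_{pos}\ \text{or}\ \varepsilon_{neg}).$$

Both state vectors start at zero. Parameter supports are $\phi, \alpha,
k, w \in (0,1)$, $\lambda, c \in (0,5)$, and $\varepsilon_{pos},
\varepsilon_{neg} \in \mathbb{R}$. Published cohort tables place
$\varepsilon$ values far outside $(-1, 1)$ (median $\varepsilon_{neg}$
near −6.5), so the increments are treated as unbounded reals.

Numerical notes: the softmax is computed with a max-shift (log-sum-exp),
so extreme values cannot overflow; the decay-then-increment order makes
$k = 0$ mean "complete decay of the past" while the current increment
survives; utility is computed on the net outcome, matching the gain/loss
definition of the perseveration rule; the sequence log-likelihood scores
each recorded choice against the state *before* the trial and then
updates the state with the recorded outcome. The likelihood inner loop is
compiled (Rcpp); the R-level simulator (`simulate_session`) performs the
same rollout independently and records its own log-probabilities, and the
two routes are required to agree to 1e-10 in the tests.

## Estimation: per-subject MAP with a cohort-calibrated prior

Child-specific point estimates are obtained by maximum a posteriori
estimation: the sequence log-likelihood plus a log-prior is maximised
over an unconstrained parameterisation (scaled logit for the bounded
parameters, identity for the $\varepsilon$s) by BFGS from `n_starts = 10`
prior-drawn initialisations (relative tolerance 1e-8), and the best
optimum is mapped back.

The default prior (`vpp_prior()`) is an empirical-Bayes prior: normal on
each unconstrained coordinate with the moments of the cohort-calibrated
generator distribution (next section) mapped to that scale. This choice
is deliberate. The VPP likelihood for a 200-trial session leaves a
near-flat trade-off between the expectancy weight $w$ and the scale of
the perseveration increments (only $(1-w)\varepsilon$ is strongly
identified); under a diffuse prior, MAP estimates drift along this ridge
($w$ collapsing towards 0.4 and $\varepsilon_{neg}$ compressing towards
zero), and rank recovery of $\varepsilon_{neg}$ and $c$ degrades
markedly. A hierarchical Bayesian fit resolves this with group-level
shrinkage; the calibrated prior is the single-subject analogue of that
device. We verified that the optimiser is not the limiting factor (MAP
optima dominate the true generating values in every check) and that an
importance-sampled posterior-mean estimate offers no material gain over
the mode. A diffuse prior remains one argument away:
`vpp_prior(mean = rep(0, 8), sd = c(1, 1, 1, 5, 5, 1, 1, 1))`.

Sessions whose best log-likelihood is within 5 units of the uniform-choice
value $n \ln(1/4)$ — the chance-level overfit scale for eight free
parameters — are flagged `near_uniform`: their estimates are
prior-dominated, as for random responders with $c \approx 0$.

`recovery_experiment()` packages the simulate–fit–correlate loop. Under
the default conditions (100 subjects × 200 trials), rank correlations
between true and estimated values are roughly 0.9 for $\phi$, 0.95+ for
$\varepsilon_{pos}$, 0.7 for $c$ and $k$, and 0.5–0.7 for
$\varepsilon_{neg}$ (seed-to-seed variability is substantial for the
latter); with 2000-trial sessions every bounded parameter's RMSE shrinks
further, while the $\varepsilon$ increments retain a prior-shrinkage bias
floor.

## The synthetic cohort

`draw_params()` draws decision parameters independently from marginals
calibrated so that large-sample quartiles reproduce the published cohort
quartiles: Beta marginals for $\phi$, $\alpha$, $k$, $w$ (and a scaled
Beta for $c$), a log-normal truncated below 5 for the strongly
right-skewed $\lambda$, and normals for the $\varepsilon$s. Where a
two-parameter family cannot match all three printed quartiles (e.g.
$\phi$), the 25th/75th percentiles are matched and the median lands
inside the printed interquartile band. Skewed location families
($\lambda$, $\varepsilon$s) are centred at the quartile midpoint so both
printed quartiles match. Parameters are drawn independently; the
generator does not attempt to reproduce the published between-parameter
correlations, so tests of the correlation *machinery* use it, but no test
asserts those correlation values.

`simulate_phenotypes()` generates the three intake phenotypes on the
kcal/100 scale as linear functions of the *standardised* perseveration
parameters plus Gaussian noise, with the published unstandardised path
coefficients as defaults (standard meal: $\varepsilon_{pos}$ 0.88, $k$
−0.12; EAH: 0.40, −0.55, $\varepsilon_{neg}$ −0.45 and the
$k \times \varepsilon_{neg}$ interaction 0.89; buffet: 1.36, 0.12,
−0.07), intercepts anchored at the published mean intakes (643.9, 379.9,
1271.3 kcal) and residual SDs chosen so the population $R^2$ of each
equation approximates the printed values (0.17, 0.25, 0.14). BMI-z is
generated from a single *designated* paradigm's intake (default: the
standard meal, $b = 0.15$, residual SD 0.919 matching $R^2 = 0.11$).
Designating one driver is a deliberate simplification: it makes the
conditional-independence assumption of the path models (given intake,
BMI-z carries no further information about the decision parameters) hold
exactly, at the cost that only the designated paradigm's b-path equals
its published value — analyses of another paradigm should designate it
instead, e.g. `structural_spec(bmi = list(paradigm = "buffet", coef =
0.07, resid_sd = 0.817))`. Intakes are truncated at zero (a rare event,
\>3 SD, under the defaults). Covariates are drawn from documented ranges
(age truncated-normal 9.5 ± 1.4 on 7–12 y; fullness truncated-normals on
the 0–150 mm scale with the published paradigm means/SDs; compliance
flagged at rate 3/70).

What the generator does *not* emulate: correlations among decision
parameters, non-Gaussian intake residuals, measurement error in intake,
or any age/sex structure in the decision parameters. Passing tests
therefore demonstrate that the estimation and path-analysis machinery
recovers known structure under clean conditions, not that it would be
unbiased under every violation real data can present.

## Path models

Each of the six models (expected-value and perseveration parameter sets ×
three paradigms, `default_model_specs()`) is a two-equation recursive
system: intake regressed on parameters (plus optional interaction and
covariates), and BMI-z regressed on intake alone. Preprocessing z-scores
the parameter predictors on the analysis sample (after a natural-log
transform of $\lambda$, whose raw skewness/kurtosis fail the |skew| > 2
or |excess kurtosis| > 7 screen), scales intake to kcal/100, and forms
interactions as products of the standardised components without
re-standardising the product. Missing data are handled by listwise
deletion; z-scoring is redone within each (sensitivity) analysis sample.

Because the system is recursive with uncorrelated errors, equation-wise
least squares is the ML estimator; coefficients, conventional SEs and
$R^2$ come from the per-equation fits, and the intake→BMI-z coefficient
is identically the simple regression slope. Indirect effects are products
of the a- and b-paths with delta-method (Sobel) standard errors;
`bootstrap_uncertainty()` provides nonparametric case-resampling
percentile intervals for coefficients and indirect effects. Robust
(sandwich/Satorra–Bentler-style) corrections are out of scope; the
bootstrap addresses the same concern about non-normal residuals.

Fit indices compare the model-implied covariance matrix (exogenous
moments free; endogenous rows implied by the fitted paths and ML residual
variances) with the sample ML covariance matrix (denominator $n$):
$T = (n-1) F_{ML}$ with degrees of freedom equal to the number of omitted
direct exogenous→BMI-z paths, $\text{RMSEA} = \sqrt{\max(T - df, 0) /
(df\,(n-1))}$, CFI against the diagonal-covariance independence baseline,
and SRMR as the RMS standardised covariance residual. The $(n-1)$ scaling
is a documented convention choice, as is the use of *excess* kurtosis in
the normality screen. Free parameters for the 10:1 sample-size rule are
counted as structural path coefficients plus the two residual variances.

`moderation_probe()` evaluates simple slopes $B_{focal} +
B_{interaction} \cdot level$ at chosen moderator levels (on the
standardised scale) with delta-method SEs, reproducing the
decay-moderated association between loss-perseveration and
eating-in-the-absence-of-hunger intake when the generating interaction is
present.

## Association statistics

`spearman_matrix`, `mann_whitney`, `kruskal_wallis` and `bh_adjust` are
thin, fully specified surfaces over the corresponding base-R routines
(tie-corrected throughout), kept as module functions so the test suite
can hold them against independent brute-force oracles: rank-then-Pearson
for Spearman, exhaustive pair counting for U, a hand-computed ranks
statistic for H, the step-up definition for Benjamini–Hochberg, and a
Monte-Carlo global-null experiment for FDR control. `mann_whitney(...,
exact = TRUE)` enumerates all group assignments for small pooled samples.
The three published test families (28 pairwise parameter tests, 8 tests
per behavioural metric, 6 tests per parameter) are expressed through
`bh_adjust`'s `family` argument.

## Pipeline and reproducibility

`run_pipeline(pipeline_config(...))` chains simulate → fit → metrics →
descriptives → six path models (plus covariate-adjusted and
exclusion-filtered sensitivity variants) and optionally writes the CSV
bundle and a plain-text summary. One global seed derives fixed per-stage
child seeds (`seed + stage_index * 104729 mod 2^31 - 1`), so stages are
individually reproducible and two runs with the same configuration are
identical. Exclusion rules: non-compliant subjects, and pre-EAH fullness
strictly below 75% of the 150 mm scale (112.5 mm; a rating of exactly
112.5 is retained).

Problem sizes used by the shipped checks — 100 × 200 (and 30 × 2000)
sessions for parameter recovery, 500 cohorts of n = 70 with 200 bootstrap
replicates for path-coefficient recovery and interval coverage, n =
20,000 cohorts for the large-sample indirect effects, n = 10,000 for the
conditional-independence check — were chosen so each quantity's
Monte-Carlo error is small relative to the property being demonstrated.

## Known limitations

* MAP point estimates stand in for hierarchical posterior estimation; the
  calibrated prior imports cohort-level information into each subject's
  fit, which is the intended shrinkage but means single-subject estimates
  are not prior-free.
* $\varepsilon_{neg}$ is weakly identified at 200 trials because
  lose-shift behaviour saturates; its recovery is honest but noisy.
* The generator's independence assumptions (above) bound what recovery
  tests demonstrate about real cohorts.
* Fit indices use conventional ML statistics; with strongly non-normal
  observed variables their reference distributions are approximate, and
  the bootstrap intervals are the package's primary uncertainty
  statement.
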