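---
title: "Methods: multimorbidity networks and survey-weighted hospitalisation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimorbidity networks and survey-weighted hospitalisation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbinet)
```

`morbinet` analyses how chronic conditions cluster in over-50 cohorts and
how those clusters relate to hospitalisation, readmission and length of
stay. This vignette is the package's account of its methods: the models,
the tunable parameters, the synthetic-data generator that stands in for
restricted survey microdata, the numerical choices, and the limits of what
the tests demonstrate.

## 1. The estimation problem

The data are one rectangle: one row per subject; 19 binary morbidity
indicators; sociodemographic covariates; outcomes hospitalisation (yes/no,
past 12 months), readmission (number of admissions, defined only for the
hospitalised) and length of stay (days, last admission); and a complex
survey design (stratum, primary sampling unit, weight). Two families of
questions are asked of it:

* *Association*: how much more prevalent is hospitalisation among men, or
  among subjects with three or more conditions? These are design-based
  quantities: weighted prevalences with between-PSU variance, prevalence
  ratios from weighted Poisson models with cluster-robust variance, and β
  coefficients from weighted linear models.
* *Structure*: which conditions are conditionally associated with each
  other and with the outcome, controlling for all other conditions? These
  are graphical-model quantities: an Ising network over binary nodes, or a
  mixed graphical model when a count or continuous outcome joins, plus the
  analyses computed on the estimated network.

## 2. Survey-weighted estimation

`weighted_prevalence()` uses the Horvitz–Thompson ratio estimate
$\hat p = \sum w_i y_i / \sum w_i$. Variance comes from Taylor
linearisation with the usual with-replacement first-stage approximation:
linearised residuals $z_i = w_i (y_i - \hat p) / \sum w$ are summed within
PSUs, and each stratum contributes $n_h/(n_h - 1)$ times the scatter of
its PSU totals. The 95% interval is Wald on the logit scale and
back-transformed, which respects the (0, 1) range; a prevalence of exactly
0 or 1 returns a width-zero interval rather than an undefined one. A
stratum with a single PSU makes the variance undefined; the package
refuses by default (silent misestimation being worse than refusal) and
offers `single_psu = "collapse"` to pool lone-PSU strata explicitly.

`fit_poisson_pr()` estimates prevalence ratios by weighted log-link
Poisson regression — the standard device for PRs on binary outcomes in
cross-sectional data — via IRLS run to a relative deviance change below
1e-10 (at most 100 iterations). `fit_linear()` is weighted least squares.
Both report CR0 cluster-sandwich standard errors on PSUs with the weights
inside the meat, and Wald 95% intervals with z = 1.959964, exponentiated
to the PR scale for Poisson. Reference levels appear with effect 1 (PR) or
0 (β) and an empty interval; a covariate level with zero outcome events is
reported with an unbounded interval and a warning. With one observation
per cluster and unit weights the CR0 sandwich reduces exactly to HC0.
Small-sample cluster corrections (CR2/CR3) are deliberately out of scope.

Readmission and length of stay are modelled on the hospitalised subset
only: readmission is undefined for the never-admitted, and treating
structural absence as data would bias everything downstream.

Missing data are handled by IPW plus complete-case analysis, not by
imputation: `compute_ipw()` fits a logistic model of the complete-case
indicator on fully observed predictors and weights complete rows by
$1/\hat p(\text{complete})$. The final analysis weight is the survey
weight times the IPW multiplier; the composition rule is multiplicative —
the standard choice where no other is stated — and `weight_mode =
"design"` exposes the unadjusted alternative. A fully complete table gets
unit multipliers; a table with no complete rows is refused. Perfect
separation in the completeness model is detected (|linear predictor| > 15)
and refused with a diagnostic, since the resulting multipliers would be
unbounded.

The asset index is the first principal component of the standardised
block of 12 household asset variables, cut into weighted quintiles
(left-closed boundaries, the last interval closed). Because a principal
component's sign is arbitrary, the score is made sign-canonical through
its own skewness: household asset counts are right-skewed, so the long
tail is taken to point toward wealth. This rule — unlike any rule linear
in the standardised inputs — leaves the categories unchanged when every
input's sign is flipped. If the score is essentially symmetric
(|skewness| < 1e-8) the orientation falls back to a positive loading sum.

## 3. Network estimation

All networks are fitted by nodewise regression: node $j$ is regressed on
all other nodes with an L1 penalty, giving sparse conditional-association
estimates. The engine (`glm_lasso_path()`) is cyclic coordinate descent
on an IRLS quadratic approximation, in compiled code, with warm starts
along a 100-value log-spaced penalty path from $\lambda_{\max}$ (the
smallest penalty with an all-zero solution, from the KKT condition at the
null fit) down to $0.01\,\lambda_{\max}$. Convergence is declared when no
coefficient moves more than 1e-7 in an IRLS pass. Predictors are
standardised internally; coefficients return on the original scale.

Model selection per node uses the extended BIC with $\gamma = 0.25$, the
conventional value for graphical models,
$\mathrm{EBIC}(\lambda) = -2\ell(\lambda) + \mathrm{df}\,\log n +
2\gamma\,\mathrm{df}\,\log p_{\text{cand}}$, where df counts nonzero
penalised coefficients, $\ell$ is the likelihood of the penalised fit
(the convention of the nodewise-Ising literature), and $p_{\text{cand}} =
p - 1$ is the number of predictors offered to the node (the EBIC
literature varies here; this choice is fixed and documented). Ties go to
the larger penalty, i.e. the sparser model.

`fit_ising()` symmetrises directed coefficient pairs with the AND rule by
default (an edge needs both nodewise coefficients nonzero; OR is
available) and averages the pair into the edge weight; intercepts become
node thresholds. `fit_mgm()` runs the same machinery with the family set
by declared node type (binary → logistic, count → Poisson with log link,
continuous → gaussian after standardising to unit variance), reports edge
strength as the mean absolute coefficient, and carries a sign attribute:
the common sign of the two directed coefficients, or 0 (undetermined)
when they disagree. With all-binary nodes the mixed model's edge set
coincides with the Ising fit's.

Two deliberate choices deserve emphasis. First, estimation is nodewise
pseudo-likelihood, not joint maximum likelihood — the de-facto standard,
and the one the selection behaviour above is calibrated for. Second,
**sampling weights are not used in network estimation**: the graphical
models are fitted unweighted on the complete-case sample, and the
pipeline logs this prominently. Design-weighted pseudo-likelihood would
change the implied estimand and has no established selection theory; the
networks therefore describe the analytic sample, while the regression
module carries the design-based claims.

Networks for readmission and length of stay are fitted on the
hospitalised subset, where those outcomes exist. Whether readmission
should enter as a raw count is genuinely open; count-with-log-link is the
documented default here. Covariates (age, sex) do not enter the networks:
nodes are the morbidities plus one outcome.

## 4. Network analysis

*Communities.* `walktrap()` implements the random-walk agglomeration of
Pons and Latapy: node distances from 4-step transition probabilities
($t = 4$ is the conventional walk length), Ward-style merging of adjacent
communities minimising the increase in mean squared distance, a full
dendrogram, and a cut at maximum Newman modularity. Components of a
disconnected graph are processed independently and never merged. Edge
weights must be non-negative, so signed networks contribute |weight| —
the standard psychometric-network practice — while signs are preserved in
exports. The implementation agrees with the reference igraph
implementation on planted-partition benchmarks (and this agreement is a
test, not an implementation dependency).

*Predictability.* Per node, the unpenalised GLM on the node's selected
neighbours is refitted and scored in-sample: proportion correctly
classified at 0.5 for binary nodes (baseline: the larger marginal class
share), proportion of variance explained for quantitative nodes
(baseline 0). Isolated nodes report their baseline and are flagged.

*Stability.* `bootstrap_edges()` resamples rows n-out-of-n, refits, and
summarises each edge by 2.5/50/97.5% quantiles and an inclusion
proportion; replicates that fail to fit are dropped and counted, and more
than 10% failures is an error. `case_drop_stability()` subsamples without
replacement at drop fractions 0.1–0.7 and reports the
correlation-stability coefficient: the largest drop fraction at which the
subsample edge vector still correlates ≥ 0.7 with the full-sample one in
≥ 95% of replicates (thresholds configurable; these defaults follow the
established stability methodology). Degenerate correlations — an all-zero
edge vector has no defined correlation — count as failures, so pure-noise
networks get CS = 0 rather than an undefined value.

*Flow layout.* `flow_layers()` places the target outcome alone in layer 0
and layers the remaining nodes by BFS distance over nonzero edges:
layer 1 holds the morbidities directly (conditionally) associated with
the outcome; deeper layers hold conditions whose association is mediated.
Unreachable nodes — an isolated morbidity — go to a sentinel layer one
past the deepest reachable one. Within-layer vertical order is a single
barycenter pass over the previous layer.

## 5. The synthetic cohort generator

`generate_cohort()` emulates the structure of a national ageing-cohort
baseline so that every stage has a parameter-recovery surface. Defaults
are the generator's study conditions and are not tuned per analysis:

* **n = 9412** subjects in **10 strata × 7 PSUs** (70 PSUs, standing in
  for 70 municipalities), subjects allocated with unequal stratum and PSU
  probabilities; PSU-level weights vary 1–5× as inverse inclusion
  probabilities. Per-stratum weight sums are recorded as notional
  population sizes.
* **Covariates** from fixed marginals (53.7% female; age 48.3/38.3/13.5%
  across 50–59/60–74/75+; 85% urban at PSU level; 63.7% with partner;
  alcohol use declining with age), plus 12 household asset variables
  driven by a latent wealth factor.
* **19 diseases** from an Ising model whose couplings are sparse
  (density 0.15, |θ| in 0.3–1.0, 80% positive — diseases mostly
  co-occur) and whose thresholds target a realistic prevalence profile
  (hypertension ≈ 0.5 down to parkinsonism ≈ 0.015) through a first-order
  mean-field correction, with an age-graded threshold shift (+0.25 and
  +0.5 logits at 60–74 and 75+, centred so population marginals stay on
  target). For p ≤ 12 diseases the exact enumerated sampler is used; past
  that, a single-chain Gibbs sampler (burn-in 500 sweeps, thinning 10).
* **Hospitalisation** is Bernoulli with a log-link linear predictor in
  sex, partner, alcohol, age and multimorbidity category (effects on the
  log-PR scale of magnitudes typical for these factors, e.g. 2.39 for
  ≥ 3 conditions), plus a PSU-level log-risk effect (sd 0.15) that makes
  the design variance real. The intercept that hits the target 10%
  prevalence has a closed form under the log link; if any fitted
  probability would reach 1 the calibration is infeasible and the
  generator says so.
* **Readmission** is 1 + Poisson among the hospitalised (admitted
  subjects have at least one admission), mean ≈ 1.55. **Length of stay**
  is a linear predictor in days (baseline 5.2, +3.5 for men, −2.7 rural)
  times unit-mean lognormal noise (sdlog 1.15), giving mean ≈ 6 and
  sd ≈ 10 days — strongly right-skewed, while keeping E[LOS | x] linear
  so regression recovery is well defined.
* **Missingness**: rows are flagged with probability logit-linear in age
  and sex, the intercept calibrated by root-finding so the expected
  flagged share is 6.4%; one randomly chosen disease or hospitalisation
  cell is blanked per flagged row, making "missing on at least one
  analysis variable" literal and the complete-case definition
  unambiguous. Covariates are never blanked, so they remain valid IPW
  predictors.

What the generator does *not* emulate: questionnaire instruments,
multi-stage address sampling, interviewer effects, item-level "don't
know" codes (folded into missingness), or any weight-construction detail
of a real survey — its inverse-inclusion weights are a stand-in, not a
reconstruction. Passing tests therefore demonstrate estimator
correctness under a faithful structural emulation, not agreement with any
real cohort's point estimates, which would require the restricted
microdata.

## 6. Numerical choices and degenerate inputs

* Coordinate-descent tolerance 1e-7 on coefficient updates; IRLS weights
  floored at 1e-6 and linear predictors clamped at ±30 for logistic and
  Poisson stability. A coordinate sitting exactly on the KKT boundary
  (|gradient| = λ, as at λ_max) is kept at zero rather than entering
  with floating-point noise — otherwise the null model would never
  appear on the path and the EBIC could not select it.
* Gaussian log-likelihoods are profile likelihoods with σ² = RSS/n, the
  EBIC convention; constants cancel in selection.
* `sample_ising_exact()` refuses p > 15 (2^p state enumeration) and
  points to the Gibbs sampler; the Gibbs chain is deterministic under a
  seed and its thinning trades autocorrelation for time.
* Zero-variance nodes, non-binary disease cells, missing design columns,
  constant outcomes, rank-deficient designs, unknown flow targets and
  single-PSU strata are all explicit, named errors rather than silent
  degradation.
* Pipeline determinism: all randomness flows from stage-scoped seeds
  (simulation, bootstrap, subsampling), so stages can be re-run
  independently and a repeated run reproduces every numeric artefact byte
  for byte.

## 7. Problem sizes used in the test suite

The suite exercises each property at the smallest size where it is
informative rather than at survey scale: samplers at n = 20,000–50,000
draws for distributional checks; chain-recovery at p = 8, n = 3000
(50 replicates); null sparsity at p = 10, n = 1000 (100 replicates);
regression calibration at n = 2000 with 100 clusters (300 replicates);
survey CI coverage across 500 simulated designs of 70 PSUs; IPW
de-biasing across 200 replicates at n = 1500; walktrap against the
reference implementation on 100 planted 16-node graphs; and the full
pipeline twice at n = 1200–2000 for byte-identity. These sizes are the
package's own choices for a decisive yet fast test surface.

## 8. Known limitations

* Nodewise pseudo-likelihood does not maximise the joint Ising
  likelihood; edge weights are regularised and shrunken, so their
  magnitudes are comparable within a network, not across differently
  sized samples.
* The EBIC is applied to penalised logliks along a finite path; it is
  consistent for sparse graphs but conservative at small n — absent
  edges are the expected failure mode, not spurious ones.
* The survey variance estimator assumes with-replacement sampling of
  PSUs within strata (the standard approximation); finite-population
  corrections are not implemented.
* Predictability is in-sample by construction (it conditions on the
  selected neighbourhood); it is a descriptive measure, not an estimate
  of out-of-sample performance.
* The generator's outcome models are log-linear/linear by construction;
  model misspecification robustness is not part of the test surface.
* Because the generator drives hospitalisation through the multimorbidity
  *category* (a function of the disease count), no single disease carries
  a strong conditional association with the outcome; in fitted networks
  the outcome node therefore often lands isolated, in the flow layout's
  sentinel layer. Recovery of disease–disease structure is the network
  test surface; direct disease–outcome edges are not planted.
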