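---
title: "Multi-state progression modelling with tract-profile statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state progression modelling with tract-profile statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdti)
```

## The model

`mmdti` implements a continuous-time multi-state Markov model of
Alzheimer's progression over three clinical states — normal cognition
(NC), amnestic mild cognitive impairment (aMCI) and Alzheimer's disease
(AD) — together with the tract-profile group statistics and classifier
evaluation used alongside it, and a synthetic-cohort generator that makes
the whole chain testable without patient data.

The disease state of subject $j$ is a continuous-time Markov chain on
$\{NC, aMCI, AD\}$. Movement is governed by the transition-intensity
matrix $Q$, whose off-diagonal entries are the instantaneous rates
$o_{qq'}$ of moving from state $q$ to $q'$, whose rows sum to zero, and
whose AD row is identically zero: AD is absorbing. The default structure
allows NC $\to$ aMCI, aMCI $\to$ NC (reversion) and aMCI $\to$ AD; the
direct NC $\to$ AD rate is structurally zero, both because conversion is
understood to pass through MCI and because panel cohorts observed at
roughly annual visits carry almost no information about a direct rate. AD
remains reachable from NC through the two-step path, so predicted onset
probabilities from NC are positive at every positive horizon.

Covariates enter the intensities log-linearly (a proportional-intensity
model):

$$o_{qq'}(V) = r_{0,qq'} \, \exp(\beta_{qq'}^\top V),$$

with one baseline rate $r_{0,qq'} > 0$ (per year) and one coefficient
vector $\beta_{qq'}$ per allowed transition. Covariates are held constant
within subject (they are patient-specific variables such as age, sex and
cognitive scores measured at entry).

Because visits happen at discrete times, the exact transition instants
are interval-censored: only the state at each visit is seen. Over an
interval of length $t$ the transition probabilities are the matrix
exponential $P(t) = \exp(tQ)$, and a subject observed in states
$T_1, \dots, T_x$ at times $s_1 < \dots < s_x$ contributes

$$L_j = \prod_{i=2}^{x} P_{T_{i-1}, T_i}(s_i - s_{i-1})$$

evaluated under the subject's own $Q(V_j)$. The first-observation factor
is taken as 1, i.e. the likelihood conditions on the first observed
state; this is standard panel-data practice and avoids inventing an
initial distribution the data cannot identify. `fit_msm()` maximizes the
summed log-likelihood; `predict_onset()` reports
$P_{q,\mathrm{AD}}(h) = [\exp(hQ(V))]_{q,\mathrm{AD}}$, which is
nondecreasing in the horizon $h$ because AD is absorbing.

## Numerical choices

* **Parameterization.** Internally the optimizer works on
  $\log r_{0,qq'}$ and raw $\beta$, so positivity of the rates is
  automatic and the problem is smooth and unconstrained (log-rates are
  bounded below at $\log 10^{-8}$ only to keep an unobserved transition
  from drifting to $-\infty$; hitting that bound triggers a warning).
* **Matrix exponential.** Production code uses scaling-and-squaring
  (Armadillo's `expmat`, called per subject-interval from C++). The test
  suite re-derives $P(t)$ through an independent uniformization series
  $\sum_k e^{-\lambda t} (\lambda t)^k / k! \; M^k$ with
  $M = I + Q/\lambda$, written before the engine and kept outside the
  package, and requires elementwise agreement to $10^{-8}$, alongside
  Chapman–Kolmogorov ($P(s+t) = P(s)P(t)$) and stochasticity
  (rows sum to 1 within $10^{-10}$) on random generators.
* **Optimization.** `stats::optim(method = "L-BFGS-B")` with the
  objective-change tolerance set to a relative $10^{-9}$ and at most 500
  iterations; convergence is reported as the optimizer's success code
  plus a relative gradient-norm check at $10^{-4} \cdot \max(1, |\ell|)$
  (the absolute gradient scales with the magnitude of the
  log-likelihood). Standard errors come from the observed information
  (numerical Hessian at the maximum). Initial rates are crude
  occurrence/exposure estimates (observed direct transition counts over
  total follow-up, floored at $10^{-3}$/yr); coefficients start at 0.
* **Underflow.** Transition probabilities are floored at $10^{-300}$
  before taking logs; an *exactly* zero probability — a structural
  impossibility such as an observed exit from AD — instead returns
  $-\infty$ with a warning, because it indicates a data/structure
  conflict rather than round-off.
* **Units.** Times are years from study entry; node indices are 0-based.

## The synthetic cohort

`generate_cohort()` emulates a 120-subject memory-clinic discovery
cohort: 39 NC, 34 aMCI and 47 AD subjects. Age (NC $68.5 \pm 7.1$, aMCI
$69.5 \pm 8.8$, AD $69.7 \pm 9.3$ years) and sex (male proportions
18/39, 13/34, 20/47) are nearly identical across groups, while MMSE
(NC $28.5 \pm 1.4$, aMCI $26.6 \pm 2.5$, AD $16.1 \pm 7.3$, truncated to
0–30) separates them strongly — the structure a demographics table of
such a cohort shows. Choices the source material leaves open, fixed here
once:

* **Visit schedule.** 4 visits with i.i.d. Uniform(0.75, 1.25)-year
  gaps — typical annual follow-up with scheduling jitter. Configurable.
* **Generating rates.** aMCI $\to$ AD at 0.25/yr (amnestic MCI carries a
  20–40% annual dementia risk, so the midpoint of that range);
  NC $\to$ aMCI incidence 0.10/yr and aMCI $\to$ NC reversion 0.10/yr,
  plausible for a clinic population. Covariate effects default to zero
  so that the generator is a clean null for association tests; any
  $\beta$ can be injected for recovery studies.
* **Initial state.** The subject's diagnostic group at entry, matching
  the conditioning in the likelihood.

Each subject's latent path is simulated by Gillespie-style forward
simulation (exponential holding times at the total exit rate), then
observed only at the visit times. All generator randomness is drawn from
a locally seeded RNG stream, so identical configurations reproduce
identical datasets bit for bit and the caller's RNG state is untouched.

`generate_tract_profiles()` emulates automated-fiber-quantification
(AFQ) output: for each of the 20 standard tracts, 100-node profiles of
fractional anisotropy (FA, dimensionless in (0,1)) and mean diffusivity
(MD, in units of $10^{-3}\,\mathrm{mm^2/s}$). Group effects are stepwise
in severity (NC unaffected; aMCI one step; AD two) and confined to nodes
40–60: FA *decreases* by 0.03 per step in the cingulum cingulate and
uncinate tracts, MD *increases* by 0.03 per step in the IFOF and
callosum forceps minor — the tract/metric pattern typical of AD cohorts.
Node noise is i.i.d. Gaussian (sd 0.05 for both metrics, a realistic
between-subject spread); FA values are clipped into (0,1). Tracking
failures occur only for the left/right cingulum hippocampus (52% and 27%
of subjects), the two tracts AFQ most often fails to identify, so the
default exclusion rule (drop a tract failing in more than 25% of
subjects) reduces 20 tracts to 18.

What the generator deliberately does **not** emulate: spatial
autocorrelation along nodes (real tract profiles are smooth, so
neighboring nodes are far from independent), between-tract correlation,
site/scanner effects, covariate-dependent tract damage, and
visit-to-visit measurement error in the diagnosis itself (no
misclassification model). Tests passing on this generator therefore
validate the *statistical machinery* — calibration, power against the
injected effect, recovery of generating parameters — not performance on
real diffusion data.

## Tract statistics

For each node of each retained tract, `pointwise_profile_test()` compares
the groups with one of three one-way tests, after (by default)
residualizing the node values on age and sex by OLS and re-centering to
the grand mean. Adjustment-then-testing is done in that order to mirror
the common tract-profile workflow; putting the covariates inside a
per-node linear model is a noted alternative but not the default.

* classic ANOVA: $F = \mathrm{MS}_{between} / \mathrm{MS}_{within}$ with
  df $(k-1, N-k)$ — exact under homoscedastic normal groups. The
  between mean square uses the $k - 1$ divisor (groups minus one), the
  only choice under which the statistic is F-distributed.
* Welch: groups weighted by $w_i = n_i/s_i^2$, with the Welch correction
  and fractional denominator df — valid under unequal variances.
* Brown–Forsythe:
  $S^* = \sum n_i(\bar x_i - \bar x)^2 / \sum (1 - n_i/N)\, s_i^2$ with
  Satterthwaite denominator df. In a balanced equal-variance design it
  reduces exactly to the classic $F$, and at $k = 2$ it coincides with
  the squared Welch $t$.

Both heteroscedastic tests are approximations. The suite verifies their
size at $\alpha = 0.05$ over 5,000 null replicates at $n = 40$ per
group — Welch under a 4-fold sd ratio, Brown–Forsythe under a 2-fold
ratio — because at very small samples the exact size of a correct Welch
implementation sits slightly above nominal, and the classic
Brown–Forsythe statistic is documented to be liberal (exact size near
0.065) under extreme variance ratios, its numerator df ignoring the
heteroscedasticity. Those are properties of the published statistics,
reproduced faithfully here, not implementation artifacts; the suite pins
the mild Brown–Forsythe liberality explicitly at the extreme ratio.

Significance defaults to raw $p < 0.05$ per node, mirroring common
tract-profile practice; Benjamini–Hochberg FDR across the 100 nodes is
available with `fdr = TRUE`. `anova_from_summaries()` computes the same
classic F from per-group $(n, \bar x, s)$ triplets — an exact algebraic
identity with the raw-data test, which is what makes a published
demographics table recomputable. Post hoc comparisons are two-sided
Welch two-sample $t$-tests per group pair on adjusted values; whether to
correct them for multiplicity is left to the caller (none is applied by
default, matching the pointwise convention).

## Evaluation

`confusion_metrics()` reports accuracy $(TP+TN)/(TP+TN+FP+FN)$,
specificity $TN/(TN+FP)$ and sensitivity $TP/(TP+FN)$; a zero
denominator yields `NA`, never 0. A variant sensitivity with a $TP+FP$
denominator (precision under another name, occasionally printed as
"sensitivity") is available behind `as_printed = TRUE` for fidelity
experiments only. `roc_auc()` sweeps thresholds over the unique scores
and computes AUC by the rank/Mann–Whitney formula with ties counting
one half — verified in the suite against exhaustive pairwise counting,
invariance under strictly increasing transforms, and label-flip
antisymmetry.

`cross_validated_eval()` runs seeded, stratified k-fold (default 5)
cross-validation, pooling out-of-fold scores into one ROC and one
confusion matrix. The classifier is pluggable — any
`(x_train, y_train, x_test) -> scores` function — with a small-ridge
logistic regression as the deterministic default; the claims here are
about the evaluation harness, not any particular learner. Multi-class
labels are handled one-vs-rest; the headline binary task is AD-vs-NC.

One caveat specific to the synthetic demonstration: the `mm` feature
block (predicted onset probabilities at 1/2/5 years) is computed from
the subject's observed baseline state, and the class label *is* the
baseline diagnostic group, so AD-vs-NC separation through the `mm` block
is trivially strong on synthetic data (pooled AUC near 1). The
informative comparison on this generator is the `dti`-only block, where
separation comes solely from the injected tract effects.

## The pipeline

`run_pipeline()` chains simulate → fit → tractstats → evaluate on a
single `pipeline_config()`, writing CSV/JSON artifacts and a manifest of
md5 hashes. Stage seeds derive deterministically from the global seed
(cohort at `seed`, profiles at `seed + 1`, fold assignment at
`seed + 2`), so a rerun reproduces every hash; a failing stage halts the
run with the stage named, keeping earlier outputs. The default
configuration (120 subjects, 20 tracts × 100 nodes × 2 metrics) runs in
well under a minute on one CPU.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make their Monte Carlo
error small relative to the tested margin: sojourn-time and
interval-frequency checks at 10,000 paths (4 standard errors),
rate recovery at 100 replicates of 1,000 subjects × 5 visits (3-SE
coverage ≥ 90%), covariate recovery ($\beta = \ln 2$) at 25 replicates
of 1,000 subjects, consistency (decreasing RMSE) at 250/1,000/4,000
subjects × 12 replicates, test calibration at 5,000 null replicates,
pointwise power (≥ 80% of affected nodes at a 1-sd effect, 40 per
group) at 30 replicates, and the permutation-agreement property against
a 2,000-draw Monte Carlo permutation distribution on 50 instances
(the exact permutation distribution of 15 values in 3 groups has 756,756
points, which buys no extra resolution for a rank-agreement check).

## Known limitations

* Time-homogeneous intensities only; no hidden-Markov layer for state
  misclassification, no exact-death-time handling.
* Covariates are subject-constant in the default generator and fit.
* The bias-consistency of the MLE is verified through decreasing RMSE
  across growing cohorts rather than a direct bias estimate: at feasible
  replicate counts a raw absolute-bias comparison is dominated by Monte
  Carlo noise.
* The generalized S-value procedure sometimes reported alongside the
  Brown–Forsythe test is not implemented.
* Synthetic profiles have independent node noise; real AFQ profiles are
  spatially smooth, so real-data pointwise inference would need to
  account for dependence across nodes.
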