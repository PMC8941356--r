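---
title: "Supervised topic-model staging of chronic limb-threatening ischemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised topic-model staging of chronic limb-threatening ischemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cltistage)
```

## The clinical problem

Chronic limb-threatening ischemia (CLTI) is the end stage of peripheral
arterial disease: rest pain and/or tissue loss with objective arterial
insufficiency.  Outcomes after revascularization are heterogeneous, and
single-feature risk markers (wound grade, rest pain, diabetes) stratify
patients poorly.  `cltistage` implements a phenotype-clustering approach:
patients are grouped into a small number of latent *stages* that jointly
reflect their presenting features and their 1-year prognosis, measured by
the composite endpoint **CLTI-free survival** — alive, free of major
ipsilateral amputation, free of CLTI recurrence, and with the index wound
healed at 1 year.

## Model

Each patient is a *document*; each present comorbid or limb-related
feature (wound grade level, dialysis, rest pain, bypass target, ...) is a
*word*.  With $K$ topics (clusters), vocabulary size $V$, and symmetric
Dirichlet priors, the generative model for patient $d$ is

$$\theta_d \sim \mathrm{Dir}(\alpha), \quad
  z_{di} \mid \theta_d \sim \mathrm{Cat}(\theta_d), \quad
  w_{di} \mid z_{di} = k \sim \mathrm{Cat}(\phi_k), \quad
  \phi_k \sim \mathrm{Dir}(\beta),$$

and the binary outcome is supervised through a probit regression on the
*empirical* cluster-assignment proportions
$\bar z_d = (n_{d1}, \dots, n_{dK}) / n_d$:

$$\Pr(y_d = 1 \mid \bar z_d, x_d)
   = \Phi(\eta^\top \bar z_d + \gamma^\top x_d).$$

Demographic covariates $x_d$ (sex, race, dummy-coded) enter **only** the
regression, never topic formation: demographics plausibly shift outcomes
through disparities in health and care, but are not features on which a
CLTI subtype should be defined.  `tokenize_cohort()` enforces this split.

## Fitting

`slda_fit()` uses collapsed Gibbs sampling: $\theta$ and $\phi$ are
integrated out analytically and only token-level assignments $z$, latent
probit utilities $y^*$, and coefficients $(\eta, \gamma)$ are sampled.

* **Token update.**  For token $i$ of patient $d$,
  $p(z_{di} = k \mid \cdot) \propto (n^{-di}_{dk} + \alpha)\,
  \frac{n^{-di}_{kw} + \beta}{n^{-di}_{k} + V\beta}\,
  \exp\!\big(-\tfrac12 (y^*_d - \eta^\top \bar z^{(k)}_d
  - \gamma^\top x_d)^2\big),$
  where $\bar z^{(k)}_d$ sets token $i$ to $k$.  The sweep is implemented
  in C++ with all randomness drawn from R's RNG, so a seed gives
  bit-identical fits.
* **Utility update.**  $y^*_d$ is drawn from $N(\eta^\top \bar z_d +
  \gamma^\top x_d, 1)$ truncated to $(0,\infty)$ if $y_d = 1$ and
  $(-\infty, 0]$ otherwise — the classic latent-utility augmentation that
  makes the probit conditionally Gaussian.  The package names the probit
  link as the outcome model and chooses this augmentation because every
  conditional then has closed form, with no tuning parameters.
* **Coefficient update.**  $(\eta, \gamma)$ are drawn jointly from the
  conjugate normal posterior of the linear model $y^* = [\bar z \mid X] b
  + \varepsilon$, $\varepsilon \sim N(0,1)$, prior $b \sim N(0, v I)$
  with `coef_prior_var` $v = 10$ by default ($v = \infty$ reproduces the
  least-squares limit and is used in tests).

Point estimates average the smoothed count ratios
$\hat\phi_{kv} = (n_{kv} + \beta)/(n_k + V\beta)$ and
$\hat\theta_{dk} = (n_{dk} + \alpha)/(n_d + K\alpha)$ over retained
samples.  No label alignment is applied during averaging (a single
characterized solution is reported); `align_topics()` provides best-
permutation alignment when comparing against a reference, as in the
simulation experiments.  Defaults are $\alpha = 50/K$, $\beta = 0.1$,
2000 sweeps with 1000 burn-in and thinning 10; the per-sweep collapsed
feature log-likelihood and Gaussian utility term are recorded as
convergence diagnostics.

Numerical choices: conditional probabilities are floored at $10^{-300}$
before normalization; truncated-normal draws invert the *tail*
probability ($y^* = \mu - \Phi^{-1}(u\,\Phi(\mu))$ for positive
truncation) so draws stay accurate far into the tails; exact ties in
stage assignment go to the smallest index with a warning.

## Choosing the number of clusters

`select_k()` fits each candidate $K$ (deterministic per-$K$ seeds derived
from one base seed) and approximates the marginal likelihood of the
features $P(w \mid K)$ by the harmonic mean of $p(w \mid z)$ over
retained samples, computed with a log-sum-exp shift.  The estimator's
known instability (domination by rare low-likelihood samples) is the
reason the retained-sample count is configurable and the full evidence
table is always returned; `evidence_elbow()` reports successive
differences as a diminishing-returns diagnostic but is never used for
automatic selection.  Exact ties break toward the smaller $K$.

One design choice deserves emphasis.  For *fitting a single model* the
package keeps the common $\alpha = 50/K$ convention.  For *comparing*
candidate $K$ by approximate evidence, however, `select_k()` defaults to
a **constant** $\alpha = 3$ across candidates.  In this setting —
5–12-token feature-documents over a vocabulary of only ~20 tokens — a
$50/K$ schedule gives every candidate a differently-sharp document–topic
prior, and the sharper posteriors of larger $K$ mechanically inflate the
harmonic-mean estimate: on simulated 3-cluster corpora the estimated
evidence then increases monotonically in $K$ regardless of the true
structure.  Holding the prior constant makes the comparison about cluster
structure rather than prior sharpness; a few pseudo-counts per topic
(comparable to the document length) keeps the posterior diffuse enough to
feel the cost of superfluous topics.  On the simulation family below the
selected $K$ is unchanged for $\alpha$ anywhere in roughly $[2, 4]$.

## Wound grading

`grade_wound_set()` maps raw per-location ulcer/gangrene records to the
WIfI wound grade: 0 (no wound), 1 (ulcer on only one toe), 2 (ulcers on
multiple toes, or gangrene of toes), 3 (hindfoot/leg ulcer, or
forefoot/hindfoot/leg gangrene), highest grade winning when several
wounds coexist.  Two rule gaps are resolved by the package and documented
here rather than hidden: forefoot **gangrene** appears in both the
grade-2 and grade-3 published rule lists and is graded 3 (consistent with
the highest-score rule and SVS WIfI convention); forefoot **ulcers** are
not covered by the published rules at all and are graded 2.  Free-text
"other" locations are recoded by a case-insensitive whole-word keyword
table shipped as an editable CSV (`inst/extdata/`); unresolvable text
flags the patient for the missing-data path instead of being dropped.

## Outcome construction

`classify_patient()` implements the composite with a 365-day horizon and
inclusive comparison ("before or at 1 year").  Component statuses can be
missing independently; a recurrence recorded before loss to follow-up of
vital status still classifies the composite as failed, which mirrors how
such patients were retained in the source analysis.  A patient whose
healing status and events are all unknown is unclassifiable and excluded
— the analogue of the enrollment records dropped for incomplete data.
`build_outcome_table()` computes, per stage and outcome, the "observed"
numerator over the denominator of patients with known status for *that*
outcome, so denominators legitimately differ between outcomes within a
stage.  The printed recurrence denominators of the reference cohort
cannot be derived from "alive with intact limb" arithmetic (the package's
fixture reproduces them through explicit missingness flags); for new data
the known-status rule above is the documented behavior.  All rates use
half-up rounding to one decimal (`round_half_up()`), which reproduces
every printed rate; base R's round-half-to-even does not.

## Stage profiles

`assign_stages()` takes the maximum-probability cluster; stages are then
relabeled by descending CLTI-free survival so stage 1 is the
best-prognosis cluster (`order_stages_by_outcome()`, configurable).
`build_stage_profiles()` reports per-stage feature counts, prevalences
with 95% Wald (normal-approximation) intervals on the percent scale —
the interval family that regenerates the reference table's printed
bounds exactly — and signed percentage-point differences from the cohort
prevalence.  Wald intervals are clamped to $[0, 100]$; their true
coverage near $p = 0.2$, $n = 130$ is around 93–96%, which the test
suite documents as a property of the approximation, not a claim of exact
nominal coverage.

## Synthetic data and the printed-count fixture

The source cohort is not public, so the package ships two substitutes.

`generate_cohort_records()` emulates a ~1238-patient infrainguinal-bypass
cohort: features sampled independently at the published marginal
prevalences, raw wound-location records realizing the published
wound-grade distribution (including a 5% admixture of free-text "other"
locations), uniform event-day offsets in 0–365, and configurable
per-field missingness.  It deliberately does **not** model feature–feature
correlation beyond what topics induce, survival-time distributions, or
center effects — so pipeline tests on it validate plumbing and
reproducibility, not clinical realism.

`generate_slda_corpus()` draws corpora exactly from the generative model
with known parameters.  The canonical simulation family
(`cluster_study_config()`) uses $K_{\text{true}} = 3$ separated
block-structured topics over $V = 20$ tokens (80% within-block mass),
document lengths 5–12, a concentrated document–topic prior
$\alpha_{\text{true}} = 0.5$, supervision $\eta = (2, 0, -2)$, and one
balanced binary covariate with $\gamma = 0.5$.  The concentrated
$\alpha_{\text{true}}$ is the substantive choice: it makes each simulated
patient predominantly a member of one phenotype cluster, which is the
regime the staging analysis is about.  With a diffuse document prior
(e.g. $\alpha = 50/3$) every document is an even topic mixture and there
is no document-level cluster structure for model selection to find —
simulations in that regime test only the word-level marginals (and the
package's law-of-large-numbers tests use it for exactly that).

`prevent3_fixture()` is fully deterministic: 1238 patients with stage
sizes 130/578/530 and per-outcome numerators/denominators encoded through
missingness flags so that every published composite and secondary rate is
regenerated by the ordinary rate machinery, not looked up.  Two garbled
rows of the published prevalence table (a "Diabetes" row repeating the
Dialysis counts, and a stage-2 Grade-3 percentage inconsistent with its
own count) are documented and excluded from cell-level reproduction
checks.

## Problem sizes and verification

The package's experiments are sized to run comfortably on one CPU: the
recovery experiment fits 1200 documents with 800 sweeps (maximum absolute
error of $\hat\phi$ against truth below 0.05 after permutation
alignment, probit coefficient signs recovered); the selection experiment
runs $K \in \{2, \dots, 5\}$ over 10 seed replicates with 600 sweeps
each; sampler correctness is checked on 6-token corpora against exhaustive
enumeration of all $2^6$ assignments (total-variation distance below
0.05, harmonic-mean evidence within 0.5 nats of the exact marginal
likelihood).  Enumeration is exact because, with coefficients held fixed,
the response term factorizes into per-document probit probabilities;
`slda_fit(update_coefficients = FALSE)` exists precisely to make the
sampler comparable against that closed form while still exercising the
utility augmentation.

## Known limitations

* The harmonic-mean evidence estimator is kept for fidelity to the
  approach it implements; it is biased upward and its variance can be
  dominated by rare samples.  Treat the evidence table as a guide and
  inspect `evidence_elbow()`.
* Ischemia and foot-infection WIfI components are out of scope (the
  underlying data lack hemodynamic and infection detail); only the wound
  grade is computed.
* The endpoint is binary at 1 year; no time-to-event modeling.
* Between-stage significance testing is deliberately absent; profiles are
  descriptive.
* The cohort emulator samples features independently; passing tests on it
  says nothing about performance under realistic comorbidity correlation.
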