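---
title: "Methods: causal-inference modelling of visuo-proprioceptive integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal-inference modelling of visuo-proprioceptive integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodyci)
```

This vignette documents the model equations, the simulation-based
likelihood, the staircase rules, and the calibration choices behind the
synthetic cohort. It is the "why", complementing the function-level "what"
in the reference documentation.

## 1. The causal-inference observer

On each trial the hand sits at a proprioceptively sensed position and a
visual cursor may be displaced by a disparity $\delta$. The observer
receives noisy samples $x_v \sim N(s + \delta, \sigma_v^2)$ and
$x_p \sim N(s, \sigma_p^2)$ and must infer the hand position under
uncertainty about whether the two signals share a common cause.

**Forced fusion.** If the cues share a cause, the optimal estimate is the
reliability-weighted average with weights
$w_v = r_v / (r_v + r_p)$, $r = 1/\sigma^2$:
$\hat{x}_{FF} = w_v x_v + w_p x_p$.

**Common-cause posterior.** With a uniform spatial prior over a 180°
workspace, the marginal likelihoods of the two causal structures are

$$L(C{=}1) = \frac{1}{\alpha}
  \exp\!\left(-\frac{(x_v - x_p)^2}{2(\sigma_v^2 + \sigma_p^2)}\right),
  \qquad
  \alpha = 180\sqrt{2\pi(\sigma_v^2 + \sigma_p^2)},
  \qquad
  L(C{=}2) = \frac{1}{180^2},$$

and the posterior mixes them with the common-cause prior $P_\pi$:
$P_{com} = P_\pi L_1 / (P_\pi L_1 + (1-P_\pi) L_2)$. The reported hand
position model-averages the two structures:
$\hat{S}_p = P_{com}\,\hat{x}_{FF} + (1 - P_{com})\,x_p$.

```{r}
p <- observer_params(sigma_v = 5, sigma_p = 5, p_prior = 0.5)
common_cause_posterior(0, 0, p)$p_com
```

`common_cause_posterior()` evaluates $L_1$ in log space, so extreme
conflicts underflow to well-defined posteriors instead of `NaN`. The test
suite checks the closed form against independent 2-D trapezoid-grid
integration of the generative model over a 125-point parameter grid
(`tests/testthat/helper-oracle.R`).

## 2. The VPD task and error normalization

`build_vpd_design()` produces the three-block session: blocks 1–2 cross 7
targets (0, ±15, ±30, ±45°) with 7 disparities (0, ±13.3, ±26.6, ±40°), 49
trials each; block 3 crosses 5 targets with 5 disparities (0, ±20, ±40°)
and adds a 1–10 ownership rating per trial. `simulate_vpd()` draws sensory
samples per trial, forms $\hat{S}_p$, and records the reaching error
$-(\hat{S}_p - x_p)$ plus motor noise. Observed errors are normalized by
subtracting the participant's mean error on zero-disparity trials
(`normalize_errors()`), which removes idiosyncratic reach bias.

Ratings are generated from $P_{com}$ through a monotone map with additive
noise, clamped to 1–10, so simulated ownership falls with disparity;
`residual_ownership_correlation()` checks that, within disparity levels,
trials rated as more "owned" also show more visual attraction.

## 3. Simulation-based likelihood and fitting

The model's error distribution at a disparity has no closed form once
$P_{com}$ varies trial to trial, so the likelihood is built by simulation.
For candidate parameters, `n_sim` trials are simulated at each disparity
level with frozen standard-normal draws (common random numbers, so the
objective is deterministic given a seed and smooth in the parameters). The
simulated errors are normalized *within the simulation* — centered on the
simulated zero-disparity mean — and summarized by a Gaussian kernel density
with Silverman bandwidth floored at 0.1°. The floor makes the degenerate
case (an all-identical sample, e.g. $P_\pi = 0$ with no motor noise)
degrade gracefully to a Gaussian with SD 0.1°.

One further subtlety matters in practice. The *observed* normalized errors
were all shifted by the same quantity: the sampling error of the
participant's own zero-disparity mean (19 trials). Conditioning on that
shared offset $b \sim N(0, \widehat{sd}_0^2/n_0)$, each trial's density is
the centered simulated density evaluated at the observation plus $b$; the
likelihood integrates $b$ out **jointly across all trials** on a fine
normal-weighted grid (log-sum-exp) whose spacing adapts to the narrowest
kernel bandwidth, because spike-shaped predicted densities make the
integrand equally spiky in $b$. Ignoring the offset floors the likelihood
of the true parameters whenever the predicted distribution is narrow;
convolving it into each trial independently over-smooths and washes out the
information that identifies $P_\pi$. The joint treatment is the faithful
probability model of the normalization actually applied to the data.

`fit_participant()` maximizes this likelihood with Nelder–Mead on
$(\log\sigma_v, \log\sigma_p, \mathrm{logit}\,P_\pi)$. Starting points are
a moment-based guess (the slope of mean error against disparity estimates
the average visual attraction $P_{com} w_v$; the zero-disparity spread
seeds the noise terms) plus a seeded Latin-hypercube pool; every candidate
is screened by a single objective evaluation and the best `n_starts` seed
full simplex runs, with a final polish restart.

`recovery_experiment()` is the package's own validation harness: simulate
known observers over the full design, fit them back, and report bias, RMSE
and true-vs-fitted correlation per parameter. At desk scale (`n_sim =
5000`, 4 starts, 20 observers) $\sigma_p$ recovers with correlation above
0.8 and $P_\pi$ above 0.6; $\sigma_v$ is intrinsically weaker because the
reach readout is proprioceptive.

## 4. Unisensory protocols

**Proprioceptive judgment (PJ).** A 5-step halving staircase (offsets
$30/2^k$ degrees) with *absolute* mirroring: each displayed offset takes
the sign opposite to the previous response. A deterministic observer's
final estimate lands within 1.875° of its decision boundary for boundaries
inside the staircase's capture range (±45/32°); beyond it the final
estimates saturate, so the measured $\sigma_{PJ}$ compresses large
proprioceptive noise. Seven targets × 4 repetitions × 5 steps = 140
presentations; $\sigma_{PJ}$ is the SD of final estimates after removing
per-target means.

**Open-loop reaching (OL).** 5 targets × 10 reaches without visual
feedback; $\sigma_{OL}$ is the SD of per-target demeaned endpoints.

**Midline judgment (MJ).** 9 adjustments of a probe to the subjective
midline; $\sigma_{MJ}$ is their SD.

**Two-point discrimination (2PD).** A descending staircase (start 2 cm on
the hand, 4 cm on the forearm) that halves the separation after 3
consecutive correct responses, returns to the midpoint of the current and
last-correct separation after an error, stops after 5 inversions, and
averages the last two correct separations; a 10-probe confirmation block
(at most 3 attempts) validates the estimate.

## 5. Metric body representation

`landmark_set()` holds localized 2-D landmark positions for an arm or hand;
`limb_dimensions()` converts them to perceived length and width, and
`dimension_indices()` forms the Estimated Dimension (ED = perceived/real)
and Estimated Error (EE = |ED − 1|). `group_compare()` tests ED against 1
(or between groups) with Shapiro-gated t/Wilcoxon tests and Bonferroni
correction over the four indices (arm/hand × length/width).

## 6. Synthetic cohort and calibration

`generate_cohort()` builds a two-group cohort (23 healthy older, 23 healthy
young) with lognormal sensory-noise distributions (older: larger
$\sigma_p$), a Beta-distributed common-cause prior with *no* group
difference, and per-participant VPD sessions, unisensory protocols, 2PD
staircases, landmark sets, and cognitive covariates. Three calibrations are
worth flagging because they are package choices, not laws of nature:

- the PJ linkage maps $\sigma_p$ into the staircase's discriminative range
  (`pj_sd = 0.30 sigma_p + 0.30 + noise`, floored at 0.2°) — necessary
  because the staircase saturates for observer SDs above ~8°;
- the older group's arm-length EE is generated from its *measured*
  covariates (TMT B−A, $\sigma_{MJ}$, $\sigma_{OL}$) at roughly 50%
  explained variance, so the downstream regression has a known active set;
- `fit_cohort()` uses reduced fitting settings (`n_sim = 3000`, 3 starts)
  sized for a single-CPU budget; per-participant analyses should prefer
  `fit_participant()` defaults.

## 7. Predictor selection

`screen_predictors()` drops near-constant columns (all but at most one
participant sharing a value). `lasso_select()` runs `glmnet` with
leave-one-out cross-validation (`alpha = 1`, `nfolds = n`, deterministic
fold assignment, predictors standardized internally) and retains the
nonzero coefficients at the CV-minimal $\lambda$. `ols_report()` refits the
retained set by least squares and reports coefficients, $R^2$, adjusted
$R^2$, the F test and Cohen's $f^2 = R^2/(1-R^2)$. At $n = 23$ the
CV-minimal rule is deliberately liberal; selection stability across seeds
is the property to look at, and the acceptance suite exercises exactly
that.

## 8. Limitations

- $\sigma_v$ recovery from reach errors alone is weak; the task reads out
  the proprioceptive estimate, so vision enters only through the attraction
  term.
- The simulation likelihood inherits kernel-density bias at sharp modes;
  the 0.1° bandwidth floor trades a little sharpness for robustness.
- The PJ staircase saturates outside its capture range, compressing large
  proprioceptive noise into similar $\sigma_{PJ}$ values.
- The synthetic cohort emulates the *statistical structure* of an aging
  study, not any particular dataset; its effect sizes are calibrated, and
  conclusions drawn from it are about the pipeline, not about aging.
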