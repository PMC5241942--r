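---
title: "Predicting maximum strength moments from theoretical Grade 3 moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting maximum strength moments from theoretical Grade 3 moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtstrength)
```

## The problem

Manual muscle testing grades strength on an ordinal 0–5 scale by felt
resistance, which makes most grades subjective. Grade 3 is the exception:
"moves through the full range of motion against gravity only" is an external
criterion, and the muscular moment it demands is exactly the maximal
gravitational moment on the limb segment — computable from body mass,
segment lengths and anthropometric segment parameters. If the maximum
isometric strength moment measured with a handheld dynamometer (HHD) is
linearly related to this theoretical Grade 3 moment, a clinician can predict
the maximum strength a subject of a given physique *should* have, and
compare the measurement against it. This package implements that chain for
hip and knee flexion/extension in three adult age groups.

## The moment model

For a subject of body mass $m$ (kg), thigh length $L_1$ and lower-leg length
$L_2$ (m), with sex-specific segment mass fractions $k_1$ (thigh; men 0.1,
women 0.1115) and $k_2$ (lower leg plus foot; men 0.0725, women 0.0685),
centre-of-gravity distance ratios $K_1 = 0.42$ and $K_2 = 0.51$, and
$g = 9.8$ m/s² (used exactly, not 9.80665 — the value the reference
computations employ):

$$M_f^{hip} = m\,g\,L_1\,(k_1 K_1 + k_2), \qquad
  M_f^{knee} = m\,k_2\,g\,K_2\,L_2.$$

The hip expression sums the thigh's own weight acting at $K_1 L_1$ and the
weight of the lower leg and foot hanging at the knee, i.e. at the full
$L_1$; both hip tasks (seated flexion, prone extension) use this one value,
and likewise both knee tasks share $M_f^{knee}$. The hip-task formula is
applied to prone hip extension as well, although the gravity geometry of the
prone position differs from the seated one; this mirrors the normative
protocol the built-in coefficients come from, and the prediction chain is
only consistent with those coefficients if the same convention is kept.

The maximum strength moment adds the HHD's resisting force $F$ (the mean of
exactly two trials — more or fewer trials is treated as an input error, not
silently tolerated) times its lever arm:

$$M_m^{hip} = M_f + F\,\ell_1, \qquad M_m^{knee} = F\,\ell_2.$$

For hip tasks the muscle holds the limb against gravity *and* the sensor, so
$M_m \ge M_f$ with equality at zero effort; for the seated knee tasks the
lower leg hangs vertically at rest, the gravitational term vanishes at the
measurement position, and $M_m = F \ell_2$. The sensor sits at the distal
one-third of the segment, so the default lever arm is $2/3$ of the segment
length, measured from the proximal landmark (greater trochanter or
knee-joint space); per-subject lever arms can override the default through
the input columns `lever_hip_m` / `lever_knee_m`.

```{r}
male <- constants_for_sex("male")
c(hip = mf_hip(65, 0.35, male), knee = mf_knee(65, 0.40, male))
```

## The statistical pipeline

Per task and age group the pipeline follows a gated two-step protocol: a
two-sided Pearson no-correlation test (the exact $t$ transform
$t = r\sqrt{(n-2)/(1-r^2)}$), and only when it rejects at $\alpha$ (0.05
throughout) an ordinary least-squares fit $M_m = a M_f + b$. The gate is not
decorative: in the normative data, knee flexion in the eldest group shows no
correlation, so that cell has no regression line, is excluded from the
knee-flexion ANCOVA, and the built-in predictor refuses it rather than
falling back to another group.

The per-task group comparison is a three-step ANCOVA with $M_f$ as
covariate:

1. **Parallelism** — F test of the `mf:group` interaction in
   `mm ~ mf * group`. If it rejects, the group lines have different slopes,
   covariate-adjusted means are not comparable, and the analysis stops.
2. **Common slope** — Type II F test that the shared slope in
   `mm ~ mf + group` is nonzero (via `car::Anova`; Type II is stated
   explicitly because the choice is otherwise invisible).
3. **Adjusted comparisons** — pairwise differences of estimated marginal
   group means at the grand mean of $M_f$ (`emmeans`), Bonferroni-adjusted
   over the three pairs. The adjustment method is configurable; Bonferroni
   is the default because it is the most conservative common choice and the
   normative report does not name one.

Group summary ratios use the ratio-of-means convention,
$100\cdot\bar{M_f}/\bar{M_m}$, which reproduces the published percentages
(e.g. 25.9/63.7 → 40.7%), not the mean of per-subject ratios.

## The clinical predictor

`builtin_prediction_model()` carries the eleven published regression lines;
`predict_from_anthropometrics()` chains the moment model into them. One
reporting convention matters: moments are reported to one decimal in N·m,
and the predictor substitutes the *rounded* $M_f$ into the line — the value
a clinician reads off a report — rather than the full-precision one. The two
conventions disagree at the display precision for three of the four tasks
of the canonical example (e.g. hip extension: 58.5 via the rounded path,
58.6 via full precision); the rounded path is the one consistent with the
published example, so it is the default, with `round_mf = FALSE` available.
Internally all moments are computed and stored at full precision.

```{r}
worked_example()
```

Predictions for groups B and C carry a warning attribute: their published
coefficients of determination (0.14–0.49) are well below group A's
(0.45–0.58), so the prediction is quantitatively trustworthy for young
adults only.

## The cohort simulator

No subject-level data are distributed, so the simulator exists to make the
whole pipeline testable: it generates raw measurement tables — never
moments — whose *recomputed* statistics match the published group numbers.

The generator works backwards from the published moment distributions,
because those are what the normative tables report, while segment-length
distributions are not:

1. sex by the published group counts; body mass from the published group
   normal (mean ± SD);
2. hip and knee $M_f$ from a bivariate normal with the published means/SDs,
   correlation 0.6 (an artifact parameter standing in for shared body size
   — no cross-task covariance is published; configurable), truncated below
   at 3 N·m;
3. thigh and lower-leg lengths back-solved from the $M_f$ values through
   the moment formulas; subjects whose implied lengths leave [0.2, 0.7] m
   are redrawn (bounded retries, counted in the provenance);
4. latent $M_m$ per task from the published line plus Gaussian noise with
   $\sigma_\epsilon = |a|\,\sigma_{M_f}\sqrt{(1-R^2)/R^2}$, which makes the
   population $R^2$ equal the published coefficient of determination; for
   the one task-group cell without a correlation, $M_m$ is drawn
   independently from the published mean/SD;
5. force back-solved by inverting the $M_m$ formulas with distal-1/3 lever
   arms and truncated at zero, then emitted as two trials with a symmetric
   relative jitter (±2% at most) that cancels exactly under the two-trial
   mean.

The noise calibration is internally coherent with the published tables: the
implied total $M_m$ SD, $|a|\sigma_{M_f}/\sqrt{R^2}$, reproduces every
published $M_m$ SD within 2%. Homoscedastic Gaussian noise is assumed
because the OLS/ANCOVA pipeline assumes it; the simulator deliberately does
not model fatigue, compensatory movement, heavy-tailed individual variation
or within-subject trial correlation, so passing tests demonstrate the
pipeline's correctness on data satisfying its own assumptions, not
robustness on real cohorts.

```{r}
cohort <- simulate_cohort(builtin_group_specs()$A, seed = 1)
cohort
res <- run_full_analysis(lapply(builtin_group_specs(), simulate_cohort, seed = 7))
res$summary
```

## Numerical and design choices

- **Formula grouping.** The hip expression is evaluated as
  $m g L_1 (k_1 K_1 + k_2)$; the canonical 65 kg example (25.5 N·m) pins
  this down, and the test suite asserts it before anything builds on it.
- **Degenerate inputs.** Zero or negative masses, lengths and lever arms
  are rejected; zero force is valid (it yields $M_m = M_f$ for hip tasks
  and 0 for knee tasks). Regression needs $n \ge 3$; the correlation gate
  needs nonzero variance in both variables.
- **Determinism.** Every stochastic entry point takes an explicit seed and
  restores the RNG state afterwards; `simulate → analyze → write` is
  byte-identical across runs at a fixed seed.
- **Problem sizes.** Calibration checks use 200 replicates of the
  published group sizes (40/46/44); the no-correlation type-I check uses
  2,000 null simulations at $n = 40$. At these sizes Monte-Carlo error is
  small against the asserted bands (binomial SD ≈ 0.5% at 2,000 draws).
- **Truncation effects.** The plausibility redraws (step 3) clip the low
  tail of the $M_f$ distribution slightly, which shrinks the realized
  $M_m$ SD a few percent below its analytic target; the calibration checks
  account for this by testing at the 10% coherence band, and truncation
  events are counted in the cohort provenance so they remain auditable.

## Known limitations

The built-in coefficients describe healthy Japanese adults measured without
torso/pelvis restraints in specific limb positions; predictions do not
transfer to other populations, restrained protocols or other joint angles.
ANCOVA p-values published for the normative cohort depend on its raw data
and cannot be reproduced from summary statistics; the package reproduces
them only qualitatively (which decisions fall where at $\alpha = 0.05$
in the majority of simulated cohorts). Prediction intervals are not
provided — only point predictions from the fitted lines.
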