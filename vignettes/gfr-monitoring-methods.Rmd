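---
title: "Models and methods behind gfrmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gfrmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfrmon)
```

`gfrmon` evaluates how well serum-biomarker estimates of glomerular
filtration rate (eGFR) track *change* in reference measured GFR (mGFR) over
years of follow-up in moderate chronic kidney disease. This vignette is the
package's own account of the statistical machinery: the models, the
conventions that had to be fixed where the field leaves room, the synthetic
cohort the tests run on, and what those tests do and do not demonstrate.

## Estimating equations

Eight published equations are implemented, all returning
body-surface-indexed GFR (mL/min/1.73 m²) from serum creatinine (Scr,
mg/dL internally; the API accepts µmol/L and divides by 88.4) and/or serum
cystatin C (Scys, mg/L), with age and sex.

The CKD-EPI family has the piecewise power form

$$\mathrm{eGFR} = A \cdot \min(m/\kappa, 1)^{\alpha}
  \cdot \max(m/\kappa, 1)^{\beta} \cdot g^{\mathrm{age}}
  \cdot f_{\mathrm{sex}} \;[\cdot\, f_{\mathrm{race}}]$$

per marker (the combined equations multiply one such term per marker). The
EKFC family rescales each marker by a reference median $Q$ and applies

$$\mathrm{eGFR} = 107.3 \,/\, (m/Q)^{x} \cdot
  0.990^{\max(\mathrm{age}-40,\,0)},\qquad
  x = \begin{cases}0.322 & m/Q < 1\\ 1.132 & m/Q \ge 1,\end{cases}$$

with sex-specific creatinine $Q$ (0.70 / 0.90 mg/dL for women / men) and an
age-dependent cystatin $Q$ (0.83 mg/L below age 50, increasing by
0.005 mg/L per year above 50). The EKFC combined estimate is the arithmetic
mean of its two single-marker estimates, as published. All coefficients
live in one declarative registry (`equation_registry()`, serialisable with
`equation_registry_json()`) so they can be audited against the source
publications rather than hunted through code.

Design choices in this module:

- **Race term.** The historical 1.159 / 1.08 coefficients of the 2009/2012
  CKD-EPI equations sit behind `apply_race_term` (default `FALSE`),
  matching contemporary UK practice; the 2021 revisions and the EKFC
  equations have no such coefficient and ignore the flag by construction.
- **Adults only.** Ages below 18 are rejected; the adult sex-specific EKFC
  creatinine $Q$ constants are used for all ages ≥ 18 rather than the
  paediatric/young-adult growth-curve interpolation, which is immaterial
  for a cohort with median age 67.
- **Continuity.** Each closed form is continuous at its knot
  ($m = \kappa$, $m/Q = 1$); the test suite verifies this numerically to
  relative tolerance 1e−6 under ±1e−9 perturbations, along with strict
  monotonicity in each biomarker and non-increase in age on
  creatinine ∈ (0.1, 20] mg/dL, cystatin ∈ (0.1, 10] mg/L, age ∈ [18, 100].

A conformance fixture of 144 input/output rows (all eight equations, both
sexes, ages 25/50/80, marker levels below/at/above every knot) was
generated by an independent brute-force script before the R implementation
was written, and the implementation is tested against it.

## Staging and the progression classifier

KDIGO G-categories use half-open intervals with the lower bound in the
*less* severe category: [90, ∞) G1, [60, 90) G2, [45, 60) G3a, [30, 45)
G3b, [15, 30) G4, (0, 15) G5. So exactly 45 is G3a, matching the printed
"45–59" convention under 1-decimal reporting; a convention had to be fixed
and this is it.

Progression between two visits requires **both** a relative reduction of at
least 25% (inclusive) **and** a strictly worse G-category at follow-up, of
any number of steps. Albuminuria-category changes are out of scope: the
classifier is GFR-only.

## Slopes

- `two_point_slope`: (follow-up − baseline) / elapsed years, with elapsed
  years defined as actual calendar days / 365.25. Percentage slopes divide
  by the *observed baseline value* of the same source — not a fitted
  intercept — for every slope method, so the two scales stay comparable.
- `ols_slope`: per-individual least squares of value on years since first
  visit; identical to the two-point slope when there are exactly two
  visits.
- `mixed_model_slopes`: one model for the whole cohort,
  $y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t_{ij} +
  \varepsilon_{ij}$ with unstructured 2×2 random-effect covariance, fitted
  by maximum likelihood (`lme4::lmer`, `REML = FALSE`). Per-participant
  slopes are $\beta_1 + \hat b_{1i}$ (BLUPs), which shrink noisy individual
  slopes toward the population mean. Participants with a single visit carry
  no slope information of their own and are assigned the population slope
  (the literal BLUP would add a small correlation-induced shift through the
  random intercept; we regard that as an artefact for this use). If the fit
  errors out entirely the function falls back to per-individual least
  squares and says so in a `method` column; singular fits (zero random
  variance) are accepted, in which case everyone's slope collapses to the
  population slope, as it should.

Large-error classification mirrors the two criteria's stated typography:
the absolute criterion is **inclusive** (|error| ≥ 3 mL/min/1.73 m²/yr is
large), the percentage criterion **exclusive** (only differences strictly
beyond ±5 %/yr are large). For continuous data the distinction is
irrelevant; for constructed boundary cases it is fixed and tested.

## Agreement and diagnostic accuracy

Exact binomial (Clopper–Pearson) intervals are computed in the
beta-quantile form, with the conventional 0/1 bounds at $k = 0$ / $k = n$.
The tests compare them, for every $(k, n)$ with $n \le 50$, against an
independent oracle that inverts the binomial tail probabilities by
bisection, to 1e−9.

McNemar's paired test reports both the exact two-sided binomial p-value on
the discordant pairs and the asymptotic chi-square without continuity
correction; the exact value is primary when the discordant total is ≤ 25
(discordant counts here can be small). Zero discordant pairs give p = 1 by
convention. The paired agreement difference uses a Wald interval on the
discordant counts; the method behind any published interval for this
quantity is not standardised, so ours is labelled for what it is, and only
the point difference is treated as reproducible.

Sensitivity, specificity, PPV and NPV each carry an exact interval; a
metric with a zero denominator is reported as missing rather than invented.
P30 uses an inclusive boundary (|est − meas| / meas ≤ 0.30). Bias is the
median of (estimated − measured) at a timepoint; change summaries are
medians with IQRs of within-person (follow-up − baseline), grouped by
measured progression status. No multiple-testing adjustment is applied
anywhere, deliberately: the equations under comparison are strongly
dependent, and the analysis reports estimates with intervals rather than a
family of accept/reject decisions. Report tables round half-up to 1 dp
(`round_half_up`), while machine outputs keep full precision.

## The synthetic cohort

`simulate_cohort()` exists so that every stage of the pipeline can be
exercised, end to end and with known ground truth, without any patient
data. Its defaults encode the design of a three-year prospective
monitoring study of moderate CKD:

| Parameter | Default | Status |
|---|---|---|
| Evaluable participants | 875 (from ~1229 recruited, 875/1229 evaluable fraction) | design |
| Male fraction | 0.577 | design |
| Age | two-piece normal, median 67.1, IQR 58.1–73.6, truncated [18, 95] | design |
| Baseline true GFR | log-normal, median 48.1, IQR 40.2–57.2 | design |
| Progressor fraction | 0.159 | design |
| True slopes | progressors N(−5.5, 1.5²), others N(−1.0, 1.5²) mL/min/1.73 m²/yr | assumption |
| mGFR measurement CV | 0.05 (multiplicative log-normal) | assumption |
| Biomarker visit CV | 0.05 | assumption |
| Person-level biomarker bias SD | 0.10 (log scale) | assumption |
| Non-GFR drift | 0 /yr (settable) | assumption |
| Visit schedule | biomarkers 6-monthly ×7; mGFR at 0 and 36 months for all, extra at 12 months (n = 215) and 24 months (n = 188), scaled with cohort size | design |

Rows marked *design* restate the study structure the generator emulates;
rows marked *assumption* are modelling choices the study does not report
(within-person mGFR variability is cited to external work there), chosen
once at what a kidney-function laboratory would consider realistic levels,
and not revisited.

Generation works backwards from latent truth: each participant gets a
linear true-GFR trajectory (floored at 5 mL/min/1.73 m²), observed mGFR is
truth times log-normal noise, and biomarkers are manufactured by *inverting*
a configured single-marker equation (bisection in log-concentration space,
tolerance 1e−8 — each equation is strictly decreasing in its marker) at the
person-biased, optionally drifting, biomarker-implied GFR, then adding
visit-level noise. Two-piece-normal ages match the skewed printed quartiles
exactly at the quartiles. Everything is deterministic given the seed, and
the latent truth ships alongside the observations for recovery tests.

The **drift** parameter makes the biomarker-implied GFR decline more slowly
than true GFR (rate per year on the log scale), emulating the mechanism by
which estimated GFR underestimates decline (e.g. rising tubular and
extra-renal creatinine elimination as disease progresses). With drift of
0.01/yr the pipeline reproduces the qualitative finding that the median
estimated change is smaller in magnitude than the median measured change,
in progressors and non-progressors alike. Note the property is stated for
*modest* drift: a drift rate comparable to a subgroup's own fractional
decline rate (e.g. 0.04/yr against the ~2%/yr decline of non-progressors)
can reverse the sign of that subgroup's small estimated changes, at which
point magnitude comparisons stop being meaningful.

What passing tests on this cohort do **not** show about real data: the
generator has linear trajectories, non-informative dropout, a clean
two-component slope mixture, and noise that is independent across visits.
Real cohorts have none of these guarantees; in particular the agreement
percentages the pipeline produces on synthetic data are systematically
higher than published cohort values because the generator's biomarkers are
(by construction) consistent with one generating equation per marker. The
package therefore validates its *machinery* against published count tables
(reproducing printed percentages, intervals and diagnostic metrics exactly
from printed numerators), and validates its *pipeline* by parameter
recovery on synthetic data — the two validations are deliberately separate.

## Evaluable-cohort construction

`run_analysis()` mirrors a single-denominator design: a participant is
evaluable when they have measured GFR at two visits at least
`min_followup_years` apart (default 2.5, against a nominal 36-month
follow-up) and *every* requested equation is computable at both of those
visits. All agreement, diagnostic, P30 and bias blocks share that one
denominator; the filtering counts are recorded in the report. Age is
advanced to the sampling date (baseline age plus elapsed years) for each
visit's estimates, matching how the generator inverts the equations.

## Numerical conventions

- Year length 365.25 days, everywhere.
- Bisection (80 iterations, log-space) for equation inversion; round trips
  recover targets to 1e−6 relative.
- ML rather than REML for the mixed model, so that the fit is a single
  well-defined likelihood optimum; the covariance structure is
  unstructured.
- Half-up rounding to 1 dp for printed tables only.
- Problem sizes in the test suite: unit and property tests run cohorts of
  40–200 participants and 10⁴ random biomarker panels; the parameter
  recovery checks run the full 875-participant design three times (noise
  free, default noise, drifted). These sizes give Monte-Carlo error
  comfortably inside the asserted bounds while keeping the default suite
  quick.

## Known limitations

- The progression classifier is GFR-only; albuminuria staging is carried as
  data but never analysed.
- No joint modelling of dropout, no nonlinear trajectories, no
  accelerated-progression (NICE-style) or rapid-progression (>5/yr)
  classifiers.
- The paired-difference interval is a Wald interval; exact methods for
  paired differences exist and may disagree in small samples.
- Raw (non-indexed) GFR and body-surface-area de-normalisation are out of
  scope; everything is per 1.73 m².
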