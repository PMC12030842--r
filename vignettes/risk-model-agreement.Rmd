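---
title: "Projecting radiation-induced cancer risk and comparing model families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting radiation-induced cancer risk and comparing model families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(radoncrisk)
```

## The problem

Patients in intensive care accumulate substantial ionising-radiation exposure
from bedside radiographs, fluoroscopy-guided procedures and repeated CT over
a single admission — cumulative effective doses of tens of mSv are routine.
Several frameworks exist for turning such a dose into a projected lifetime
cancer risk (the BEIR VII report, ICRP Publication 103, the US EPA
methodology), and they disagree in structured ways: different weightings of
the two epidemiological projection pathways, different dose-rate corrections,
different site coverage and reporting conventions. This package implements
the full chain — exposure log to cumulative effective dose to per-site risk
under several configurable model families to formal inter-model agreement
statistics — so that the variability between families can be quantified on
any cohort, real or synthetic.

## From exposure events to cumulative effective dose

Each irradiation event carries the dose metric its modality actually
records:

* **radiograph** — no per-event metric; a per-region median effective dose
  (mSv) is looked up,
* **fluoroscopy / interventional** — dose–area product (DAP, mGy·cm²),
  converted as effective dose = k × DAP with k in mSv/(mGy·cm²),
* **CT** — dose–length product (DLP, mGy·cm), converted with a per-region
  coefficient in mSv/(mGy·cm). This deterministic coefficient is a
  documented stand-in for phantom-matched Monte Carlo organ dosimetry,
  which is out of scope.

A precomputed `effective_dose_msv` on an event overrides the conversion.
The per-patient cumulative effective dose is the plain sum over the
admission's events; scout and bolus-tracking acquisitions are simply not
event rows. The bundled conversion factors
(`default_conversion_factors()`) are order-of-magnitude-typical
placeholders and fully replaceable via YAML
(`read_conversion_factors()`).

## The lifetime-risk engine

For one exposure of dose $D$ Gy at age $e$, the lifetime attributable risk
of a cancer site is

$$\mathrm{LAR}(D, e) = \int_{e+L}^{a_{\max}} M(D, e, a)\,
  \frac{S(a)}{S(e)}\, da,$$

where $M(D,e,a)$ is the excess absolute cancer rate at attained age $a$,
$S(a)/S(e)$ the conditional probability of remaining alive and cancer-free,
$L$ the minimum latency (5 years for solid cancers, 2 for leukemia) and
$a_{\max} = 100$ years. The excess rate is projected along two pathways
sharing one functional form,

$$\beta \cdot D \cdot \exp(\gamma e^{*}) \cdot (a/60)^{\eta}, \qquad
  e^{*} = \frac{\min(e, 30) - 30}{10},$$

multiplicative on the baseline incidence $\lambda_c(a)$ for the excess
*relative* risk (ERR) pathway, and additive (with $\beta$ in excess cases
per 10⁴ person-year-Gy) for the excess *absolute* risk (EAR) pathway. The
two pathway LARs are combined by a weighted arithmetic or weighted
geometric mean, the choice and weights being properties of the model
family. Solid-site linear components are divided by the family's DDREF
(dose and dose-rate effectiveness factor); leukemia instead uses a
linear-quadratic dose response $D(\beta + \theta D)$ with no DDREF, the
curvature playing that role at low dose. ICRP-style families can replace
LAR with REIC (risk of exposure-induced cancer), which weights the
integrand by the *exposed*-cohort survival — baseline survival depleted by
the accumulated excess hazard; the two agree within 1% at 0.1 Gy on the
package's toy tables and converge as dose → 0.

Key tunable parameters, with the bundled defaults:

| parameter | units | default(s) | meaning |
|---|---|---|---|
| `w_ear`/`w_err` | – | 0.3/0.7 (BEIR VII-, EPA-like), 0.5/0.5 (ICRP-like) | pathway weights |
| `ddref` | – | 1.5, 2 (ICRP-like) | divisor on solid linear components |
| `combination` | – | geometric (BEIR VII-like), arithmetic (others) | pathway-combination rule |
| `latency_solid`, `latency_leukemia` | years | 5, 2 | minimum latency |
| `leukemia_quadratic_theta` | Gy⁻² | 1.0 | leukemia dose-response curvature |
| `scaling` | – | per-100,000-per-0.1 Gy or per-10,000-per-Gy | reference-table convention |

### Reference tables and the AOR

`build_lar_table()` evaluates the engine at the family's reference dose
(0.1 Gy or 1 Gy) on a decade grid of exposure ages (20–90) and scales to
the declared denominator. At analysis time the reference LAR is linearly
interpolated at the patient's age (a 75-year-old gets the midpoint of the
70- and 80-year values; ages outside the grid are clamped to the nearest
endpoint, no extrapolation) and scaled linearly by the patient's cumulative
effective dose — the linear no-threshold assumption. Every convention is
normalised to the per-100,000-persons scale, so the additional oncogenic
risk (AOR) is

$$\mathrm{AOR} = \mathrm{LAR}_{\mathrm{ref}} \times \frac{D_{\mathrm{Gy}}}{0.1}
  \quad\text{or}\quad
  \mathrm{LAR}_{\mathrm{ref}} \times D_{\mathrm{Gy}} \times 10 .$$

Effective dose in mSv is treated as numerically equal to absorbed dose in
mGy (radiation weighting factor 1 for X-rays), and the whole-body
cumulative effective dose is used as the organ dose for every site. Both
are deliberate modelling simplifications: the first is exact for photons,
the second overstates organ doses for exposures that never irradiated the
organ, and is inherited from projecting risk off a single cumulative dose
number.

Aggregates are `all_solid` (sum over the solid sites the model covers for
that sex), `leukemia`, and `all_cancer = all_solid + leukemia`. A site a
family does not cover is reported as an explicit not-estimated marker —
never zero — so agreement statistics can exclude it listwise.

## The bundled model families are illustrative

The engine is coefficient-table-driven. The three bundled families
(`illustrative_risk_models()`) reproduce the *structural* contrasts of the
published frameworks — pathway weights, DDREF, combination rule, reporting
convention, site coverage, and a single shared estimate for both sexes in
the EPA-like family — but their numeric β, γ, η, baseline incidence curves
and life table are an illustrative catalogue chosen for plausible
magnitude, not the official publications' coefficient tables (reproducing
those is explicitly out of scope). Consequently cohort risk numbers
produced with the bundled tables illustrate the machinery; only their
structural behaviour (orderings, agreement patterns) is meaningful. All
tables are user-replaceable: model specs via `read_model_spec()` /
`write_model_spec()` (YAML, schema-versioned), life tables and baselines
via their constructors.

With DDREF 2 against 1.5, a 0.5/0.5 pathway weighting and narrower male
site coverage, the ICRP-like family projects the lowest all-cancer median
AOR of the three on a default synthetic cohort — the same direction the
published comparison reports; the acceptance suite asserts exactly this
ordering and nothing numeric about it.

## Agreement statistics

`agreement_report()` runs the comparison battery on a patients × models
matrix for one site:

* **Friedman rank test** — within-patient mid-ranks, tie-corrected
  statistic referred to χ²(k−1); for fewer than 5 patients the p-value is
  computed by exhaustive enumeration of all within-row permutations. A
  fully tied matrix returns statistic 0, p = 1 by contract.
* **Consistency ICC** — two-way model, single measurement, ICC(C,1) =
  (MS_rows − MS_err) / (MS_rows + (k−1)MS_err), models treated as fixed
  raters; 95% CI by the F-distribution method; categories poor (< 0.5),
  moderate (≥ 0.5), good (≥ 0.75), excellent (≥ 0.9), left-closed. The
  Shrout–Fleiss form is a deliberate, documented choice; zero
  between-patient variance flags the coefficient undefined rather than
  erroring.
* **Bland–Altman** — bias = mean(x−y), limits of agreement bias ±
  1.96·SD(x−y) (sample SD), with the per-pair (mean, difference) points
  for plotting.
* **Pearson r** and **orthogonal regression** — total least squares with
  error-variance ratio 1; the slope follows the principal axis of the 2×2
  covariance matrix.

Shapiro–Wilk normality screening is reported per model column but is
advisory only: risk distributions here are right-skewed, so the pipeline
always uses the rank-based omnibus test.

## The synthetic cohort generator

`generate_cohort(cohort_spec())` emulates the statistical structure of a
71-patient adult ICU cohort: 58/71 male; ages from an asymmetric two-piece
normal matched to the printed quartiles (56, 66, 71), truncated to
[18, 99]; per-patient cumulative doses from the two-parameter lognormal
whose theoretical quartiles equal the printed IQR bounds (17.34, 84.64)
mSv — implying a median of √(17.34 × 84.64) ≈ 38.3 mSv, within 1.3% of the
printed 38.82; event counts Poisson around 2847/71 ≈ 40 per patient (floor
1); modalities drawn from the 87/9/4% radiograph/CT/fluoroscopy mix.
Hospitalization length is generated (lognormal fit to the printed 15–70
day IQR) for reporting only.

Event dose metrics are *back-solved*: each patient's target dose is split
across their events proportionally to modality-typical weights
(radiograph : fluoro : CT = 1 : 100 : 300), then fluoro events invert
DAP = dose/k and CT events invert DLP = dose/ct_k, while radiograph events
carry the effective-dose override (their engine path is a fixed per-region
median that cannot be inverted per event). This guarantees the cohort dose
distribution matches the calibrated lognormal exactly and makes the
generator → dose-engine round trip exact to floating-point error. What the
generator deliberately does **not** model: correlation between age, length
of stay and dose; the time course of exams within a stay; admission
diagnoses. Passing tests on synthetic cohorts therefore demonstrate the
machinery and the stated distributional margins — not fidelity to any
joint structure of real ICU data.

The lognormal choice itself is a modelling decision: the printed summary
(right-skewed, positive, median/IQR only) determines exactly two
parameters, and the lognormal is the standard two-parameter family with
that support.

## Numerical and convention choices

* **Quadrature**: annual-step trapezoid over integer ages, matching
  life-table granularity; the integral's lower limit $e + L$ is rounded up
  to the next integer age. Validated against 0.1-year-step oracles within
  0.5% relative on toy tables.
* **Quantiles**: all medians/IQRs use the (n+1)p convention
  (`quantile(type = 6)`, the method of common clinical statistics
  packages); on three ordered values the quartiles are the extremes. Fixed
  once, package-wide, for reproducibility.
* **Geometric mean at zero**: defined as 0 when either pathway value is 0
  (continuity from below, avoids log-domain failure).
* **Sex-specific sites**: breast/ovary/uterus/prostate are excluded from
  the non-applicable sex's coverage and contribute 0 to its aggregates.
* **Degenerate inputs**: empty integration range (e + L > amax) yields
  LAR 0; S(e) = 0 is an error; a fully tied Friedman matrix and a
  zero-variance ICC are flagged contracts, not exceptions.

## Problem sizes used by the test suite

The suite exercises parameter recovery at 50,000 synthetic patients
(~2 × 10⁶ events, quartiles within 2%, mix and sex fraction within
±0.02), the lognormal median check at 100,000 draws, white-noise ICC at
10,000 rows, and exact Friedman enumeration at n = 4, k = 3 — sizes at
which the stochastic margins above are comfortably stable. The whole suite
runs in well under a minute.

## A worked run

```{r example}
models <- illustrative_risk_models()
lt <- illustrative_life_table()
bls <- illustrative_baselines()
tables <- lapply(models, build_lar_table, lt = lt, baselines = bls)

cohort <- generate_cohort(cohort_spec(seed = 1))
cohort_report(cohort$patients)
cohort_dose_summary(cohort$patients)

results <- cohort_aor(cohort$patients, tables)
cohort_risk_summary(results)

agreement_report(results, "all_cancer")
```

## Known limitations

* Incidence only — mortality LAR, heritable effects and projection beyond
  age 100 are out of scope.
* Single-admission scope: the age used for interpolation is age at
  admission; multi-admission dose accumulation is not modelled.
* No uncertainty intervals on AOR (the projection is a point calculation).
* The CT DLP coefficient replaces patient-specific Monte Carlo dosimetry;
  organ-level dose maps are not computed.
* Bundled tables are illustrative (above); absolute risk numbers from them
  should never be quoted as model-family estimates.
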