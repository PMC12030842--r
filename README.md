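# radoncrisk

Radiation-induced cancer-risk projection and inter-model agreement for
cumulative imaging exposure.

Critically ill patients accumulate ionising-radiation exposure from bedside
radiographs, fluoroscopy-guided procedures and repeated CT over a single
admission — cumulative effective doses of tens of mSv. Several frameworks
project such a dose into lifetime cancer risk (BEIR VII, ICRP 103, the US
EPA methodology), and they disagree in structured ways. `radoncrisk`
implements the whole chain for quantifying that disagreement:

1. **Dose engine** — per-event effective dose (radiograph region lookup,
   k × DAP for fluoroscopy, DLP coefficient for CT) summed to a per-patient
   cumulative effective dose.
2. **Risk engine** — lifetime attributable risk from one exposure at age
   *e*:

   LAR(D, e) = ∫ from e+L to a_max of M(D, e, a) · S(a)/S(e) da,

   with excess rate M projected along the ERR and EAR pathways
   (β·D·exp(γe\*)·(a/60)^η; multiplicative on baseline incidence for ERR,
   absolute for EAR), latency L (5 y solid, 2 y leukemia), survival
   weighting from a life table, DDREF division of solid linear components,
   linear-quadratic leukemia response D(β + θD), and a weighted arithmetic
   or geometric pathway combination. An ICRP-style REIC variant (exposed-
   cohort survival) is included.
3. **AOR pipeline** — reference-dose LAR tables per model × sex × site ×
   exposure-age decade, interpolated at the patient's age and scaled
   linearly by dose (linear no-threshold), normalised to excess cases per
   100,000 persons; per-site results plus `all_solid`, `leukemia`,
   `all_cancer` aggregates.
4. **Agreement statistics** — Friedman rank test (exact by enumeration for
   n < 5), consistency ICC(C,1) with F-based 95% CI and the
   poor/moderate/good/excellent categories, Bland–Altman limits of
   agreement, Pearson r, and orthogonal (total least squares) regression.
5. **Synthetic ICU cohort generator** — 71 patients, 58 M / 13 F, age
   quartiles (56, 66, 71), lognormal cumulative dose calibrated to the
   17.34–84.64 mSv IQR, 87/9/4% radiograph/CT/fluoroscopy mix, ~40 events
   per patient, fully deterministic given a seed.

The bundled coefficient tables, baseline incidence curves and life table
are **illustrative**: they reproduce the structural contrasts between the
model families (pathway weights, DDREF, combination rule, site coverage,
reporting convention), not the official publications' coefficients. All
tables are user-replaceable via YAML/CSV configs (see
`inst/extdata/`).

## Worked example

```r
library(radoncrisk)

models  <- illustrative_risk_models()        # BEIR VII-, ICRP 103-, EPA-like
lt      <- illustrative_life_table()
bls     <- illustrative_baselines()
tables  <- lapply(models, build_lar_table, lt = lt, baselines = bls)

cohort  <- generate_cohort(cohort_spec(seed = 1))
cohort_dose_summary(cohort$patients)
#> Cumulative effective dose, n = 71 patients
#>   overall  median 36.78 mSv (IQR 15.85-96.68)
#>   male     median 31.68 mSv (IQR 13.57-70.45)
#>   female   median 96.68 mSv (IQR 39.10-247.24)

results <- cohort_aor(cohort$patients, tables)
s <- cohort_risk_summary(results)
tail(s$wide, 3)
#>        site         BEIR VII-like         ICRP 103-like           US EPA-like
#>   all_solid 150.01 (66.02-376.96) 106.47 (46.92-267.43) 155.88 (70.45-402.24)
#>    leukemia    18.62 (9.09-47.94)   31.38 (15.35-79.95)   34.72 (16.13-93.72)
#>  all_cancer 170.78 (75.11-429.77) 141.53 (62.22-356.56) 189.96 (86.58-495.96)

agreement_report(results, "all_cancer")
#> Agreement report, site 'all_cancer' (n = 71 patients, 3 models)
#> Friedman rank test: chi2 = 123.4, df = 2, p = 1.593e-27 (chi-square, n = 71)
#> ICC(C,1) = 0.978 (95% CI 0.968-0.986), excellent agreement
#> ...
```

Reading: with the illustrative tables, a median synthetic patient
(~37 mSv) carries a projected additional all-cancer risk of roughly 140–190
excess cases per 100,000 persons depending on the model family. The
families rank patients almost identically (ICC excellent) while assigning
systematically different magnitudes (Friedman p ≪ 0.001), and the
ICRP-like family — DDREF 2, 0.5/0.5 pathway weights, narrower male site
coverage — projects the lowest all-cancer median. Because the coefficient
tables are illustrative, the orderings and agreement patterns are the
meaningful output, not the absolute numbers.

A thin command-line wrapper over the same functions ships in
`inst/cli/radoncrisk.R` with `simulate`, `aor` and `agree` subcommands.

The methods vignette (`vignettes/risk-model-agreement.Rmd`) documents the
model, its assumptions, every convention (quadrature, quantile type,
clamping, degenerate cases) and the generator's scope.

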