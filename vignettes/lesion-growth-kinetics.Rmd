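---
title: "Volumetric tumor growth kinetics: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric tumor growth kinetics: model, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionkinetics)
```

This vignette is the package's account of its science: the measurement and
growth model, the tunable parameters and why their defaults are what they
are, what the synthetic-cohort generator does and does not emulate, and the
numerical policies applied at edge cases. It states no empirical result that
the test suite or the acceptance script does not itself compute.

## Setting

In stage IV small intestinal neuroendocrine tumors (SI-NETs), the mesenteric
lymph node metastasis (MLNM) — often a single conglomerate mass encased in
desmoplastic fibrosis — is the lesion whose growth determines whether an
initially asymptomatic patient will eventually need surgery. Cohorts in this
setting are followed with serial CT; the radiologist records, per scan, the
maximal diameter of the mass in the transverse, coronal and sagittal planes.
The package turns those tri-planar measurements into volumes, volumes into
growth rates, and growth rates plus clinical covariates into the standard
cohort-level statistical surface.

## Measurement model: ellipsoid volumetry

A lesion with plane-wise maximal diameters $d_1, d_2, d_3$ (mm) is treated as
an ellipsoid with semi-axes $d_i/2$:

$$V = \frac{4}{3}\pi\,\frac{d_1}{2}\frac{d_2}{2}\frac{d_3}{2}
    = \frac{\pi}{6} d_1 d_2 d_3 .$$

Assumptions and conventions:

* **Inputs are full diameters**, not semi-axes — the radiological convention;
  the halving is explicit in the formula.
* The three planar measurements are taken as the three principal diameters
  with no cross-plane reconciliation; no deduplication procedure exists for
  caliper measurements made independently per plane.
* A **conglomerate** measured as a single entity is computationally identical
  to a single lesion; the `is_conglomerate` flag is carried through untouched.
* Millimetres in, mm³ out, always.

`ellipsoid_volume()` is symmetric in its arguments and homogeneous of degree
3; both properties are enforced by tests, since they are what make the
volume-form and diameter-form growth estimators agree.

## Growth model: exponential kinetics and TGR

Between baseline volume $V_1$ and the most recent volume $V_2$, measured $t$
months apart, growth is modelled as exponential, $V_2 = V_1 e^{gt}$, so

$$g = \frac{\ln(V_2/V_1)}{t}, \qquad
  \mathrm{TGR} = 100\,(e^{g}-1)\ \ [\%/\text{month}].$$

Because $V \propto D^3$, the volume form equals the classical diameter form
$g = 3\ln(D_2/D_1)/t$ exactly; the package works in volumes and tests the
equivalence through effective diameters $d = (6V/\pi)^{1/3}$.

Key choices:

* **Natural logarithm throughout** — required for the $e$-based
  back-transform; $g = \ln(1+\mathrm{TGR}/100)$ recovers the constant.
* **Month = 30.4375 days** (365.25/12). Clinical sources rarely define a
  month; this average keeps intervals consistent across leap years.
* **Baseline = earliest scan, follow-up = latest scan**; intermediate scans
  are ignored for the headline per-patient estimate. For symptomatic
  patients with pre-surgical scans the earliest available scan plays the
  baseline role.
* **Minimum interval 2 months**: pairs closer than that estimate noise more
  than growth; such patients are excluded and listed in the exclusion
  report rather than silently dropped.
* **Progression is a strict increase**: $\Delta V > 0$ (equivalently
  $g > 0$, $\mathrm{TGR} > 0$); an exactly unchanged volume is not
  progression. The three formulations are mutually equivalent and tested as
  such.

## Cohort statistics

* **Quantiles** use linear interpolation between order statistics (type 7) —
  the most common software default; nothing in the analysis depends on the
  choice beyond reporting.
* **Continuous group comparisons**: Mann–Whitney U, two-sided. For group
  sizes of at most 8 each, the p-value is exact by full enumeration of all
  $\binom{n+m}{n}$ group assignments (ties handled by midranks inside the
  enumeration); beyond that, the normal approximation with tie correction
  and continuity correction. The exact branch is verified against an
  independent enumeration oracle, the approximate branch against
  `wilcox.test`.
* **Binary group comparisons**: Fisher's exact 2×2 test, two-sided by the
  probability method (summing hypergeometric probabilities not exceeding the
  observed table's). Small cells (single-patient categories are routine in
  44-patient cohorts) make chi-square unreliable, so Fisher is used for all
  2×2 rows; the one three-level row (grade) uses the r×c generalisation from
  `stats::fisher.test`.
* **Kaplan–Meier**: the product-limit estimator with Greenwood's variance
  and 95% CIs on the complementary log–log scale — the transform that keeps
  bounds in $[0,1]$ and a standard default in survival software. Death and
  end of follow-up censor the time-to-symptom-surgery endpoint (plain KM;
  competing-risk estimation is deliberately out of scope). The
  implementation is checked against a brute-force product-limit oracle and
  against `survival::survfit(conf.type = "log-log")`.
* **Logistic progression model**: `progressed ~ age + sex + u5hiaa + ki67 +
  grade`, maximum likelihood, male and grade 1 as reference levels, odds
  ratios with Wald 95% CIs. Missing covariates cause listwise deletion with
  the removal count reported. Complete or quasi-complete separation (e.g. a
  grade level with no progressors) is detected per term — an absurd Wald
  standard error on the log-odds scale, or an aliased coefficient — and
  reported as a non-identifiable term with a $(0, \infty)$ interval instead
  of a crash or a penalised re-fit: the goal is to reproduce the
  presentation style of clinical reports, which print exactly such rows.
* **No multiplicity adjustment**: raw p-values, as is conventional for
  descriptive cohort tables. Report percentages are rounded to integers and
  p-values to 3 decimals *for display only*; full precision is retained in
  every CSV consumed downstream.

## The synthetic cohort: a stated world

Observational studies of this kind deposit no patient-level data, so the
generator (`simulation_config()` + `generate_cohort()`) encodes a fixed,
explicit generative world with the cohort structure the analysis assumes.
Defaults, chosen once:

| Parameter | Default | Rationale |
|---|---|---|
| group sizes | 44 asymptomatic + 10 symptomatic | the cohort structure analysed |
| baseline volume | lognormal, median 10,000 mm³, sdlog 1.0 | a 2–3 cm mesenteric mass, right-skewed across patients |
| growth constant $g$ | Normal(−0.006, 0.04) /month | median TGR ≈ −0.6 %/month; sd puts the TGR IQR near −3.6…+1.9 |
| PRRT | 16/44 treated, shift −0.012 /month | treated fraction and the observed direction/magnitude of extra shrinkage |
| scan interval | lognormal, median 29 months, sdlog 1.4, truncated at 2 | right-skewed follow-up with the reported median; truncation mirrors the eligibility rule |
| diameter noise | lognormal, sdlog 0.05 per axis | ~5% caliper error per plane, a realistic CT repeatability figure; no published variance exists, so this is a free calibration knob |
| symptom hazard | $7.86\times10^{-4}$/month, log-linear in $g$ (coef 20) | $1-e^{-120\lambda}=0.09$: a 9% 10-year event fraction; faster-growing masses more likely to cause symptoms |
| death hazard | $7.43\times10^{-3}$/month | 59% 10-year mortality |
| follow-up cap | 120 months | the 10-year horizon |
| location probabilities | .30/.27/.36/.05/.02 over I, II, III-down, III-up, IV | the reported location distribution |
| missingness | 1/44 for 5-HIAA and for Ki-67 (+grade) | the reported missing-data pattern; Ki-67 and grade come from the same biopsy |

Mechanically, each true volume is realised as a random-aspect ellipsoid
(aspect ratios uniform on $[0.6, 1]$ relative to the largest diameter,
diameters solved to preserve the volume) so that the permutation-invariance
and irregular-shape code paths are exercised, then each diameter is
perturbed multiplicatively. Scan dates are rounded to whole days and the
true follow-up volume is computed from the *rounded* interval, which is what
makes the noise-free pipeline recover $g$ to machine precision — an identity
the acceptance suite relies on. One seeded private RNG stream per cohort;
the caller's `.Random.seed` is never touched.

**What the generator does not emulate**: CT acquisition and reading,
radiologist-specific bias (noise is symmetric and independent per axis),
correlation between growth and covariates other than the PRRT shift and the
symptom-hazard link (age, sex, Ki-67, 5-HIAA and grade are generated
independent of $g$, which is precisely what makes the null-covariate
coverage test meaningful), non-exponential growth, and informative
censoring. A green recovery test therefore establishes that the pipeline
estimates what the generator encodes — not that real MLNM growth is
exponential.

Two deliberate calibration notes:

* With the PRRT shift active, the *population* median TGR sits below the
  untreated median by construction (a mixture of a shifted and an unshifted
  component). The acceptance check that recovers the −0.6 %/month target
  therefore runs with `prrt_fraction = 0`: it calibrates the growth knob,
  not the treatment knob. The treatment knob is checked separately by the
  sign and magnitude of the recovered treated-vs-untreated median split.
* A single exponential death hazard cannot match a two-point survival
  profile (≈49% at 5 years *and* ≈38% at 10 years) exactly; the default
  matches the 10-year mortality fraction and accepts the implied 5-year
  value. Time-varying hazards were judged not worth the added surface.

## Numerical and degenerate-input policies

* Diameters must be strictly positive and finite; violations name the
  offending field and row. Dates are ISO-8601 only — silent format guessing
  is a correctness hazard in clinical CSVs.
* Duplicate `(patient_id, scan_date)` keys are an error listing the
  duplicates; a patient with one scan is skipped with a warning, not an
  error.
* Mann–Whitney with identical groups returns $p = 1$; Fisher with a zero
  margin returns $p = 1$; an empty group is an error.
* The KM confidence interval is undefined where $S \in \{0, 1\}$ under the
  log–log transform; the package reports 0 at $S=0$ and `NA` at $S=1$,
  matching `survfit` behaviour at the curve's endpoints.
* `estimate_growth` exclusions (short interval, too few scans) are data, not
  log noise: they are returned as an attribute and surfaced by the CLI.
* All report CSVs are written with deterministic formatting (no timestamps),
  so a rerun on identical inputs is byte-identical — tested.

## Limitations

The ellipsoid approximation under-represents irregular, stellate masses;
TGR from two endpoints ignores non-monotone trajectories (an intermediate
scan is used only to exercise the endpoint rule, not modelled); the logistic
model at $n \approx 42$ with six parameters is a screening device, not a
prediction model, and separation-prone by design; and the synthetic world,
however carefully calibrated, is simpler than any real cohort — conclusions
about method behaviour transfer, point estimates do not.
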