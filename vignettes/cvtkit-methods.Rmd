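---
title: "Methods and conventions behind cvtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions behind cvtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific and numerical conventions that
`cvtkit` commits to, and why. Every choice below is also enforced by the
test suite; this document explains the reasoning.

## 1. The data model

A CvT database is five relational tables: `documents` (the publication a
study came from), `studies` (one dosing experiment: substance, species,
route, dose), `series` (one concentration-time curve: analyte, medium,
units, subject description, LOQ), `conc_time_values` (individual time /
concentration pairs, both as reported and as normalized), and
`tk_parameters` (fitted or literature-extracted toxicokinetic parameters).
Each table has a character primary key and explicit foreign keys to its
parent. The interchange format is one CSV per table; writing sorts rows by
id so repeated writes are byte-identical, which makes the files usable
under version control.

`validate_database()` returns a data frame of issues (severity, entity,
id, field, message) instead of throwing on the first violation, because
curation is iterative: a curator wants the full list. Referential
integrity violations at read time, by contrast, throw immediately — a
database with dangling keys cannot be represented in memory coherently.

## 2. Normalization

**Concentrations** are converted to ug/mL for liquid media, ug/m^3 for
breath, with an `Eq` marker preserved for radiolabel measurements
(`ugEq/mL`): radioactivity-equivalent concentrations convert like mass
concentrations but must not be confused with parent-chemical mass, so the
label survives normalization. Molar units require a molecular weight;
asking for one that was not supplied is an error, never a silent skip.
Unit spellings are canonicalized (ASCII `u` for micro) and the registry of
factors ships as an editable CSV in `inst/extdata/`.

**Times** convert to hours; **doses** to mg/kg body weight. When a dose is
reported in absolute mass, the subject's mass is used if recorded,
otherwise a cohort-average mass; the provenance of that choice is stored
alongside the value (`per_kg_reported`, `subject_mass`,
`cohort_average_mass`) so downstream users can filter on it.

**Storage rounding.** Normalized values are stored to 5 decimal places,
rounding halves away from zero (`round5()`). Fixing the storage precision
makes round-trips through CSV exact and makes equality tests meaningful;
half-away-from-zero is chosen over banker's rounding because it matches
what curators expect from hand calculation.

**Age categories.** Reported ages map to seven life stages (neonate,
infant, child, adolescent, young adult, adult, aged) using
species-specific lower thresholds for dog, human, mouse, non-human primate
and rat, shipped as `inst/extdata/age_thresholds.csv`. Thresholds are
inclusive lower bounds — an animal exactly at the adult threshold is an
adult — and anything below the infant threshold is a neonate. Ages
reported in other units (e.g. a human age in months) are converted via
days (one month = 365.25/12 days) before comparison. Unknown species yield
`"unknown"` with a warning rather than an error, since a database may
legitimately contain species outside the table.

## 3. Compartmental models

Two disposition models are implemented in closed form:

* **One-compartment**: `C(t) = (D/Vd) e^{-kelim t}` for IV bolus; for oral
  first-order absorption the standard Bateman function, with the
  coincident-rate limit `F D ka t e^{-ka t} / Vd` substituted when
  `|ka - kelim| < 1e-8 kelim` to avoid catastrophic cancellation.
* **Two-compartment**: macro rates alpha, beta are the roots of
  `s^2 - (k12 + k21 + kelim) s + k21 kelim`; IV concentration is the
  standard bi-exponential with coefficients
  `A = D (alpha - k21) / (V1 (alpha - beta))` and
  `B = D (k21 - beta) / (V1 (alpha - beta))`; oral dosing adds the
  absorption exponential by partial fractions, nudging `ka` by a relative
  `1e-7` if it coincides with a macro rate.

Before being trusted, every model x route combination was verified against
independent numerical integration of the compartment ODE system
(`deSolve::lsoda`, rtol 1e-10): the worst relative discrepancy over
random parameter draws is below 1e-6, and that check is kept as a
permanent test. Derived quantities follow from the same parameters:
half-life `ln 2 / kelim` (terminal `ln 2 / beta` for two-compartment),
clearance `CLtot = kelim * V`, `AUCinf = F D / CLtot`, and Cmax/tmax
(closed form where available, numerical maximization for the
two-compartment oral curve). `AUCinf` is reported per 1 mg/kg dose so the
value is dose-independent under the linear kinetics assumed throughout.

## 4. Fitting

All studies of a substance/species pair are fitted **jointly**: each study
is collapsed to its mean series (averaging replicate curves on the union
time grid), and a single parameter vector must explain every study
simultaneously, with dose and route taken from the study record. The error
model is Gaussian on log concentration with a **separate SD per study** —
plot-digitized decades-old studies differ wildly in precision, and a
shared SD would let one noisy study dominate. Observations flagged below
the LOQ contribute the censored-likelihood term
`-ln Phi((ln LOQ - ln C_pred)/sigma)` rather than being dropped, which
avoids the upward bias that discarding non-detects induces in terminal
slopes.

Numerically: parameters are optimized on unconstrained scales (log for
rates and volumes, logit for Fbio); when no observation is censored, the
per-study SDs have a closed-form profile (the RMS log residual), which
removes them from the search space; SDs are floored at 1e-6 so that
noise-free synthetic data cannot drive the likelihood to infinity. The
optimizer runs Nelder–Mead from five deterministic starts (a
terminal-slope heuristic and multiplicative perturbations of it) followed
by a BFGS polish; the best converged result wins. Fbio is free only when
both IV and oral data are present; oral-only data identify the apparent
volume `Vd/Fbio`, and the fit records that Fbio was held at 1.

**Model selection** uses AIC with the per-study error SDs counted in the
parameter total; the lesser AIC wins and exact ties go to the
one-compartment model (parsimony). Two caveats are documented rather than
hidden. First, with study-mean series a group often has only ~8 points per
study, and AIC's fixed 2-per-parameter penalty is then marginal: at
moderate noise (CV 0.05–0.2) the two-compartment model is over-selected
for genuinely mono-exponential data in roughly 15–30% of simulated
replicates, converging to ~10% as noise shrinks. Second, with
one-compartment truth the extra parameters sit on a boundary
(`k12 -> 0` with `k21` unidentified), so the likelihood-ratio tail is
heavier than the nominal chi-squared — this is a property of the selection
problem, not a defect of the optimizer, and the acceptance experiment
therefore evaluates selection consistency in the low-noise regime
(CV = 0.01).

## 5. Validation statistics

* **Trapezoidal AUC** over the observed range (no extrapolation), via
  `pracma::trapz`.
* **Fractional AUC variability** of replicate series: the *population* SD
  (divide by n, not n-1 — the replicates on a plot are the whole
  population of interest) of per-series AUCs, divided by the area of the
  axis-anchored plot rectangle `(max t - min(0, min t)) * max conc`. The
  rectangle makes the statistic dimensionless and invariant to unit
  changes on either axis; two constant series at concentrations 1 and 2
  over 10 hours give AUCs 10 and 20, SD 5, rectangle 20, hence 0.25 — the
  worked example in the tests.
* **K-S concordance**: two replicate extractions of the same curve should
  draw from the same distribution; `stats::ks.test` (two-sample) with a
  0.05 threshold gives a yes/no concordance call plus the D statistic.
* **Confusion-matrix metrics**: recall, precision and F1 computed from raw
  counts, with F1 always computed from *unrounded* precision and recall,
  plus half-away-from-zero roundings for table display. Degenerate cases
  (a zero denominator anywhere, including precision + recall = 0 for F1)
  report 0 with a `degenerate` flag rather than NaN.

## 6. Literature triage

Finding the papers worth curating is a needle-in-haystack classification
problem. Two complementary approaches are implemented:

* **MeSH enrichment rule**: for each class of a labelled corpus, the
  feature terms are those appearing in strictly more than sqrt(class size)
  documents of that class; terms enriched in both classes are removed from
  both. A record is positive iff it carries at least one positive feature
  and no negative feature. The sqrt threshold adapts to class size and the
  strict inequality keeps marginal terms out.
* **TF-IDF consensus ensemble**: abstracts are lower-cased, tokenized,
  stop-word filtered, and tokens with corpus-wide counts strictly below
  the 25th percentile of the distinct-token count distribution are
  removed (strict, so a uniform-count corpus loses nothing). Features are
  raw counts times smoothed IDF `ln((1+N)/(1+df)) + 1`, rows normalized to
  unit length. Seven classifier families (naive Bayes, ridge logistic
  regression, linear SVM, 3- and 5-nearest neighbours, decision tree,
  random forest) are trained on a class-balanced corpus (negatives
  undersampled once, seeded), evaluated by stratified 10-fold CV, and only
  members with CV accuracy >= 0.90 vote. A record is positive when the
  positive-vote fraction reaches the consensus threshold: 1.0 (unanimity)
  or 0.75. Unanimity positives are provably a subset of 75% positives,
  and the test suite asserts it.

All seeding is private: generators and the ensemble save and restore
`.Random.seed`, so library calls never perturb a caller's RNG stream.

## 7. Synthetic data: realism and limits

`simulate_cvt_database()` evaluates the true model on each study's grid,
multiplies by lognormal noise `exp(eps)`, `eps ~ N(0, sqrt(ln(1+CV^2)))`
(so the *median* curve is the true curve and the coefficient of variation
is exactly the design CV), emits the values in heterogeneous as-reported
units (ng/mL with minutes, mg/L with hours, ...), and pushes everything
through the real normalization pipeline, so the generator exercises the
same code paths a curated database would. LOQ flags are set from the
normalized values. The default design — one mono-exponential substance
observed in two IV studies and one oral study, one clearly bi-exponential
substance — is deliberately modest: it is a study-conditions fixture, not
a tuning knob, and its parameters are fixed independently of any test
outcome.

What the generator does **not** simulate: plot-digitization error
structure (systematic, not multiplicative), multi-dose regimens,
nonlinear (saturable) kinetics, tissue compartments other than plasma, or
real abstract text — the corpus generator produces class-conditional
bags of synthetic words, which is sufficient to validate the pipeline
mechanics but says nothing about performance on real literature. Results
on synthetic corpora are upper bounds, not forecasts.

## 8. Reproducing everything

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the complete battery against the installed package and writes a JSON
report; the `testthat` suite covers the same ground with fixed seeds plus
the ODE oracle, property-based and hand-computed checks.
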