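---
title: "Trigger-based ADE surveillance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-based ADE surveillance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adetrigger)
```

## The surveillance problem

Passive pharmacovigilance — clinicians spontaneously reporting adverse drug
events (ADEs) — is known to miss most harm. Trigger tools in the tradition
of the Global Trigger Tool (GTT) take the opposite route: a fixed set of
machine-detectable *triggers* (an abnormal laboratory value, an antidote
order, a coded symptom, an escalation of care) is screened over every
admission, and the flagged charts are reviewed by humans who adjudicate
whether each signal reflects a genuine drug-induced event. The package
implements this workflow end to end for hospitalized pulmonary arterial
hypertension (PAH) patients on targeted therapy (phosphodiesterase-5
inhibitors, endothelin-receptor antagonists, riociguat, selexipag,
prostacyclin analogues), together with the statistics used to evaluate the
trigger set itself and a synthetic cohort generator that provides ground
truth for testing.

Two assumptions shape everything downstream:

* **Counting unit.** A trigger either fires or does not fire for a given
  admission: hits are deduplicated to one per (patient, trigger) pair. This
  is the unit under which per-trigger positive counts, the overall positive
  predictive value and the patient-level confusion matrix are coherent with
  each other.
* **Review is external.** The package records adjudication outcomes
  (dual-reviewer verdicts, WHO-UMC causality, NCC MERP severity); it never
  produces them. Automated causality scoring is deliberately out of scope.

## The data model

A cohort is a list of five validated tibbles: `patients` (one admission per
row), `labs`, `medications`, `events`, `interventions`. The reader enforces
the inclusion-criterion invariants — discharge on or after admission, age
above 28 days, at least one targeted drug, at least 24 h of stay (a same-day
admission/discharge pair counts as one patient-day via the length-of-stay
floor `max(1, discharge − admission)`).

Units are *fixed per analyte* (hemoglobin g/L, creatinine µmol/L, bilirubin
µmol/L, cell counts 10⁹/L, …). A `unit` column that disagrees with the fixed
unit is rejected, never converted: silent unit conversion is the classic way
a threshold rule goes quietly wrong, and a hard failure at ingest is the
cheapest place to catch it.

Symptom terms pass through a flat controlled vocabulary with free-text
aliases ("joint pain" → `arthralgia`, "puffy" → `puffiness`); the
vocabulary is a package abstraction — hospital systems encode symptoms in
many ways, and a code list with aliases is the smallest model that keeps the
symptom triggers testable. Drug names resolve through a YAML dictionary to
exactly one class; unknown names resolve to `"other"` and can therefore
never satisfy an antidote trigger by accident.

## Trigger semantics

Rules live in YAML and come in seven shapes: plain thresholds, age/sex
stratified thresholds, boolean `any`/`all` composites, baseline-ratio rules,
drug-class exposures, symptom term sets, interventions, and the
abrupt-cessation flag. Conventions the engine fixes:

* **All thresholds are strict** (`>`, `<`), exactly as the rules are worded.
  Hemoglobin of exactly 110 g/L in an adult woman does not fire L6;
  creatinine at exactly twice baseline does not fire L5.
* **Baseline = first in-stay value.** The baseline-ratio rule (L5) compares
  later observations against the earliest in-stay measurement of the same
  analyte, ordered by timestamp with row identity as tie-break.
  Pre-admission values are outside the data model, so the first in-stay
  value is the only baseline the data can support.
* **Upper limits of normal are configuration.** L4 ("ALT or AST > 3× ULN, or
  bilirubin and ALP both > 2× ULN") reads its ULNs from the rule file
  (defaults ALT 40 U/L, AST 40 U/L, total bilirubin 21 µmol/L, ALP
  125 U/L — common adult reference values); sites override them in place.
  The bilirubin/ALP branch is a true conjunction: each component must be
  satisfied by some observation during the stay, and the conjunction is
  timed at the later of the two.
* **Hemoglobin strata are half-open**: [6 mo, 5 y), [5, 12), [12, 15),
  [15, ∞) split by sex above 15. Ages below six months are not evaluated for
  L6 — the bands simply do not reach them. Stratum validation rejects
  overlapping or gapped bands at load time.
* **Abrupt cessation is a recorded flag**, not an inference. Deriving
  "abrupt" from dosing gaps would be inventing a rule the source data does
  not define; the generator and the readers carry an explicit boolean.

The engine is deterministic, order-independent (hits are keyed and sorted),
and monotone: adding observations can only add hits. The test suite checks
these as properties, pins one minimal firing record and one boundary
non-firing record for every one of the 24 rules, and cross-checks whole
cohorts against an independently written brute-force scan.

## Detection metrics

With per-trigger positives $n_t$ and adjudicated true positives $a_t$:

* per-trigger PPV $= 100\,a_t/n_t$; overall PPV $= 100\sum a_t / \sum n_t$
  (the weighted ratio — not the mean of per-trigger PPVs);
* patient-level sensitivity $= TP/(TP+FN)$, specificity $= TN/(TN+FP)$;
* the "correctness index" is Youden's $J =$ sensitivity $+$ specificity
  $- 1$: on the published confusion matrix $0.9821 + 0.7257 - 1 = 0.7078
  \approx 0.71$, which is what identifies the index numerically;
* false-negative rate $= FN/(FN+TN)$, the share of screen-negative patients
  who nonetheless had an ADE;
* rates: ADEs per 1,000 patient-days ($\times 1000$ over total stay days)
  and per 100 patients ($\times 100$ over admissions). The "per 1,000
  drugs" quantity is computed with a $\times 100$ multiplier over the total
  count of medication types across cases — that is the formula as printed in
  the surveillance literature this package follows, and it is reproduced
  verbatim despite the naming inconsistency, which we document rather than
  silently "fix".

Undefined ratios (zero denominators) surface as `NA`, never as 0.
Percentages are rounded half-up to two decimals, matching clinical reporting
style; base R's banker's rounding would disagree on exact halves.

Utility classes default to high ≥ 50% PPV, moderate ≥ 20%, low otherwise.
These cut points are configurable; the defaults are consistent with every
labelled row of the published per-trigger table, and rows left unlabelled
there are completed by the same rule.

## Risk-factor analysis

Covariates are binned into the standard categorical schemes (age 0–17 /
18–40 / 41–60 / >60; stay 1–10 / 11–20 / 21–30 / >30 days; comorbidities
1–3 / 4–6 / 7–9 / >9; previous admissions 1–3 / 4–6 / >6; targeted drugs 1 /
2 / 3 / >3; positive triggers 0–1 / 2–4 / ≥5). The trigger-count scheme
exists twice — once labelled `>=5` (univariate use) and once `>4`
(regression use) — because both labels circulate; for integer counts they
are numerically identical, and keeping both names avoids pretending the
sources agree.

The univariate screen is Pearson's chi-square without continuity correction
on each r×2 table (the convention of the statistical software the published
analysis used); empty levels are dropped with a warning. The multivariable
model is a maximum-likelihood binary logistic regression, dummy-coded
against the first (reference) level of each scheme, reporting β, OR =
exp(β) and Wald p per level. The model-fit statistic is **Nagelkerke's
R²** — reported under that explicit name because the quantity called "overall
fit" in applied reports is often unnamed and could equally be Cox–Snell;
naming it removes the ambiguity without claiming equivalence to any
particular published value. Separation is detected from diverging
coefficients and reported with the offending terms.

Paired detection methods (trigger screen vs spontaneous reporting on the
same patients) are compared with the exact McNemar test — a two-sided exact
binomial at 0.5 on the discordant pairs, the correct test for paired
proportions — while the Pearson chi-square p on the same 2×2 table is also
reported for comparability with reports that quote a chi-square there.

## Delphi statistics

Item statistics over an experts × items score matrix: Mj (column mean), Kj
(percent of experts awarding the full mark), Vj (sample SD over mean).
Retention cut-offs across items: mean − SD for Mj and Kj (pass at or above),
mean + SD for Vj (pass at or below). Items failing all three criteria are
dropped; passing all three, retained; anything mixed goes to discussion.

Conventions fixed here, because the literature leaves them open:

* the score scale is configurable with full mark = scale maximum (1–5 is
  the Delphi convention and the default);
* **sample (n−1) SDs everywhere**, visible in the frozen test fixtures;
* boundary equality counts as *passing* (≥ / ≤). The degenerate case forces
  a choice: if all items tie, the SD is zero, every item sits exactly on
  every cut, and the non-strict convention retains them all rather than
  dropping the entire instrument;
* the authority coefficient is the standard Cr = (Ca + Cs)/2 per expert,
  reported as panel mean ± SD; the positive coefficient is
  responders/invited.

Kendall's W uses the tie-corrected formula
$W = 12S / (m^2(n^3-n) - m\sum T)$ with average ranks within experts. It is
1 for identical rankings, 0 for two exactly reversed rankings, and matches
vegan's independent implementation to machine precision in the test suite
(vegan is used only as a cross-check, never as the implementation).

## The synthetic cohort generator

`simulate_cohort()` emulates the validation cohort's marginal structure:
626 admissions by default, sex 39.14% male, age truncated normal
50.04 ± 18.18 on [0.33, 93] years, comorbidity and prior-admission counts as
shifted negative binomials matched to 5.74 ± 3.63 and 3.65 ± 3.55, targeted
drug count as a shifted Poisson matched to mean 1.93 on 1–6. Length of stay
is lognormal truncated to [1, 68] days with the pre-truncation parameters
*re-solved so the truncated, integer-rounded distribution* matches
8.87 ± 8.08 — matching the stated moments before truncation would bias both
downward. Distribution families are the package's choice (only moments and
ranges are published); they are stated in `sim_config()` and not tuned
beyond moment matching. Covariates are drawn independently — their
correlations are unreported — which is a known simplification.

ADE status follows a logistic model over the standard covariate binning with
the published regression coefficients as default effects; the intercept is
calibrated at run time by root-finding so the marginal ADE-patient fraction
hits the configured prevalence (default 0.1757). ADE patients receive
1 + Poisson(0.3) events (so roughly 1.3 per ADE patient), each assigned an
organ-system type, severity and causality from the published empirical
distributions.

Each ADE type maps to exactly one trigger signature (anemia → a hemoglobin
value below the admission's age/sex band; liver injury → ALT above 3× ULN;
kidney damage → a creatinine at 2.2–4× the admission baseline; constipation
→ a laxative order; rescue → a salvage intervention; …). With probability
`emission_prob` (default 1 − 2/143, mirroring the two undetected events in
the validation study) the signature is injected into the record streams;
otherwise the ADE stays *silent* — the only false-negative mechanism.
Independently, every (patient, trigger) pair receives a false-positive noise
signature with probability `noise_rate` (default 0.0133, chosen so that the
probability a non-ADE patient trips at least one of 24 triggers matches the
published false-positive patient fraction 141/514). One edge case: anemia in
an infant below the youngest hemoglobin stratum would be undetectable by
construction, so for ages under six months the blood-system signature is
emitted as a bleeding event instead; this keeps the ledger's invariant that
*every emitted signature is detectable*.

That invariant is what makes the generator an oracle: with `noise_rate = 0`
and `emission_prob = 1`, the engine's deduplicated hit set must equal the
ledger exactly, and patient-level sensitivity must be 100%. The test suite
and the acceptance script both verify this closure, and additionally fit the
logistic model on replicated cohorts to confirm that Wald 95% intervals
cover the generating coefficients at the nominal rate.

What the generator does **not** emulate: longitudinal lab physiology (labs
are point injections on a normal baseline), drug–drug interactions,
correlated covariates, or informative timing of events within the stay.
Passing tests on synthetic cohorts therefore demonstrate the *pipeline's*
correctness — rule semantics, bookkeeping, metric arithmetic, estimator
calibration — not that the trigger set performs identically on any
particular real-world cohort.

## Problem sizes and randomness

All randomness flows from a single seed per simulation; runs are
reproducible byte-for-byte. The test suite uses cohorts of 30–400 admissions
for engine and pipeline checks, 4,000–5,000 for distribution and estimator
checks, and 200 replicates at n = 5,000 for the coverage property — sizes
chosen so Monte-Carlo error is small relative to the tolerances being
asserted. The acceptance script repeats the coverage check at 60 replicates,
which is enough to place the coverage estimate within a couple of points of
its target.

## Known limitations

* The published per-patient regression estimates cannot be reproduced here:
  they require the original hospital's patient-level data, which is not
  deposited. The package instead validates its regression machinery by
  parameter recovery on synthetic cohorts.
* One source inconsistency is deliberately left visible: the narrative
  count of trigger-positive patients (375) conflicts with the confusion
  matrix (251 positive / 375 negative). The package follows the confusion
  matrix, which is the arithmetic the false-negative rate 2/375 requires;
  the discrepancy is flagged here rather than silently resolved.
* The symptom vocabulary and drug dictionary are deliberately small; they
  cover the shipped trigger set and are user-extensible, not exhaustive
  formularies.
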