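---
title: "Detecting hematologic organ dysfunction on sparse PICU lab series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hematologic organ dysfunction on sparse PICU lab series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemod)
```

## The clinical problem

In children with systemic inflammation or sepsis, failure of the
hematologic system is one of the organ dysfunctions that defines
progression toward multiple organ dysfunction syndrome. The International
Pediatric Sepsis Consensus Conference (IPSCC) criteria diagnose
hematologic organ dysfunction (OD) from two routine laboratory parameters:

* platelet count **< 80,000/mm³**, or
* a **decline of at least 50 %** in platelet count relative to a reference
  value, applicable to chronic hematology/oncology patients whose counts
  may stay above 80,000/mm³ while collapsing relative to their own
  baseline, or
* an international normalized ratio (INR) **> 2**.

`hemod` implements these rules as a deterministic detector over per-patient
timelines of LOINC-coded observations (platelets `777-3`, INR `6301-6`),
ICD-10-GM diagnosis lists and procedure episodes, together with the
block-based diagnostic-accuracy evaluation used to validate such detectors
against a clinician reference standard, and a synthetic cohort generator
that makes the whole pipeline testable without any clinical data.

Three institution-level adaptations are part of the rule set:

1. **Admission baseline.** The comparator for the relative-decline rule is
   the *first* platelet value after admission, not a rolling maximum, so
   platelet transfusions or surgical bleeding later in the stay cannot
   inflate the reference.
2. **Diagnosis gating.** The relative rule applies only to patients with a
   documented chronic hematologic/oncologic diagnosis; conversely,
   patients whose primary disease itself raises the INR (e.g. hereditary
   factor deficiencies) never contribute INR alarms.
3. **ECMO suppression.** During extracorporeal membrane oxygenation the
   circuit (heparin, consumption) depresses platelets independently of
   sepsis, so platelet alarms are suppressed from 2 h before until 12 h
   after each ECMO episode. Only the platelet branch is suppressed; the
   windows are configurable via `rule_config()`.

## From point measurements to episodes

Laboratory values are point measurements on a sparse, irregular grid, while
organ dysfunction is an interval-valued state. The detector bridges this
with an explicit event-persistence convention: each observation is
categorized against its analyte's normal range (`TOO_LOW` / `NORMAL` /
`TOO_HIGH`, with boundary values normal because the criteria are strict
inequalities), and **an abnormal value holds from its specimen timestamp
until the next observation of the same analyte with a different category,
or until discharge** if none follows. This is the natural semantics of a
forward-chaining rule engine over an event stream: a fact persists until
contradicted. It also makes merging meaningful: alarm events of the same
analyte and category that overlap or touch are united into one event from
the first start to the last overlapping end.

Episodes are then assembled per patient:

1. merged platelet `TOO_LOW` events, minus the extended ECMO windows
   (partial overlaps truncate the alarm rather than delete it);
2. merged INR `TOO_HIGH` events, unless the patient carries an
   INR-exclusion diagnosis;
3. surviving platelet intervals become `PLATELETS` episodes, INR intervals
   `INR` episodes, and overlapping or touching episodes of different cause
   are concatenated into one `BOTH` episode spanning their union.

Elevated platelets and depressed INR are representable alarm categories
(the plausibility bounds `plt_max_plausible`, `inr_min_plausible` complete
each normal range) but never map to organ dysfunction. Touching intervals
(end == next start) count as overlapping everywhere, which avoids
fragmenting an episode at a zero-length gap.

```{r example}
p <- patient_record(
  "demo", age_years = 6,
  admission = "2024-03-01 00:00", discharge = "2024-03-05 00:00",
  observations = data.frame(
    analyte = c("PLT", "PLT", "PLT", "INR", "INR"),
    value = c(250000, 60000, 210000, 2.6, 1.1),
    timestamp = c("2024-03-01 02:00", "2024-03-02 02:00", "2024-03-03 08:00",
                  "2024-03-03 06:00", "2024-03-03 20:00")
  )
)
detect_hematologic_od(p)
```

The platelet alarm (from the 60,000/mm³ value until the recovered count)
overlaps the INR alarm, so both concatenate into a single `BOTH` episode.

### Design choices worth knowing about

* **Boundary strictness.** Platelet alarms fire iff value < 80,000/mm³ and
  INR alarms iff value > 2 (both strict); the relative rule fires iff value
  ≤ 50 % of baseline (inclusive), so a drop of exactly half counts and no
  measure-zero dead zone appears between "less than" and "more than" half.
* **Diagnosis code lists.** The chronic hematology/oncology and
  INR-exclusion lists are deployment-specific expert knowledge. The
  shipped defaults — prefixes C81–C96 and D66–D68 with prefix matching
  enabled — are documented placeholders that exercise the mechanism;
  `rule_config()` and the YAML `rule:` section accept arbitrary lists.
* **Diagnosis timing.** Diagnoses gate rules at stay level with no temporal
  dimension: the gated conditions are chronic.
* **INR exclusion scope.** The exclusion silences only the INR branch.
  A thrombocytopenic excluded patient still produces platelet episodes.
* **Suppressed alarms.** ECMO-suppressed platelet intervals can be
  surfaced as a non-diagnostic annotation
  (`detect_hematologic_od(..., annotate_suppressed = TRUE)`); they are
  never episodes.
* **Units and time.** Platelets are counted per mm³ (the reader converts
  ×10⁹/L inputs by ×1,000); timestamps are timezone-naive ISO 8601 handled
  at minute resolution. Observations outside the admission window are
  rejected by the reader with a warning, never silently clamped.

## Block-based accuracy evaluation

To compare detector episodes with a clinician-adjudicated reference
standard, each stay is partitioned at every instant where the diagnostic
status (OD present / absent) of either source changes. Every resulting
maximal sub-interval is one **block**, labeled TP, FN, FP or TN from the
(detector, reference) status pair — a forced choice with no indeterminate
outcome. Two preprocessing steps precede the partition:

* **24 h merging** (`merge_gap_hours`): episodes of one source separated by
  *strictly less than* 24 h are one diagnostic episode. Applied to both
  sources by default (`apply_merge_to = "both"`), configurable to
  reference-only.
* **±4 h snapping** (`tolerance_hours`): a detector boundary within 4 h of
  a reference onset or end is moved onto it, symmetric for onsets and
  ends. Without this, a detector that fires 3 h late — inevitable when the
  next blood draw is hours away — would generate a spurious FN sliver
  block. Snapping is implemented as boundary movement (nearest reference
  boundary wins, the earlier one on exact ties; episodes collapsed to
  nothing are dropped) rather than post-hoc relabeling of sliver blocks,
  because moving boundaries preserves the partition property that block
  labels rely on. This reconstruction of the block rules from their
  published summary cannot be validated against the original study data,
  which is why the block counts themselves, not the published confidence
  bounds, are the reproducible quantity.

Sensitivity and specificity are pooled block-count ratios,
Se = ΣTP/Σ(TP+FN), Sp = ΣTN/Σ(TN+FP). Blocks are counted, not
duration-weighted, matching how such cross-tabulations are reported;
`accuracy_from_counts()` exposes the same computation for count data.

### Clustered confidence intervals

Several blocks come from each patient, so block outcomes are not
independent. The Wald intervals therefore use a **ratio-of-cluster-totals
linearization**: with per-patient totals \(x_i\) (correct blocks) and
\(n_i\) (eligible blocks), \(R = \sum x_i / \sum n_i\) and

\[
\widehat{\mathrm{Var}}(R) \;=\; \frac{m}{m-1}\,
  \frac{\sum_i (x_i - R\,n_i)^2}{\left(\sum_i n_i\right)^2},
\]

summing over the \(m\) patients with \(n_i > 0\) — patients without
reference-positive blocks contribute nothing to the sensitivity variance,
and symmetrically for specificity. Intervals are estimate ± 1.96·SE,
clipped to [0, 1]; the naive pooled-binomial variance is available as
`variance = "binomial"` for comparison. When no reference-positive blocks
exist at all, sensitivity is reported as undefined with an explanatory
note rather than a silent 0/0.

`ci_coverage_study()` checks the calibration of these intervals by Monte
Carlo: per-patient block counts are simulated with beta-distributed
patient-level detection probabilities (known marginal sensitivity and
specificity because the probabilities are drawn independently of the block
counts), and the empirical coverage of the nominal 95 % intervals is
reported. At 200 patients and 1,000 replicates the cluster-robust
intervals sit a little below nominal (≈ 0.93 in the runs the acceptance
script performs), the usual small-sample behavior of linearized cluster
variances, while remaining inside the 0.90–0.98 band one expects of a
usable Wald interval.

## The synthetic cohort generator

No public dataset carries these timelines, so `generate_cohort()` builds
one from an explicit generative model whose purpose is to make **every
rule branch reachable**, not to be physiologically faithful:

* stay lengths are lognormal (median 3 days, floored at the 12 h inclusion
  minimum); ages uniform on 0–18 years;
* each patient draws chronic, INR-exclusion and ECMO status by prevalence
  (defaults 0.10, 0.05, 0.05), and with probability
  `episode_prevalence` (default 0.21, matching the roughly one-fifth of
  stays with clinician-charted episodes) one to three dysfunction
  episodes of 12–96 h, kept ≥ 25 h apart so that injected episodes stay
  distinct under the evaluator's 24 h merge;
* latent trajectories are baseline plateaus (platelets uniform
  150,000–450,000/mm³, INR 0.9–1.3) with trapezoidal excursions during
  episodes — ramps over 15 % of the duration at each edge, a plateau at
  the platelet nadir (`plt_nadir_fraction` × baseline, default 0.2) or the
  INR peak (uniform 2.2–4.0) between — sampled at irregular uniform
  intervals (platelets every 6–24 h, INR every 12–48 h by default) with
  multiplicative lognormal noise (`noise_cv`, default 0.05);
* **ground truth is defined on the noise-free latent curve**: the truth
  episodes are the intervals where the latent trajectory crosses the same
  configured thresholds, with the chronic relative rule and the INR
  exclusion applied. Sensitivity loss under sparse sampling or noise is
  therefore a measurable property of the detector, not a tautology.
  ECMO timing is drawn independently of the injected episodes and is *not*
  subtracted from the truth, so detector suppression around ECMO is a
  genuine, quantifiable source of disagreement.

Two consequences deserve emphasis. First, an excursion whose nadir stays
above the platelet threshold (possible when the baseline exceeds
400,000/mm³ under the default nadir fraction) never crosses and is
excluded from truth with a warning — the generator treats "injected but
sub-threshold" as non-disease, keeping truth and rules consistent.
Second, on a noise-free, densely sampled cohort without confounders the
whole pipeline recovers the truth exactly (Se = Sp = 1), which the test
suite asserts; under the realistic defaults the detector's block
sensitivity drops substantially (the next blood draw can be a day away),
which is precisely the sampling-quality dependence the degradation helper
`degrade_sampling()` quantifies.

All randomness flows from one master seed through fixed per-patient
substreams, so regeneration is bit-identical and extending a cohort leaves
existing patients untouched.

```{r pipeline}
cohort <- suppressWarnings(generate_cohort(sim_config(n_patients = 30, seed = 7)))
episodes <- detect_cohort(cohort$patients)
res <- evaluate_episodes(cohort$patients, episodes, cohort$truth)
res$accuracy
```

## Files, configuration and the command line

The canonical interchange formats are plain CSV (UTF-8, header row,
ISO 8601 minute timestamps): `patients.csv`, `observations.csv`
(`patient_id, loinc_code, value, unit, timestamp`), `diagnoses.csv`,
`procedures.csv` and episode tables (`patient_id, start, end[, cause]`).
These columns deliberately mirror the fields a clinical data repository
would hold for a laboratory test result — analyte code, magnitude, unit,
specimen time — so an adapter from a standards-based repository only has
to emit flat rows. A YAML file with `rule:`, `eval:` and `sim:` sections
(see `inst/extdata/config-example.yaml`) overrides any threshold or
window. The four pipeline stages are available as R functions
(`run_simulate()`, `run_detect()`, `run_evaluate()`, `run_report()`) and
as subcommands of the `inst/cli/hemod` Rscript; every output directory
receives a `manifest.json` with the resolved configuration and input
digests. Reports are static files (text listing plus per-patient timeline
plots with norm bounds and episode shading); there is deliberately no
interactive interface.

## Numerical and testing notes

* Problem sizes in the test suite — cohorts of 15–80 patients for the
  behavioral properties, 500 and 2,000 for the prevalence recovery, 1,000
  Monte-Carlo replicates of 200 patients for CI coverage — were chosen as
  the smallest sizes at which the corresponding statistical checks are
  stable; everything is generated in code at test time.
* The detector is cross-checked against an independently written
  brute-force classifier (per-observation thresholding with run
  reconstruction) on confounder-free cohorts; the two must agree
  interval-for-interval.
* Estimates are conventionally reported to 3 decimal places; internal
  computation is double precision with no rounding.
* Known limitations: no age-stratified norm ranges (the hematologic
  criteria are age-independent), no modeling of transfusions or
  pharmacokinetics in the generator, no pre-analytic error screening
  beyond an optional artifact-spike knob (`error_spike_rate`), and the
  published study's exact confidence bounds are not reproducible because
  they depend on the unpublished per-patient clustering structure.
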