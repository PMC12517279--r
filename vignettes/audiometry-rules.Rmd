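---
title: "Rule-based audiometric classification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based audiometric classification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audscreen)
```

## The problem

Workers exposed to occupational noise receive a baseline audiogram at hire
and annual audiograms thereafter: hearing threshold levels in dB HL at 500,
1000, 2000, 3000, 4000, 6000 and 8000 Hz, per ear. An occupational health
doctor reads each audiogram series and decides, per ear and per worker,
whether it shows normal hearing, hearing loss, hearing impairment, a
permanent or temporary standard threshold shift (PSTS/TSTS), or
noise-induced hearing loss (NIHL) — and whether the audiogram needs to be
repeated or reported. `audscreen` automates those calls with explicit,
auditable threshold rules, and provides the statistical machinery to
measure how well the rules agree with expert judgment.

## The model: six deterministic rules

All rules operate on exact arithmetic; thresholds and pure-tone averages
are never rounded internally. Diagnostic rules read the **annual**
audiogram — the surveillance event — while the baseline serves as the
reference for shifts and the optional retest only resolves a shift as
permanent or temporary.

| Rule | Criterion | Cutoff (default) | Inclusivity |
|---|---|---|---|
| Hearing loss | any threshold above cutoff, any frequency | 20 dB HL | strict `>` |
| Hearing impairment | speech PTA (500/1k/2k/3k Hz mean) | 25 dB HL | `≥` |
| STS | change in 2/3/4 kHz PTA vs baseline | 10 dB | `≥` |
| PSTS / TSTS | STS persists / resolves at retest | 10 dB, window 92 d | `≥`, `≤` |
| NIHL | 5 notch terms and 3 recovery terms | 15 dB notch, 10 dB recovery | `≥` |
| Normal | none of the five positive categories | — | — |

The NIHL rule is the conjunction `T(3000)−T(1000) ≥ 15` ∧
`T(4000)−T(500) ≥ 15` ∧ `T(4000)−T(1000) ≥ 15` ∧ `T(6000)−T(500) ≥ 15` ∧
`T(6000)−T(1000) ≥ 15` ∧ the recovery terms at 8 kHz. All cutoffs are
fields of `rule_config()` so that variant criteria can be audited without
touching code.

### Design choices where the criteria left room

Several published formulations of these criteria are internally
inconsistent, and the package takes a documented position on each:

* **STS frequency set.** The shift is computed over {2000, 3000, 4000} Hz,
  the set used by hearing-conservation practice (OSHA-style STS); 9 kHz,
  which sometimes appears in typeset formulas, is not a tested frequency
  and is treated as a typographical artifact.
* **NIHL recovery sign.** "Recovery at the high frequency" clinically means
  the 8 kHz threshold is *better* (lower) than the notch. The default
  `recovery_sign = "corrected"` therefore requires `T(notch) − T(8000) ≥
  10`. Formulations with the difference written the other way around are
  retained verbatim behind `recovery_sign = "literal"` for auditability;
  the two modes are both covered by the engine-vs-oracle property tests.
* **Notch conjunction.** Prose descriptions of notch criteria often say a
  notch "at 3, 4 **or** 6 kHz", but the operational formula implemented
  here ANDs all five notch terms (and has no `T(3000)−T(500)` term). The
  package implements the conjunction exactly as printed and does not add
  or relax terms; an OR-logic variant would be an extension point, not a
  configuration.
* **Hearing-loss cutoff.** The binary call uses strict `> 20` dB HL, the
  WHO-style simplification of the severity grades; the cutoff is
  configurable for sensitivity analyses.
* **Pending shifts.** An STS without an in-window retest is *not* a
  diagnosis: `normal` is computed from the five confirmed categories only,
  and the pending state is carried separately (`sts_pending`) and surfaced
  through the `repeat_required` action flag.
* **Worker-level aggregation.** A worker carries a category if at least one
  ear does (union), and is normal only if both ears are; the conservative
  choice for surveillance, where a unilateral finding still warrants
  action.
* **Retest window.** "Within 3 months" is implemented as ≤ 92 calendar
  days, configurable.
* **Action flags.** `repeat_required` fires on any pending shift;
  `report_required` on confirmed PSTS, NIHL or hearing impairment in any
  ear. These triggers are a design choice of this package, not a published
  criterion, and are deliberately simple.

## Validation apparatus

Agreement with a gold standard is summarised per category from the 2×2
table of worker-level one-vs-rest calls: sensitivity `tp/(tp+fn)`,
specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, and Cohen's
kappa `κ = (p_o − p_e)/(1 − p_e)`, interpreted on the Landis–Koch bands. A
large-sample z-test of κ against zero accompanies the pooled estimates.

Numerical conventions:

* A metric whose denominator is zero is **undefined** and reported as `NA`,
  never imputed as 0 or 1. In fold aggregation, undefined values are
  excluded from the mean/SD with an explicit exclusion count.
* When `p_e = 1` (both raters constant — e.g. a small fold with no
  positives of a rare category in either rating), κ is 0/0; the package
  returns 1 for perfect agreement with a warning. (In a 2×2 table `p_e = 1`
  in fact forces perfect agreement, so the imperfect branch of the
  convention is defensive only.)
* Report tables round percentages to one decimal and κ to three decimals,
  half away from zero; stored fold values keep full precision.

### Cross-validation of an untrained classifier

The evaluation design mirrors the k-fold protocol used for learned
classifiers: workers are partitioned by a seeded uniform shuffle into `k`
folds whose sizes differ by at most one (320 workers, `k = 5` → five folds
of 64), each fold serves once as the test set, and the per-fold metrics are
aggregated as mean ± SD. The rule engine has no fitted parameters, so the
"training" step is a documented no-op that records the training-fold
category prevalences — the structure of the harness is kept so results are
comparable with the standard protocol. Two consequences are useful checks:
pooled metrics over the concatenated test folds equal whole-dataset metrics
exactly for any seed, and categories on which the gold standard agrees with
the rules come out 100.0 ± 0.0 with κ = 1.000 under *any* fold plan.

The SD across folds is the sample SD (denominator `k − 1`), the
conventional choice at small `k`; `sd_type = "population"` is available.

## The synthetic cohort generator

`generator_spec()` describes a cohort of workers with known ground truth,
used throughout the tests and by `scripts/acceptance.R`. Its defaults are
fixed once and describe a noise-exposed industrial cohort:

* **Mixture.** 48.6% of workers are normal — equivalently, 51.4% carry at
  least one noise-related finding, the prevalence reported for this
  population in occupational surveys — with the remainder split across
  isolated hearing loss (10.0%), hearing loss with impairment (13.0%),
  PSTS (9.0%), TSTS (9.0%) and NIHL (10.4%).
* **Templates.** Flat low thresholds for normal ears; a single elevated
  high frequency for isolated loss; broadband 35 dB elevation for
  impairment; a 3–6 kHz notch (45/50/45 dB) with 8 kHz recovery for NIHL;
  and an exact +15 dB overlay on the 2/3/4 kHz set for shifts, persisting
  or resolving at a retest 20–45 days after the annual test.
* **Noise.** Gaussian test-retest noise, SD 2.5 dB — the order of magnitude
  of audiometric test-retest variability — applied before snapping to the
  5-dB audiometer grid, then clamped per frequency so each scenario keeps
  its defining signature. At the three STS frequencies of shift scenarios
  the overlay is exact rather than noisy, so the shift magnitude is
  controlled.
* **Gold labels are the oracle's, not the template's.** Every generated
  record is labelled by the independently coded brute-force classifier;
  the construction target is only an intent. This removes template/rule
  inconsistency by design — e.g. an NIHL notch always also constitutes
  hearing loss, and the gold table reflects that.
* **Expert disagreement.** `nihl_flip_prob` flips a fraction of gold NIHL
  labels, emulating the between-clinician criteria variability that makes
  NIHL the least reproducible category; flipping lowers NIHL κ
  monotonically while other categories stay perfect, reproducing the
  qualitative imperfect-NIHL/perfect-others pattern seen with real expert
  panels.

What the generator does **not** emulate: real expert labelling behaviour
beyond the flip knob, presbycusis and age structure, exposure histories,
demographic covariates, asymmetric or conductive losses, and off-grid
thresholds. Perfect self-consistency results on synthetic data therefore
demonstrate the correctness and determinism of the pipeline — not field
performance against human raters, which depends on how closely the raters'
criteria match the implemented rules.

## The independent oracle

`oracle_classify()` is a second, deliberately naive implementation of all
six rules: every mean and inequality written out longhand, no helpers
shared with the engine. The test suite requires exact agreement between
engine and oracle on 10,000 random records (thresholds uniform on the 5-dB
grid over [−10, 120] dB HL, retests present half the time and sometimes
outside the resolution window) and on full template cohorts, in both
recovery-sign modes. The suite also exercises every cutoff at one grid step
below, at, and above its value, with the documented inclusivity.

Problem sizes used by the default test run and acceptance script — 10,000
random records for the equivalence property, 320-worker cohorts for the
cross-validation checks, 1,500-worker cohorts for the label-noise response
— were chosen to make binomial noise negligible relative to the effects
asserted while keeping the suite quick on a laptop.

## Known limitations

* Binary calls only: no WHO severity grading, no conductive/sensorineural
  typing, no bone-conduction or masking data.
* No age (presbycusis) correction; the rules assume a screened,
  noise-exposed working population.
* Only the two recovery-sign modes of the NIHL rule are built in;
  alternative notch criteria families are an extension point.
* Confidence intervals are limited to the kappa z-test; no ROC analysis,
  as the rules produce no scores to threshold.
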