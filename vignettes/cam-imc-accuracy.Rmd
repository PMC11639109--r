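---
title: "CAM-IMC scoring, diagnostic accuracy and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAM-IMC scoring, diagnostic accuracy and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camimc)
```

## The instrument

The CAM-IMC screens non-intubated patients for postoperative delirium by
combining the CAM-ICU features — acute change or fluctuating course of
mental status, altered level of consciousness, inattention — with a verbal
disorientation test, in an additive point score:

* **Fluctuation** (0/1): one point if an acute change or fluctuating
  course of mental status is present.
* **Consciousness** (0/1): one point for any Richmond Agitation–Sedation
  Scale (RASS) value other than 0. RASS runs from −5 (unarousable) to +4
  (combative); at −4/−5 the patient cannot respond to voice, so the whole
  assessment is treated as not performable rather than scored.
* **Inattention** (0–3): the patient squeezes the examiner's hand at every
  letter "A" while a ten-letter word (ANANASBAUM or CASABLANCA) is read;
  each error adds a point, capped at three. Errors are counted as total
  mistakes (missed plus false squeezes); the instrument does not
  distinguish the two.
* **Disorientation** (0–5): five verbally tested dimensions — the
  patient's age, date of birth, current place, current year, and
  situational awareness (how they came to hospital) — one point per
  dimension answered in error. The package consumes already-adjudicated
  correct/error marks; it does no free-text judging.

The total (0–10) is compared against a cut-off, 3 by default. The additive
design means inattention alone (3+ errors) or disorientation alone (3+
errors) can trigger a positive screen, while fluctuation plus altered
consciousness alone cannot — deliberately weighting the cognitive features
most. Because the cut-off is a parameter, per-cutoff accuracy tables for 3,
4 and 5 points are all reproducible from the same scored data.

```{r}
tibble::tibble(
  fluctuation = "no", rass = 0L, inattention_errors = 0L,
  dis_age = "correct", dis_dob = "correct", dis_place = "error",
  dis_year = "error", dis_situation = "error"
) |> score_cam_imc() |> dplyr::select(total, positive, assessable)
```

### Missing data and assessability

Two policies are provided. Under `"strict"` (the default) any missing
feature makes the record unassessable; it is excluded downstream and the
reason recorded. Under `"lenient"`, missing features contribute zero
points and the record is flagged `partial`; disorientation errors are
counted among the answered dimensions. Strict exclusion is the default
because partially scored totals are biased toward negativity; the lenient
mode exists for sensitivity analyses. Unarousable records (RASS ≤ −4) are
excluded under both policies, mirroring CAM-ICU practice.

## Accuracy statistics

The unit of analysis is the paired observation: one index assessment and
the same-day reference diagnosis. Within-patient clustering over the three
assessment days is ignored — each evaluation warns that intervals are
anti-conservative under strong clustering. This matches how such screening
instruments are conventionally evaluated, but it is an assumption, not a
fact about the data.

* **Proportions** (sensitivity, specificity, PPV, NPV) get exact
  Clopper–Pearson intervals via the beta-quantile formulation: the lower
  bound is the α/2 quantile of Beta(x, n−x+1), the upper the 1−α/2
  quantile of Beta(x+1, n−x), with the boundary cases pinned to 0 and 1.
  Coverage is conservative (at least nominal), which the test suite
  verifies by simulation at the study's own scale (n = 54, p = 0.9, 2000
  replicates).
* **Likelihood ratios** use the log-normal method:
  se(ln LR+) = √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)), analogously with fn
  and tn for LR−. Degenerate cells are flagged rather than silently
  numeric: fp = 0 gives LR+ = ∞ with an undefined lower bound, fn = 0
  gives LR− = 0 with an undefined upper bound.
* **AUROC** is computed twice on every call — trapezoid over the
  threshold-sweep ROC and the Mann–Whitney midrank statistic — and the two
  are asserted equal to 10⁻¹⁰ before a value is returned. For a
  dichotomized test this reduces to (sensitivity + specificity)/2 exactly.
  The per-cutoff AUROC columns of an accuracy table are computed on the
  *dichotomized* test at that cut-off; the single overall AUROC is
  computed on the raw 0–10 score. Only this reading makes the two kinds of
  AUROC simultaneously meaningful.
* **DeLong intervals** use the placement-value variance S10/m + S01/n with
  a normal interval truncated to [0, 1].
* **Youden selection** maximizes J = sensitivity + specificity − 1 over
  candidate cut-offs, breaking ties toward the lowest cut-off (favouring
  sensitivity, the safer error direction for a screen).
* **Cohen's κ** for the two index raters' positivity calls uses the
  Fleiss–Cohen–Everitt large-sample variance with normal quantiles. When
  both raters are constant and identical, chance agreement is 1 and κ is
  returned as undefined with a warning rather than a number.

Numerical conventions: the normal quantile is carried at full precision
(1.959964… for 95%), all arithmetic is done unrounded, and rounding —
half-up to two decimals — happens only in display and report formatting.

## The synthetic cohort

`cohort_config()` + `simulate_cohort()` generate observation-level data
with the structure the analysis assumes, so the full pipeline is testable
end to end. The defaults emulate a realistic development cohort: 155
elective cardiac-surgery patients aged ≥ 50, three postoperative days, two
index raters and one reference rater per patient-day, ~8.7% of
observations reference-positive, and a 33% uniform index-assessment
missingness rate so about 624 of the 930 possible index assessments are
completed.

The generative model, and why each piece looks the way it does:

* **Latent delirium course**: a two-state Markov chain per patient. Only
  an incidence is available as a calibration target, not durations, so
  persistence (P(delirious tomorrow | delirious today)) is a free
  parameter defaulting to 0.5, and the daily onset probability is solved
  by root-finding so the mean over days matches the incidence target.
  The incidence target can be interpreted at observation level (default,
  54/624 ≈ 0.087) or patient level.
* **Item responses**: given the latent state, each item's *dichotomized*
  rate is calibrated to configured operating characteristics
  (sensitivity/specificity 0.83/0.81 fluctuation, 0.35/0.89 consciousness,
  0.83/0.99 inattention, 0.80/0.99 disorientation). Inattention error
  counts follow a one-parameter family with pmf ∝ r^k on 0..10 — a
  truncated geometric when r < 1 — with r solved so P(errors ≥ 3) hits the
  target. A strictly decreasing geometric cannot place 83% of its mass at
  ≥ 3 errors (its ceiling on 0..10 is 8/11), so r > 1 is permitted for the
  delirious state, giving an increasing profile there. Disorientation
  errors are per-dimension Bernoulli draws whose common probability is
  solved so P(≥ 2 dimension errors) hits the target; this also decides
  *which* dimensions are in error.
* **Interrater agreement**: with a calibrated mixing probability w the
  second rater observes the identical presentation (identical responses);
  otherwise the two raters draw independently given the latent state.
  κ(w) has a closed form from the state-conditional positivity
  probabilities — themselves computed exactly by convolving the four
  component point distributions — and w is found by root-finding so κ
  equals the 0.80 target. Targets below the conditional-independence floor
  κ(0) or above 1 are rejected with the feasible range named.
* **Covariates**: age from a normal (mean 67, sd 9) truncated to [50, 95]
  — the truncation skews it slightly right, matching a median of ~68 with
  IQR ~61–73; 21.3% female; Mini-Cog on 0–5 with median 4 and about a
  quarter of patients under the impairment threshold (< 3); baseline
  orientation mostly 5/5 and baseline RASS mostly 0. Covariates are drawn
  independently of the latent state: no usable conditional association is
  available to calibrate one.

`expected_performance()` exposes the analytic consequences of a
configuration — the implied instrument sensitivity/specificity at a
cut-off, prevalence, and item rates — and these are the "configured
truths" that parameter-recovery tests compare simulation output against.

```{r}
expected_performance() |> dplyr::select(sensitivity, specificity, prevalence)
```

### What the simulator does *not* emulate

These are deliberate simplifications, and they bound what a passing test
suite shows about real data:

* Items are conditionally independent given the latent state (apart from
  the shared-presentation mixing between raters). Real delirium features
  are positively dependent. One visible consequence: the analytic
  cut-off-3 operating characteristics implied by the calibrated item
  marginals (≈0.99 sensitivity / 0.96 specificity) are somewhat better
  than a real cohort's, and the synthetic raw-score Youden optimum lands
  at 4 rather than 3. Recovery tests therefore target the *configured*
  truths, not any external per-cutoff table.
* No association between covariates and delirium: subgroup analyses on
  simulated data have, by construction, the same operating
  characteristics as the whole cohort.
* Missingness is uniform, not structured by staffing or patient state;
  delirium severity, subtype (hypo-/hyperactive) and laboratory values
  are not modelled; the reference rater is perfect by default
  (`reference_error = 0`).

## Problem sizes used by the test suite

Scales were chosen so Monte-Carlo error is small relative to the tolerance
being checked: Clopper–Pearson coverage uses 2000 binomial replicates;
AUROC dual-route equivalence uses 300 random instances of size ≤ 12
against a rank-statistic oracle; κ recovery uses cohorts of 4000 patients
(> 5000 complete rater pairs, tolerance ± 0.05); and the operating-
characteristic recovery check pools three independent 10 000-patient
replicates and compares each recovered rate against 3 Monte-Carlo
standard errors of the pooled estimator — pooling is used because roughly
ten simultaneous 3-SE comparisons on a single replicate would false-alarm
by chance alone in about one run in four, while the pooled band is
strictly tighter and hence more sensitive to genuine calibration bias.

## Known limitations

* Clustering of observations within patients is ignored throughout, as is
  conventional for this design; intervals are anti-conservative if
  within-patient correlation is strong.
* The κ interval is a large-sample normal approximation; at a few hundred
  pairs it can disagree with bootstrap intervals in the second decimal.
* The exact flowchart branch order of the bedside instrument is not
  encoded; the additive-total-with-cut-off reading is used, which is the
  form all per-cutoff results depend on.
* Whether fluctuation is judged against the preoperative baseline or the
  prior day is left to the assessor: the instrument consumes the
  adjudicated flag.
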