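---
title: "Tiered adaptive screening: model, evaluation machinery, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered adaptive screening: model, evaluation machinery, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierscreen)
```

## The screening model

`tierscreen` implements a three-tier adaptive screening procedure for four
common mental disorders — depression, anxiety (a single collapsed
anxiety-disorder construct), posttraumatic stress, and insomnia — built from
five validated self-report symptom scales totalling 56 Likert items:

* **Tier 1 — distress gateway.** The 13-item Refugee Health Screener
  (RHS-13, items 0–4, sum 0–52) is administered to everyone. A score below
  11 terminates the procedure: the respondent screens negative on all four
  disorders after answering only 13 items.
* **Tier 2 — symptom differentiation.** Distress-positive respondents
  answer all four short-form gates together (9 items): PHQ-2 (cutoff ≥ 2),
  GAD-2 (≥ 2), a 4-item PCL-5 short form (≥ 5), and the sleep-interference
  item of the ISI-7 (≥ 2). If every gate is negative the procedure ends
  after 22 items.
* **Tier 3 — severity.** For each positive gate, the corresponding full
  scale is presented **minus the items already answered in Tier 2**; the
  Tier-2 responses carry over into the full-scale sum. Full-scale cutoffs
  for a moderate-symptom (screen-positive) outcome: PHQ-9 ≥ 10, GAD-7 ≥ 10,
  PCL-5 ≥ 32, ISI-7 ≥ 11.

A disorder screens positive only when all three tiers agree. Every cutoff
uses the ≥ convention, so dichotomisation is monotone: raising any item
response can never turn a positive screen negative, nor shorten the
administration.

All of this is configuration, not code: `load_battery()` reads a YAML
description of scales, items, ordinal ranges, tier membership, short-form
maps and cutoffs, and `default_battery()` ships the configuration above.
Item ordinal ranges follow the published instruments (RHS-13 and PCL-5 and
ISI-7 items 0–4, PHQ-9 and GAD-7 items 0–3); none of the five instruments
reverse-scores, so scale scoring is a validated plain sum. The 4-item
PCL-5 short-form membership is the one genuinely open configuration choice
(its primary source does not constrain our default); we ship items 1, 4, 7
and 10 and keep every downstream computation driven by the configured map,
so replacing the membership is a one-line YAML edit.

## Adaptive engine and retrospective simulation

Two independent implementations of the tier logic exist on purpose.

`start_session()` / `submit_responses()` / `finalize()` form a stateful,
append-only engine: each submission must cover exactly the pending items,
outcomes are dichotomised as soon as a tier completes, and every response
is recorded in an event log that `write_session_log()` serialises to JSON
and `replay_session()` can re-feed deterministically. Submissions are
immutable and answers cannot be revised — a deliberate provenance choice
for a screening instrument, where the audit trail should reconstruct
exactly what the respondent saw and answered.

`simulate_tiered()` applies the same gates retrospectively to a complete
wide response table (one row per respondent, one column per item) as a
vectorised computation over the score matrix. Because the two routes share
no code beyond scale definitions, the test suite's equivalence property
(identical flags, termination reasons and item counts on 1,000 random
response vectors) is a genuine dual-route check, not a tautology.

**Item burden.** `burden_reduction()` reports the percentage reduction in
administered items relative to administering the four full scales
non-adaptively — a 43-item baseline. The Tier-1 gateway is deliberately
outside the baseline: it is the price paid for adaptivity, so a respondent
who completes all 56 items shows a *negative* reduction (−30.2%), while a
symptom-free respondent answers 13 of 43 — a 69.8% reduction — and a
respondent positive only on the anxiety gate answers 13 + 9 + 5 = 27 items,
a 37.2% reduction. Percentages are reported to one decimal, rounding half
away from zero (`round_half_up()`), the convention used for every reported
percentage and applied only at the reporting layer.

**Culling.** `culling_report()` treats each tier's continue/terminate
decision as a diagnostic test against reference labels and reports its
TP/FP/TN/FN per disorder and for "any diagnosis"; the four cells always sum
to the respondents entering the tier.

## Accuracy machinery

`confusion()` cross-classifies screen flags against reference labels
(`confusion_from_margins()` reconstructs a 2×2 table from a published
sample size, reference positives, test positives and concordant
positives). `dta_metrics()` computes sensitivity, specificity, PPV, NPV and
accuracy as percentages with 95% Wald intervals
\(p \pm 1.96\sqrt{p(1-p)/m}\) over each metric's own denominator, clipped
to [0, 100]. We chose the Wald form because it matches the interval bounds
conventionally reported for this procedure (including upper bounds clipped
at 100); its well-known undercoverage at small n is tolerated and verified
by a simulation test (coverage within 90–97% at n = 70, p = 0.8). A metric
with a zero denominator is reported as an explicit undefined flag — never
silently as 0 or 100.

`cohen_kappa()` implements chance-corrected agreement
\(\kappa = (p_o - p_e)/(1 - p_e)\) from the 2×2 marginals. Reporting
precision is 1 decimal for percentages and 2 for κ, half-up. One
reconstruction detail worth noting: recomputing κ from a published table's
own marginals can disagree with the printed value in the last digit (our
test suite pins one such value at its recomputed 0.52 rather than the
printed 0.53), and pooled positive identification
(`pooled_positive_identification()`, \(\sum tp / \sum(tp+fn)\)) follows the
identified-fraction denominators as printed even where a prevalence table
suggests a different count — both are documented conventions, not fitted
choices.

`cutoff_sweep()` re-evaluates one scale over candidate cutoffs (e.g. the
proposed insomnia thresholds 8, 11, 14) and `per_individual_correctness()`
counts, per respondent, how many of the four disorder calls agree with the
reference standard (0–4), plus the share of discordant calls that are
false positives. `prevalence_and_comorbidity()` produces the descriptive
tables (per-disorder prevalence under both index test and reference,
pairwise comorbidity, multimorbidity distribution).

## The synthetic cohort generator

No participant data ship with the package; `generate_cohort()` makes the
whole pipeline testable. Per respondent it draws a latent severity vector
over the five constructs (distress, depression, anxiety, ptsd, insomnia)
from a multivariate normal with a configurable correlation matrix; a
diagnosis is present when the disorder's latent exceeds
\(\Phi^{-1}(1-\text{prevalence})\), then flips with probability
`diagnosis_noise`; each ordinal item discretises
\(\lambda\,\theta + \sqrt{1-\lambda^2}\,\varepsilon\) through per-scale
category thresholds — a graded-response-style scheme in which internal
consistency, inter-scale correlation and prevalence are all controlled
directly and every pipeline-facing quantity is emergent rather than
hard-coded.

Defaults, chosen once and frozen, emulate a high-prevalence refugee
screening cohort: prevalences (0.286, 0.243, 0.286, 0.371) for depression,
anxiety, ptsd, insomnia; compound-symmetric latent correlation 0.85, which
after discretisation and measurement attenuation lands observed inter-scale
Pearson correlations near 0.75–0.80 (the 0.70–0.89 band typical of these
instruments in distressed samples); item loading \(\lambda = 0.8\), giving
Cronbach α ≈ 0.90–0.97 across the five scales; diagnosis noise 0.05 so
index-test/reference concordance resembles a clinical-interview reference
(κ ≈ 0.5–0.7) instead of being degenerate; and category thresholds placed
so default mean scale scores fall in the moderate range (≈ 21.7 / 10.0 /
8.2 / 29.8 / 11.7 for RHS-13 / PHQ-9 / GAD-7 / PCL-5 / ISI-7 at n = 5,000).
`calibration_report()` recomputes all of these achieved quantities from a
generated cohort using the same operations applied to real data.

What the generator deliberately does **not** model: missing responses,
response styles such as acquiescence, differential item functioning across
languages, and any dependence of label noise on severity. Passing tests
therefore demonstrate the software's correctness and the procedure's
behaviour under a plausible data-generating process — not the instrument's
clinical validity in any real population.

Determinism: a cohort is a pure function of its `cohort_spec` (including
the integer seed); generation saves and restores the caller's RNG state,
and draws occur in a fixed documented order (latents, labels, flips, then
item noise scale by scale).

## Numerical and design choices

* **Rounding** half away from zero, at the reporting layer only; all
  internal computation is full precision.
* **Missing data** are an error by default everywhere (`strict = TRUE`);
  permissive modes drop the affected respondent with a warning and never
  impute.
* **Tier-2 presentation** is all-gates-together; gate decisions are made
  only after all 9 Tier-2 items are answered, and Tier-3 scales are
  presented in battery order. No randomisation of order anywhere.
* **Degenerate inputs** are flagged: zero total-score variance makes α
  undefined (`NA` + warning), a zero-variance scale voids its correlation
  entries, expected agreement of 1 makes κ undefined.
* **Sample variance** (n − 1) convention for α.
* **Problem sizes** in the test suite: the engine/simulation equivalence
  property runs on 1,000 random response vectors, metric identities on
  hundreds of random tables, and the pipeline-recovery checks use n = 2,000
  (high-separation spec: loading 0.95, zero label noise — every disorder
  recovered with sensitivity ≥ 90%) and n = 5,000 (default spec
  calibration). These sizes give the Monte-Carlo assertions comfortable
  margins while keeping the suite fast.

## Worked example

```{r example}
battery <- default_battery()
battery

cohort <- generate_cohort(cohort_spec(n = 100, seed = 5), battery)
ev <- evaluate_screen(cohort$responses, cohort$labels, battery)
cat(write_report(ev$reports["depression"], "markdown"))
round_half_up(ev$pooled_identification, 1)

results <- ev$results
table(results$termination_reason)
summary(burden_reduction(results, battery))
```

## Known limitations

The anxiety screen is a single GAD-7-based flag standing in for several
anxiety disorders, so disorder-specific accuracy for panic or social
anxiety is out of reach by design. Wald intervals undercover at small
denominators. The burden baseline (43 items) is a convention — against a
56-item baseline every reduction would look larger. And the synthetic
generator, however calibrated, cannot substitute for a validation study on
real respondents.
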