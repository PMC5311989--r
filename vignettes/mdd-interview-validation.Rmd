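---
title: "Methods: structured MDD interviewing, diagnostic validation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured MDD interviewing, diagnostic validation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddscreen)
```

## The diagnostic model

`mddscreen` implements a text-mode structured interview for a DSM-5 major
depressive episode and the statistics used to validate such an instrument
against a clinician's diagnosis. The diagnostic rule is a decisional
algorithm tree over the DSM-5 criteria:

* **A-criterion symptoms** (nine): depressed mood (A1), anhedonia (A2),
  appetite/weight change (A3), sleep disturbance (A4), psychomotor change
  (A5), fatigue (A6), worthlessness/guilt (A7), impaired concentration
  (A8), suicidal ideation (A9). A positive diagnosis requires **at least
  five** symptoms present, **including at least one core symptom** (A1 or
  A2).
* **Duration gate**: the symptoms co-occurred over the same two-week
  period.
* **Criterion B**: clinically significant distress or functional
  impairment.
* **Exclusions**: substance-induced or general-medical cause (C),
  a psychotic disorder better explaining the picture (D), a lifetime
  manic/hypomanic episode (E).

Of the $2^9 = 512$ symptom presence/absence patterns, exactly
$\sum_{k \ge 5}\binom{9}{k} - \sum_{k \ge 5}\binom{7}{k} = 256 - 29 = 227$
satisfy the symptom rule; with the gates favourable these are precisely the
patterns `classify_mdd()` accepts, and the test suite verifies this by
exhaustive enumeration against an independent brute-force restatement of
the rule.

## The interview engine

The question bank is a validated, acyclic branching graph (one node per
question, each bound to a criterion element), stored as a JSON/YAML
document so alternative banks are drop-in. The bundled default bank has 15
nodes: the nine symptom probes, the duration and impairment gates, and four
exclusion screens — criterion C is probed twice (substance-induced and
general-medical cause) because the two causes are asked about differently
in practice; either answer triggers the exclusion. A reduced
`core_question_bank()` without exclusion screens is bundled for sensitivity
analysis, since published screeners differ in whether exclusion criteria
are probed by the instrument or left to the clinician. Criteria a bank does
not probe at all are treated as unremarkable by design; criteria a bank
probes but a particular interview did not reach remain *unasked*, and
`classify_mdd()` refuses to classify whenever an unasked field could change
the decision (it evaluates the rule under the most and least favourable
completion and requires agreement — the rule is monotone per field, so the
two evaluations bound the answer).

Questions are asked in the fixed order A1–A9, duration, impairment, C, D, E
absent contrary branch rules, which makes interviews deterministic and
replayable: a saved transcript (JSON, with bank version and per-answer
timestamps) replays to the identical diagnosis. One branching optimization
is enabled by default: when **both** core symptoms are denied, the
interview terminates negative without asking the remaining questions, since
no completion can reach five symptoms including a core one. This early-exit
rule is guarded by a *skip-safety* test that enumerates all $2^{15}$ full
response profiles over the bundled bank and checks that early-exit and
ask-everything interviews agree everywhere. Response encoding is strict:
yes/no synonyms (English and French) are accepted case-insensitively, and
anything else yields a re-prompt signal rather than a silent coercion.

## Instruments

`score_bdi()` scores the 21-item Beck Depression Inventory II (items 0–3,
total 0–63) with the revised-manual severity cut-offs 0–13 minimal, 14–19
mild, 20–28 moderate, 29–63 severe (boundaries inclusive). `score_aes()`
scores the 6-item Acceptability E-scale (items 1–5, total 6–30). Some
reports describe the AES total as a "0–30" scale; a sum of six 1–5 items
cannot fall below 6, and the package follows the instrument's definition.
Missing items are rejected rather than imputed. `cronbach_alpha()` uses
sample variances ($n-1$ denominator) for both the item and total-score
variances; the convention matters at small $n$ and is stated here because
published reliability coefficients rarely name it.

## Diagnostic validation statistics

`performance()` reports sensitivity, specificity, PPV and NPV with **exact
Clopper–Pearson** 95% intervals, computed through the beta-quantile closed
form and cross-checked in the tests against a bisection inversion of the
binomial tails and against `binom.test()`. Exact intervals are
conservative; a property test confirms ≥95% empirical coverage over 2,000
simulated draws at $p \in \{0.1, 0.5, 0.9\}$, $n \in \{20, 144\}$. Metrics
with empty denominators are flagged undefined, never reported as zero.

A binary (single-threshold) index test has one ROC operating point, so
`auc_binary()` uses the trapezoidal area
$\mathrm{AUC} = (\mathrm{sens} + \mathrm{spec})/2$ with the Hanley–McNeil
standard-error approximation for the confidence interval and the test
against 0.5. DeLong-type resampling inference is ill-defined at a single
operating point, which is why the simpler approximation is the default; on
the reference counts (TP 17, FN 18, FP 10, TN 134) it gives
AUC 0.71 [0.60–0.81], whose lower bound differs by one point in the second
decimal from intervals produced by some commercial packages.

Reported tables round metrics to integer percents and the AUC to two
decimals, using round-half-away-from-zero (the convention of clinical
tables), while raw proportions are always retained alongside.

### Severity stratification

`stratified_performance()` computes per-stratum sensitivity over the
reference-positive patients whose BDI-II total falls in the stratum
(default strata: the BDI-II severity bands). Published stratified tables
are often ambiguous about the negative side: a stratified specificity that
*exceeds* the overall specificity in every stratum is only arithmetically
possible if the false-positive numerator is restricted to the stratum
while the denominator keeps the full negative pool. The default convention
is therefore: denominator = all reference-negatives, false positives
counted only when their BDI-II total falls in the stratum. Both alternative
readings are available (`fp_convention = "all"` charges every false alarm
to every stratum; `negatives = "stratum"` restricts the denominator
itself), because the correct convention for a given published table cannot
always be determined from the table alone. A one-stratum analysis spanning
the whole BDI range reproduces the unstratified results under the default,
which the tests assert as a partition identity.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of an outpatient
validation study without any clinical data. Its defaults are the study
conditions the package targets, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n` | 179 | analysed cohort size |
| `prevalence` | 35/179 ≈ 0.196 | observed MDD prevalence |
| `severity_mix` | 0.400 / 0.343 / 0.257 | mild/moderate/severe split among cases |
| `detect_prob` | 0.21 / 0.57 / 0.73 | per-severity interview sensitivity |
| `false_alarm` | 10/144 ≈ 0.069 | false-positive rate among non-cases |
| `bdi_mean_pos`, `bdi_sd_pos` | 22.3, 6.9 | latent BDI-II in cases |
| `bdi_mean_neg`, `bdi_sd_neg` | 7.8, 7.3 | latent BDI-II in non-cases |
| `inter_item_corr` | 0.25 | calibrated; see below |
| `aes_mean`, `aes_sd` | 25.4, 4.6 | latent AES total |

Severity-dependent detection is modelled at the *outcome* level: the
generator first draws whether the interview fires, then samples a symptom
pattern **uniformly among the 227 qualifying patterns** (firing) or the 285
non-qualifying ones (not firing), with the duration/impairment/exclusion
gates held favourable. Uniform-within-class is the minimal-assumption
choice when only outcome rates, not symptom-level error processes, are
known. By construction, classifying the generated profile — or running the
full interview through `respond_to_interview()` — reproduces the sampled
outcome exactly, which the tests verify end-to-end.

Latent BDI-II totals for cases are drawn truncated to the sampled severity
band; for non-cases they are censored (clipped) to 0–63 rather than
truncated, because with a mean of 7.8 near the floor, truncation would
inflate the group mean by about two points while censoring keeps the bias
near half a point. The printed case-group moments and the printed severity
mix are themselves slightly inconsistent (a 22.3-mean normal truncated to
the three bands in the 40/34.3/25.7 mix has mean ≈ 23.2), so recovered
case means sit about one point above 22.3; the recovery tests use the
±1.5-point window averaged over seeds.

BDI-II item vectors distribute each latent total over 21 items: per-item
latent value plus Gaussian noise whose standard deviation is derived from
the target common inter-item correlation $\rho$ via the equicorrelation
identity $\sigma_e = s_m\sqrt{(1-\rho)/\rho}$, stochastic rounding, 0–3
clipping, and finally a sum-repair pass (random ±1 steps on adjustable
items) so each row sums exactly to its latent total. Sum-repair removes the
upward bias that plain round-and-clip introduces near the scale floor and
makes degenerate cases exact (zero latent variance ⇒ identical item sums).
The default $\rho = 0.25$ was calibrated once so that cohort-level
Cronbach's alpha at $n = 179$ centres on 0.89 (observed 0.879–0.911 across
30 seeds); discretization pushes realized alpha slightly above the
$k\rho/(1+(k-1)\rho)$ asymptote because the grouped cohort adds
between-group variance. AES items use the same allocation on the 1–5
range, independent of depression status, since the instrument measures
acceptability of the interview rather than symptoms; censoring at the 30
ceiling pulls the realized mean to ≈ 25.1.

What the generator does **not** emulate: item-level symptom/severity
coupling (a severe patient's *specific* symptom pattern is uniform within
its class, not weighted toward severity-typical symptoms), comorbidity
structure of a sleep-clinic population, order effects between the two
interviews, and any dependence of the false-alarm process on BDI score.
Passing recovery tests therefore show that the *pipeline* is correct and
calibrated, not that the instrument would achieve these operating
characteristics on real patients.

## Determinism and numerical choices

* One master seed drives the whole generation; every draw consumes a
  single RNG stream in fixed order, so equal seeds give bitwise-identical
  cohorts, and the caller's RNG state is restored afterwards.
* Truncated normals are sampled by inverse-CDF (no rejection loops).
* Ties in reported percents are rounded half away from zero.
* `clopper_pearson()` returns closed [0, 1] bounds at the boundary counts
  (0 successes ⇒ lower bound exactly 0; all successes ⇒ upper bound
  exactly 1).
* Degenerate inputs fail loudly: zero total-score variance in
  `cronbach_alpha()`, empty denominators in `performance()`, unresolved
  relevant fields in `classify_mdd()`, truncated response streams in
  `run_interview()` (the partial transcript is preserved on the condition
  object).

## Problem sizes used by the test suite

The suite enumerates all 512 symptom patterns (and a 64-pattern random
subset against all 32 gate combinations), all 32,768 full response
profiles of the bundled bank for skip-safety, simulates 100,000 patients
for rate recovery (±1 percentage point), pipes 1,000 patients end-to-end
through the interview engine, and checks reliability calibration across 20
seeds at the study size of 179. These sizes keep the full suite under
about a minute while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The question wordings are plain-language stand-ins bound to the DSM-5
  elements; the BDI-II's copyrighted item texts are not reproduced — the
  instruments module scores numeric item vectors only.
* Only binary questions are supported in banks; graded probes would need
  an extended response domain and branch rules.
* The single-operating-point AUC is a summary of one (sens, spec) pair;
  it is not comparable to AUCs of continuous-score classifiers.
* Stratified confidence intervals use the same stratum conventions as the
  point estimates; when a published table's denominators are ambiguous,
  matching its brackets may require trying the alternative conventions.
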