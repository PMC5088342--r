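---
title: "Methods: adverse-event incidence and diversity across age groups"
author: "aecohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adverse-event incidence and diversity across age groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aecohort)
```

## The problem

Public trial registries report safety outcomes at the *trial arm* level:
for each arm, an enrollment, a mean participant age, and for each
reported adverse event (AE) the number of subjects affected and the
number at risk. Pooling these summaries across many trials supports a
population-level view of how AE burden varies with participant age —
something individual trials cannot show. `aecohort` implements that
analysis as a tested pipeline over a documented registry-style XML
dialect, together with a synthetic cohort generator so every stage can
be validated without a registry download.

Two quantities are computed per age group:

* **Incidence** — the micro-average (pooled proportion): total affected
  participants divided by total at-risk participants across the group's
  arms,
  $\hat p_g = \sum_a x_a \big/ \sum_a n_a$.
* **Diversity** — the number of *distinct* AE types reported in an arm
  (an arm reporting heart failure, dizziness and nausea has diversity
  3), summarized as the arm-level mean per group, and broken down over
  the 26 MedDRA system organ classes (SOCs).

Groups are compared against a reference group (default 20-29 years, the
lowest-incidence group in registry data) by risk difference, rate ratio
and Welch *t*-tests; per-event cross-group comparisons contrast the
per-trial incidence of one event inside a group with trials reporting
the same event outside it.

## Age binning

Arms are binned by *reported arm mean age* into eight groups: 0-9,
10-19, ..., 60-69 and 70-100. The first seven bins are half-open
$[L, L+10)$ and the terminal bin is closed $[70, 100]$, so the bins tile
$[0, 100]$ without overlap; a mean age of exactly 10 falls in 10-19.
The half-open convention at decade boundaries is this package's choice
(registry reports do not dictate one). Arms with a missing or
out-of-range mean age are excluded from group analyses and always
surfaced in an exclusions report — binning is never silent.

## Term normalization and SOC mapping

Registry AE terms arrive as free text in mixed terminologies. Full
concept normalization (UMLS/MetaMap-style) is deliberately out of
scope: it is an external, licensing-dependent tool with its own error
rate. Instead, terms are canonicalized deterministically (lower-case,
punctuation to spaces, whitespace collapsed — an idempotent transform)
and resolved by exact match against a term → SOC table; a shipped
default covers ~140 common registry terms. Synonyms can be emulated by
aliasing rows in the table. A registry-provided SOC annotation on an
event always wins over the table, and unresolvable terms get the
`UNCLASSIFIED` sentinel — mapping never fails, and the unclassified
remainder is tracked as a diagnostic row rather than folded into the 26
SOC rows.

Diversity deduplicates on canonical term strings. Concept-level
deduplication would merge true synonyms ("cardiac failure" ~ "heart
failure") and so report slightly lower diversity; with the shipped
exact-match table the count is an upper bound in that respect.

## Incidence statistics

Each arm's affected total uses the registry's deduplicated
`overall_affected` when reported. When absent, the largest single-event
affected count is used as a *lower bound* and flagged — participants
affected by several events cannot be deduplicated from event-level
counts alone. Incidence for a single event always uses the event's own
at-risk denominator (the registry allows it to differ from enrollment);
micro-averages use arm enrollment.

The 95% interval on a pooled proportion is the normal-approximation
(Wald) interval $\hat p \pm z\,\mathrm{se}$ with
$\mathrm{se} = \sqrt{\hat p(1-\hat p)/N}$ and $z$ fixed at 1.96 for the
95% level. Risk differences between groups use the two-proportion
standard error
$\sqrt{p_a(1-p_a)/n_a + p_b(1-p_b)/n_b}$ with $n$ the group's total
at-risk count. Exact binomial intervals and multiplicity correction
across the seven group-vs-reference tests are intentionally omitted
(matching common registry-analysis practice; a Benjamini-Hochberg
option exists for the per-event screen only).

The *t*-test variant is Welch's unequal-variance test, two-sided, on
per-arm incidence values: group arm counts and variances differ
greatly, which makes the equal-variance pooled test indefensible as a
default. Implementation delegates to `stats::t.test(var.equal =
FALSE)`; degenerate inputs (fewer than two values per side, or zero
variance in both samples) return a flagged result with no p-value
instead of an error. The unit of analysis is the trial arm, with a
switch (`aggregate = "trial"` in `compare_groups_to_reference()`) to
average a trial's arms first.

## Per-event cross-group comparison

For event $e$ and group $g$, the target sample holds per-trial mean
incidences of $e$ over each trial's arms in $g$; the comparison sample
holds per-trial incidences from trials reporting $e$ only outside $g$.
A trial with arms on both sides contributes its in-group arms to the
target and is excluded from the comparison — disjoint samples are a
precondition of a valid two-sample test. Within a trial, arms are
averaged (not participant-pooled; a pooling variant is a documented
alternative, not implemented). `top_events()` then drops terms on a
nonserious filter list (the shipped list is a small placeholder), keeps
comparisons with $p < \alpha$ (default .01), and ranks within group by
ascending p, ties broken by descending target-group incidence.

**Small-sample caveat.** When the target side is small (roughly under
15 trials) and the pooled comparison side is several times larger, the
Welch test's two-sided tail is inflated for these skewed, discrete
per-trial incidence values: direct simulation at $\alpha = .01$ gives
rejection rates near 0.05 for 8-vs-60 trials, 0.033 for 15-vs-100,
0.023 for 30-vs-200, and nominal-or-below for balanced sides. Registry-
scale analyses (hundreds of trials per side) are unaffected, and the
calibration suite runs in that regime; desk-scale screens should raise
`min_trials` rather than trust p-values from 2-3 target trials.

## SOC diversity matrix and ranking

The 26×8 matrix cell (SOC, group) is the mean over the group's arms of
the count of distinct event types in the arm mapping to that SOC (arms
with none contribute 0, so per arm the row sums plus the unclassified
remainder conserve total diversity exactly). Support is counted in
*distinct trials* with at least one event in the SOC; cells under 30
trials are flagged low-support. Within each group, SOCs are ranked by
descending diversity with competition (min-rank) ties, flagged where
they occur; the total rank orders SOCs by the unweighted mean of their
eight group values (an alternative rank-sum reading is possible; the
unweighted mean is the simpler faithful choice).

## The synthetic generator

`generate_cohort()` draws, per arm: an age group from
`age_group_weights`; a mean age uniformly *inside* the assigned bin (so
binning recovery is exact by construction); an enrollment uniform in
range; then a participant × term matrix of independent Bernoulli draws.
Per-term affected counts are the column sums (binomial margins) and
`overall_affected` is the number of participants with ≥ 1 event, so the
two are mutually consistent; zero-affected terms are omitted, as the
registry never reports them.

Per-group term probabilities are calibrated: base probabilities are
rescaled by a per-group scalar $s_g$ (solved with `uniroot`) so that
$1 - \prod_t (1 - s_g p_t)$ equals the configured group incidence —
this makes incidence parameter recovery well-defined. `group_effect`
multipliers (e.g. doubling one term in one group) are applied *after*
calibration and clipped to $[0, 0.99]$ with a warning, so a spike is a
genuine departure from the group target. The ground truth records the
final per-group probabilities, the achieved overall incidence, and the
analytic expected diversity per arm,
$E[D_g] = \mathbb{E}_n \sum_t \left(1 - (1 - p_{t,g})^n\right)$
averaged over the integer enrollment range.

The default configuration (200 trials, 1-3 arms, enrollment 40-200,
age weights skewed older, group incidence 0.31/0.24/0.21/0.24/0.27/
0.30/0.28/0.27) qualitatively mirrors the registry pattern — incidence
peaks in the youngest and the 50-59 groups with a trough at 20-29 — and
is illustrative, not calibrated to any corpus. Because incidence
calibration rescales the whole pool, expected diversity co-varies with
incidence under the defaults; configuring group-specific pools or
multipliers decouples them. What the generator does **not** emulate:
correlated events within a participant (comorbidity), trial-level
heterogeneity in reporting practice, within-arm age spread, and
real-world term misspellings beyond whitespace/punctuation variants.
Passing recovery tests therefore shows the pipeline's arithmetic and
plumbing are correct under the stated sampling model — not that the
model captures real registry data.

The nonserious reporting threshold reproduces a registry convention:
a nonserious event is kept in a trial only if its frequency exceeds the
threshold (conventionally 5%) in at least one arm of that trial;
serious events are always kept and `overall_affected` is untouched.
This is exactly the undercount mechanism that registry analyses must
live with for nonserious events.

## Numerical and degenerate-input choices

* Counts parse as exact integers; mean age round-trips through the XML
  dialect at full double precision (`%.17g`).
* Empty groups yield flagged empty summaries, never errors; a
  single-arm group has a mean but flagged-unavailable se/CI.
* A zero denominator in a rate ratio returns `NA` with a warning.
* Ranking treats `NA` columns (empty groups) as unrankable (`NA`
  ranks); ties share the minimum rank and are flagged.
* Reports round nothing internally; percentages and ratios are
  presented at 2 d.p. only at the reporting layer.

## Problem sizes in the test suite

The suite validates oracle equivalence on 100 small random cohorts,
parameter recovery on a 200-trial cohort (within 3 standard errors per
group for incidence and diversity), Welch type-I error on 1,000 null
replicates (expected in [0.03, 0.07] at $\alpha = .05$), Wald coverage
on 1,000 replicates (expected in [0.93, 0.97]), spiked-event power on
30 replicates of 100-trial cohorts, and the null event-discovery
fraction on 50 cohorts of 500 trials each (expected in [0.002, 0.03]
at $\alpha = .01$). These sizes are the package's choices: large enough
for the stated bands to be informative, small enough to run routinely.

## Known limitations

* Arm-level analysis only: patient-level diversity and cross-event
  deduplication are impossible from registry summaries, and the
  lower-bound fallback for `overall_affected` is flagged, not hidden.
* Exact-match SOC mapping cannot resolve unseen term variants; the
  `UNCLASSIFIED` diagnostic row makes the residue visible.
* The per-event screen's p-values are anti-conservative for very small
  target samples (see above).
* No multiplicity correction by default across group-vs-reference or
  per-event tests; the BH option is off by default by design.
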