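---
title: "Measuring skeletal-related events from administrative claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skeletal-related events from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelevent)
```

## The measurement problem

Skeletal-related events (SREs) — pathologic fracture (PF), spinal cord
compression (SCC), bone palliative radiotherapy (RAD), and bone surgery
(BS) — are a composite endpoint in metastatic cancer. In a clinical trial
they are adjudicated prospectively; in administrative claims they must be
inferred from billing codes, and there is no billing code for "an SRE".
Two measurement choices dominate the result:

1. **Which codes count as an event.** For each subtype (except BS, whose
   procedure codes are unambiguous) one can use a *high-specificity* list —
   codes nearly pathognomonic for the subtype, at the cost of missing
   events — or a *high-sensitivity* list that adds less specific codes and
   risks over-counting. `skelevent` stores the sensitivity list as a
   disjoint *extension* of the specificity list, so the nesting
   (sensitivity ⊇ specificity) holds by construction.
2. **How claims are grouped into episodes.** Claims bill utilization, not
   clinical onset: a radiation course or fracture work-up spreads over
   weeks. A clean *window* of length $L$ days clusters event-days of one
   subtype into episodes; the trial convention is $L = 21$, and the
   package measures sensitivity at $L \in \{14, 21, 28\}$.

The package implements the full chain — code matching, case definitions,
cohort selection and censoring, trauma exclusion, episode clustering,
prevalence and cumulative-incidence measures — plus a synthetic claims
generator with known ground truth, because the motivating data (linked
cancer-registry/Medicare claims) are restricted-access.

## Case definitions

Two named definitions are built in, differing per subtype in which tier
counts:

| subtype | `base_case` | `alternative` |
|---|---|---|
| PF  | specificity + extension | specificity only |
| SCC | specificity only | specificity + extension |
| RAD | specificity only | specificity + extension |
| BS  | single list | single list |

The base case uses the sensitive fracture list because offices often bill
a cancer-related fracture with an "other fracture" rather than a
"pathologic fracture" (733.1X) code; it keeps SCC and RAD specific because
their extended lists (myelopathy disc disease; IMRT/SRS delivery) are
frequently unrelated to bone metastasis. The prior-SRE screen used at
cohort entry takes the **union** of all tiers and subtypes, so the
included cohort is identical whichever definition is evaluated afterwards
— which definition the screen "should" use is genuinely open, and the
union is the only choice that makes downstream prevalence comparisons
share a denominator.

### The fracture trauma rule

An "other fracture" event on day $d$ is voided when the patient has a
non-exempt accident/fall E-code claim dated in $[d-14,\,d]$: such
fractures are attributed to the trauma, not to bone weakened by tumor.
Both boundaries are inclusive — a trauma code on the fracture day itself,
or exactly 14 days before, excludes; 15 days before does not. Falls on the
same level (E885/E886) are exempt: a low-energy fall is more plausibly a
consequence of the weakened bone than its cause. The exemption is literal:
an exempt code never triggers exclusion, but it does not shield a distinct
non-exempt trauma code in the window. Specificity-tier (733.1X) fractures
are never trauma-excluded. The lookback (`trauma_lookback_days`, default
14) lives in `study_config()`.

Three literature variants are available as flags on `sre_definition()`,
all off by default because the built-in definitions do not impose them:
a same-day hierarchy (clinical events PF/SCC suppress same-day treatment
events RAD/BS), a RAD concurrency filter (RAD kept only with a same-day
bone-metastasis/fracture/cord-compression/bone-pain diagnosis, supplied by
`RAD_CONTEXT` codebook entries), and a BS trauma lookback mirroring the
fracture rule (the same inclusive $[d-14, d]$ window is used for
consistency; published phrasings of "the 14 days prior" are not more
precise). The hierarchy defaults off for an arithmetic reason as well:
when per-subtype episode totals sum exactly to the overall total, no
cross-subtype suppression can have occurred, and the package preserves
that additivity (`ANY` row = sum of subtype rows) as an invariant.

## Cohort selection and censoring

`select_cohort()` applies, in a fixed order (first failure logged):
minimum age at diagnosis (66, so the year before diagnosis is observable
under Medicare eligibility at 65); known diagnosis month; diagnosis not
post mortem; no cancer history in the prior five years; continuous Parts
A/B enrollment over the 365 days before diagnosis with zero gap-day
tolerance (abutting intervals count as continuous); and no pre-diagnosis
claim matching any event code. Day-of-diagnosis claims belong to
follow-up. The published study does not state its attrition order; a fixed
order was chosen so the exclusion log is deterministic and reasons are
mutually exclusive. Follow-up runs from diagnosis to the earliest of HMO
enrollment, fee-for-service disenrollment (first uncovered day), death,
and the administrative study end (2010-12-31) — HMO and capitated spells
do not generate fee-for-service claims, so observation must stop there.

## Episode clustering

Event-days are day-granular (several same-day claims of one subtype are
one event-day, since claims carry no intra-day ordering) and clustering is
strictly within patient and subtype. Two anchorings are implemented
because published descriptions ("within 21 days of a previous SRE") do
not pin down whether the clock restarts at the episode's first or most
recent claim:

* `episode_start` (default): day $d$ joins the open episode iff
  $d - \text{anchor} \le L$; otherwise it opens and anchors a new episode.
* `rolling`: distance is measured from the most recent event-day, so
  chains can extend indefinitely.

Boundaries are inclusive ($d - a = L$ joins). Useful structural facts,
all enforced as tests: the rolling count never exceeds the episode-start
count; totals are non-increasing in $L$; $L = 0$ returns one episode per
event-day; $L$ at least the span returns one episode per stratum. A
deliberately naive reference implementation, `brute_force_cluster()`, is
exported and used only as a test oracle.

## Measures and rounding

`prevalence_table()` reports patients with ≥1 kept event per subtype, as
counts and percents of the cohort and of SRE patients;
`incidence_table()` reports episode totals, per-patient means (denominator
= patients with ≥1 episode of that subtype), medians, and the 1/2/3+
distribution; `episode_count_change()` and `pct_change()` report
$(b-a)/a \times 100$ with the reference explicit, since "an 8 % increase"
is ambiguous about direction — the package computes the base-case
prevalence relative to the alternative as reference. All reported figures
round **half-up, ties away from zero** at the printed precision (one
decimal for rates and means, integers for percent changes);
`base::round()` rounds half to even and does not reproduce published
tables. Published tables of this kind occasionally contain cells that do
not recompute from their own numerator and denominator under any rounding
rule; the package's contract is that *its* percents always recompute
exactly from its counts, and its tests assert recomputed values rather
than chasing discrepant cells.

Time-to-event summaries measure diagnosis → first episode anchor, first →
second anchor, and diagnosis → death, over patients for whom the pair is
defined; anchors (not raw claims) mark the first and second SRE, and the
even-count median is the mean of the two middle values.

## The synthetic generator

`simulate_claims()` emulates the structure the pipeline must survive, with
known ground truth: per-patient, per-subtype episodes arrive as renewal
processes (inter-start gap = `inter_episode_gap_days` + an exponential
excess at the nominal `episode_rates`); each episode emits 1–4 claims
over at most `intra_episode_span_days`; PF claims are miscoded to
fracture-chapter "other fracture" codes with `miscode_prob`; fracture
episodes acquire non-exempt trauma co-claims (`trauma_co_claim_prob`) and
exempt same-level-fall co-claims (`same_level_fall_prob`) inside the
14-day lookback. Defaults were chosen once to echo the study conditions:
diagnoses uniform over 2000–2009 with the 2010-12-31 censor active;
exponential survival with median ≈ 1.5 years (`annual_death_hazard =
0.45`); episode rates (PF 0.25, RAD 0.27, SCC 0.05, BS 0.05 per
patient-year) calibrated so per-subtype prevalence lands near the
magnitudes observed in elderly metastatic prostate cancer (roughly
25 % PF, 30 % RAD, 6 % SCC, 6 % BS, any-SRE a little under half the
cohort), with RAD and PF dominating; occasional HMO switches (5 %) and disenrollment (3 %)
so every censoring path is exercised.

Two properties make it an oracle rather than a fixture. First,
**well-separated recovery**: with span ≤ 7 and gaps ≥ 60 days no 21-day
window can merge two true episodes nor split one, so identification plus
clustering must reproduce the true episode table exactly, per patient —
asserted at 500 patients. Second, **direction of bias**: as gaps shrink
below the window, clustering merges adjacent true episodes and cumulative
incidence under-counts monotonically, mirroring the window-length
sensitivity the measures quantify on real data. The generator is
deterministic (per-patient substreams derived from one seed, so enlarging
the cohort never reshuffles existing patients).

What it does *not* emulate: real marginal distributions of age, race or
survival; coding-intensity differences across care settings; seasonal or
secular coding drift; genuinely ambiguous codes shared between subtypes.
Passing tests therefore demonstrate the *logic* is right under the stated
generative assumptions, not that the shipped code lists are clinically
valid — published validation work for claims-identified bone events
reports sensitivities well below 100 %, and the default codebook is an
approximation assembled from codes named in the methodological literature
(complete operational lists are typically relegated to unpublished
appendices). Users with an adjudicated list should load it with
`load_codebook()`.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make every
property decisive yet quick on one CPU: 1000 random day-sets × 2
anchorings × 5 window lengths for the clustering oracle; 500 patients for
exact ground-truth recovery; 120–150 patients for monotonicity and
definition-nesting checks. Dates are ISO-8601 calendar dates throughout
and all arithmetic is exact day differences — windows are specified in
days, so no month approximation is acceptable. Degenerate inputs are
defined, not errors: empty claim streams yield empty event tables, zero
denominators yield `NA` percents (flagged, not thrown), and `L = 0` is a
valid window.

## Known limitations

The default codebook is a documented approximation (see above); ICD-10 and
native Medicare file layouts (MEDPAR/NCH/Outpatient) are out of scope —
inputs are flat CSV tables; radiation claims cannot reveal the irradiated
site, so RAD remains the subtype most sensitive to list choice; and no
clinical validation of any list is attempted.
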