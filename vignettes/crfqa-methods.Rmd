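---
title: "Methods: edit checks, completion summaries and error trends in crfqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edit checks, completion summaries and error trends in crfqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfqa)
```

`crfqa` is the computational back end of a data-quality monitoring
workflow for multi-site longitudinal studies. This vignette explains the
models and procedures it implements, the parameters that matter, the
numerical conventions it fixes, and what the synthetic-data generator
does and does not emulate.

## The tidy-table contract

All computation runs over a tidy observation table: one record per
(subject, visit, form, field), each cell holding a single value. Flat
REDCap-style exports (one row per subject × event, one column per field)
are melted into this shape by `as_tidy_records()`/`load_records()`.
Ingest is deliberately conservative: values are kept as character data,
the empty string maps to a single missing sentinel, and any value that
fails its field's declared type (a non-number in a numeric field, a
malformed date or time, an out-of-dictionary category) is *kept verbatim*
and reported as a schema violation. Nothing is silently repaired or
dropped; conservation (records out + kept-but-nonconforming = cells in)
is tested property-style.

Form completion uses the REDCap convention: the per-form status variable
is coded 0 = incomplete, 1 = unverified, 2 = complete. Unverified is
treated as incomplete everywhere downstream, because an unverified form
has not yet passed human review. Dates are ISO-8601 and all date
arithmetic is in whole days; times are `HH:MM` within a day.

## The edit-check engine

Checks are declarative rules (`check_definition()`) evaluated per form
instance. Seven kinds cover the families seen in practice: missingness,
duplicate-entry pair mismatch (with a non-negative numeric tolerance,
default 0 — duplicate entries should agree exactly), conditional
missingness (a trigger value makes dependents required), chronology over
an ordered list of time/date fields, location mismatch between
performed-at and entered-for site designators, unspecified reason for an
uncompleted test, and numeric range.

Two design choices deserve justification:

* **Checks run only on completed instances** (status 2). A blank field on
  an incomplete form is evidence of incompleteness, not of a data-entry
  error; scoping checks this way keeps the completion quadrants
  (completed-without-errors vs completed-with-errors vs incomplete)
  mutually exclusive, and makes "completed with errors" mean exactly what
  it says.
* **`flag_date` is the entry timestamp of the flagged instance** (the
  latest entry date among implicated records). Report windows and monthly
  trend series need a date per flag; the entry date is when the erroneous
  data came into existence, which is the quantity a monitoring team wants
  to age.

`run_checks()` is a pure function of (records, registry): output order is
fixed (site, subject, visit order, check id), at most one flag is raised
per (subject, visit, check), and re-running produces byte-identical
tables. The default registry for the example schema encodes one exemplar
per rule family per CRF domain plus required-field missingness per form;
its checks reference pairwise-disjoint fields within each form, so a
single perturbation of the data trips exactly one check. That disjointness
is what lets the simulator's injection log serve as exact ground truth.

## Completion summaries

`classify_forms()` assigns each (subject, visit, form) cell exactly one of
five statuses; cells excluded by the form's applicability predicate (a
cohort- or visit-restricted form) are `not_collected_by_design` and leave
every denominator. The four-quadrant percentages are computed over
applicable instances and sum to 100 before rounding; percentages
everywhere are rounded to one decimal, half away from zero.

Subject-level *streaks* summarize the primary biomarker set — by default
imaging, QST, functional testing and blood collection; the set is a
configurable argument because no single definitive list exists — across
*due* visits. A visit is due when its nominal day offset has elapsed since
the subject's baseline date; forms at future visits never count against a
subject who is simply on schedule. All due primary forms complete and
flag-free gives a clean streak; all complete with at least one flagged
gives a streak with errors; anything incomplete or unknown gives an
incomplete streak. The three statuses partition evaluated subjects.

UpSet-style combination counts stratify subjects at two anchors: fewer
than 35 days post-baseline (pre-surgery surveys and immediate post-op
data should be complete) and more than 7 *calendar* months post-baseline
(end of the primary-endpoint window). Months are calendar months with
clamping to month end, since the anchor is stated in months, not days. A
form belongs to a subject's completed subset when every applicable due
instance of it is complete without errors and at least one such instance
exists; the exclusive subsets partition the stratum, and the per-form
marginals equal the subset sums — both identities are verified in the
tests against a brute-force enumeration of all 2^k subsets (k ≤ 6).

## Scores and outliers

Scores are declarative too (`score_definition()`): sum, mean or
single-field rules over item fields, applied only to complete instances,
with any missing item making the score missing — no imputation, because a
partially answered questionnaire total is not comparable to a complete
one. Quantiles use linear interpolation between order statistics
(`stats::quantile()` type 7), fixed and documented because quantile
conventions differ. Outliers are flagged by Tukey fences
(Q1 − 1.5·IQR, Q3 + 1.5·IQR) within visit × cohort groups of at least 4
scores: the standard convention matching box/violin displays. With fewer
than 4 scores a quartile estimate is too unstable to call anything an
outlier.

## Report windows and instrument breakdowns

Error reports are filed per center × cohort stratum, CRF domain, and age
window: recent [0, 90) days, mid [90, 180] days, archive (180, ∞). The
boundary convention — both printed endpoints 90 and 180 inside the middle
window, 90 removed from "recent" — is a choice we state rather than
infer: the windows must be disjoint and exhaustive, and the behaviour at
exactly 90 and 180 days is otherwise ambiguous. Spreadsheet export is
written as SpreadsheetML 2003 XML, a plain-text format that Excel and
LibreOffice open natively; the printable format is standalone HTML. Both
carry exactly the CSV's rows and columns, which the tests verify by
re-parsing.

PRO error breakdowns carry the delivery instrument (REDCap for MCC1
sites, MyDataHelps for MCC2 sites); `instrument_breakdown()` tabulates
error-type percentages per form and site, and
`instrument_missingness_rate()` gives the per-instance missingness rate
per instrument. The package only tabulates — whether a rate difference is
meaningful is the analyst's question.

## Error-trend models

`monthly_counts()` buckets flags into calendar months per domain,
zero-filling interior months so each series is contiguous. Two change
measures are reported:

* **Observed percent change**: `100 (n_last − n_first) / n_first` between
  the first and last observed monthly counts. Undefined when the first
  count is zero (reported as `NA`, never as infinity). In the summary
  table, the `Total` row sums the per-domain first and last counts —
  domains may start and end in different months, so the total is a sum of
  endpoints rather than a single calendar month's count.
* **Model-estimated percent change**: a count regression of monthly
  counts on a linear month index with a log link — Poisson by default,
  switching to a negative-binomial when the Pearson dispersion statistic
  exceeds 2, the standard remedy for overdispersed counts. With slope β
  (log count per month) and a span of Δt months, the change is
  `100 (exp(β·Δt) − 1)`. A series lying on an exact exponential satisfies
  the Poisson likelihood equations exactly, so such series are recovered
  to numerical precision — this closed-form case anchors the tests. The
  pooled model adds domain-level intercepts with a shared slope
  (`count ~ domain + month`), quantifying an overall trend while allowing
  domains different error levels.

Model-estimated changes are smoother and usually more conservative than
the observed endpoint ratio, because they use every month rather than
two. The package makes no causal claim about *why* a series declines.

## The synthetic-study generator

`simulate_study()` defines the study conditions under which everything is
tested. Defaults: two centers × two sites each, enrollment of 4 subjects
per site per month over 14 months, observation window 2024-03-01 to
2025-09-01 (18 months, matching the span of the trend analyses), a
60/40 TKA/thoracic cohort mix, visit schedule baseline/post-op
(day 14)/3-month/6-month, and the six-form example schema (four CRF
domains, two PROs). Forms are left incomplete with probability 0.08,
status-blank with probability 0.03; these emulate realistic levels of
lagging data entry without dominating the quadrants. Tests use scaled-down
studies (2 subjects/site/month over 6 months, tens of subjects) so the
whole suite runs in well under a minute; the identities being tested are
size-invariant.

Generation is two-phase. Clean data first: values typed and in range,
duplicate pairs agreeing, chronologies ordered, locations matching,
reasons present where required. Then per-check injection: a completed
instance entered in study month *m* receives a violation of check *c*
with probability `p_c (1 − r)^m`, each perturbation constructed to trip
exactly its check. Injections that would touch a field already perturbed
by an earlier check on the same instance are skipped (not logged), so the
log remains *exactly* the set of violations present in the data — the
soundness/completeness tests compare the two set-wise across seeds.
Randomness is split into one stream per concern (enrollment, values,
injection), each seeded from the master seed, so extending one concern
cannot shift another's draws; identical configurations produce
byte-identical files.

What the generator does **not** emulate: clinical correlation between
instruments (scores are independent draws), dropout beyond the
incompleteness probabilities, inter-site heterogeneity in error rates,
and entry-date backlogs. Passing tests therefore demonstrate the
*correctness of the computations* — classification identities, check
soundness against ground truth, trend-parameter recovery — not that real
study data will show any particular error structure.

The built-in `replay_fixture("table2")` is a deterministic flag set whose
per-domain monthly series start and end at fixed anchor months and counts
(summing to 40 initial and 6 final errors across four CRF domains), with
geometric interpolation in between. It pins the observed-percent-change
surface to exactly reproducible numbers: −66.7% (blood collection),
+100.0% (functional testing, 1 → 2 errors), −93.8% (imaging), −94.1%
(QST), −85.0% in total.

## Degenerate inputs and tie-breaks

* Empty selections yield defined empty results (quadrants with n = 0 and
  `NA` percentages, empty reports with headers), never division errors.
* All-zero count series refuse a trend fit with a clear message; series
  shorter than 3 months are rejected.
* Equal scores give IQR 0; values on the fence are not outliers (strict
  inequality).
* Chronology requires at least two present times; single-time instances
  are not evaluable and defer to missingness checks.
* A future `flag_date` relative to the as-of date is an error, not a
  silently empty window.

## Problem sizes

The test suite simulates studies of 24–504 subjects; the Monte-Carlo
trend-recovery check uses 200 replicates of 12-month Poisson series with
a true 10% monthly decay and requires the mean recovered monthly change
to lie within ±2 percentage points of the truth. These sizes were chosen
once as the smallest at which the binomial/Poisson tolerances are tight
enough to be informative.
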