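---
title: "Validating prescription-pattern proxies for ACE-inhibitor adverse drug reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating prescription-pattern proxies for ACE-inhibitor adverse drug reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrproxy)
```

## The problem

Adverse drug reactions (ADRs) to ACE inhibitors (ACEIs) — chiefly dry
cough, rarely angioedema — are the main reason patients stop or switch the
drug, yet dispensing databases carry no ADR field. If a change in the
prescription pattern (switching to an angiotensin receptor blocker, ARB;
switching to another antihypertensive; stopping outright) can be shown to
predict a chart-documented ADR, the pattern becomes a usable proxy outcome
for pharmacovigilance and for large-scale risk-factor studies that only
have dispensing data.

`adrproxy` implements that validation end to end: treatment-episode
construction from dispensing lines, mutually exclusive pattern
classification, adjudication of coded primary-care events around the
switch/stop date, and the accuracy arithmetic (PPV, NPV, sensitivity,
specificity with two-sided confidence intervals). Because the original
patient-level records are protected, the package also ships a synthetic
cohort generator with latent ground truth, plus the published aggregate
contingency table (`table2_fixture()`) for exact "counts-mode"
reproduction of the published accuracy estimates.

## Episodes and prescription patterns

Each dispensing covers `max(1, round(units_dispensed / daily_number))`
days from its dispense date (rounding is half-up; the data never say how
fractional days were handled, so we fixed a deterministic rule). The
*theoretical end date* is the first uncovered day. Starting from a
patient's first ACEI dispensing, each later ACEI dispensing is chained into
the treatment episode when it falls no more than `gap_days` after the
running theoretical end of supply; the episode end is the running *maximum*
of chained end dates, so stockpiled overlapping supplies are not appended
end-to-end. Dutch pharmacies dispense at most 90 days at a time, which
motivates the default `gap_days = 90`; 180 days is the standard
sensitivity setting, and both are analysed by default.

Cohort entry follows a new-user design: the first-ever ACEI dispensing must
fall inside the study window (2000-01-01 to 2011-01-01) and be preceded by
at least 182 days of covered, ACEI-free history.

Classification is exhaustive and mutually exclusive:

* **Continuation** — follow-up ends no more than `gap_days` after the
  episode end; subdivided by the reason follow-up ended (end of study,
  moved out, death). We read the subdivision as the *exit reason of
  continuers*: a patient whose supply lapsed more than `gap_days` before
  death is classified by the discontinuation logic, not as a continuing
  decedent.
* **Switch / stop** — otherwise the episode end is the *index date*, and
  the window `(index, index + switch_window_days]` is scanned: any ARB
  dispensing wins (ARB priority keeps the groups mutually exclusive and
  reflects the guideline that ADRs prompt an ACEI-to-ARB swap); otherwise
  any beta blocker, calcium channel blocker, diuretic or other
  antihypertensive makes a switcher-to-other; otherwise the patient
  stopped. Dispensings on or after the exit date never count.

By default `switch_window_days` equals `gap_days`, so the 180-day
sensitivity analysis widens the whole definition coherently; the window can
be pinned (e.g. to 90 days) through `pipeline_config()` when only the
renewal gap should move. The data description we worked from does not say
which of the two the original analysis used; tying them is the
self-consistent reading and is therefore the default.

Months are fixed day counts throughout (3 months = 90 days, 6 months =
180) for determinism; calendar-month arithmetic would make results depend
on the calendar position of each index date.

## Adjudication of coded events

Medical-record review is represented by *coded* events
(`DEFINITE_ADR`, `DEFINITE_NON_ADR`, `PROBABLE_ADR`, `NON_PROBABLE_HP`),
mirroring a manual chart review already reduced to categories; free-text
interpretation is out of scope. For a test-positive patient the closed
window from 180 days before to 90 days after the index date is scanned.
When several events fall inside, the patient-level class is the
highest-precedence code:

`DEFINITE_ADR > DEFINITE_NON_ADR > PROBABLE_ADR > NON_PROBABLE_HP`,

with `NOTHING_MENTIONED` when the window is empty. The precedence order is
our tie-break (the categories are mutually exclusive but no tie rule was
stated): a confirmed ADR should dominate everything, and a physician's
explicit non-ADR reason should dominate speculative mentions. Permuting a
patient's events can therefore never change the class, which is tested as a
property.

Continuers have no index date. For the matched sensitivity/specificity
design a continuer is reviewed from ACEI start for exactly the matched
case's treatment duration (`adjudicate_control()`); for the full NPV
tabulation continuers are reviewed over their entire episode, from start to
`min(episode end, exit)` — a choice we had to make, since no review window
for unmatched continuers was stated.

Ascertainment levels nest: *definite*; *at least probable* adds probable
ADRs; *at least possible* additionally counts patients with nothing
mentioned, because silent records leave an ADR possible. Definite non-ADRs
and non-probable health problems belong to no level; that exclusion is
forced by the arithmetic that reproduces the published at-least-possible
PPVs from the published counts.

## Accuracy metrics

PPV is the share of a test-positive group whose class falls in the level;
the cough-specific PPV restricts the numerator to definite ADRs whose
recorded term is cough. NPV deducts definite (and, at the at-least-probable
level, probable) ADR mentions from a continuation subgroup; a
definite-only NPV is undefined by construction. Confidence intervals
default to the Wilson score interval, which reproduces the published
intervals digit for digit (e.g. 101/180 gives 48.8-63.2%); Clopper-Pearson
and Wald are available behind `ci_method` for sensitivity analyses. Report
CSVs round percentages half-up to one decimal; internal objects keep full
precision.

Sensitivity and specificity use definite ADRs only. Each test-positive
case is matched to an unused continuer whose ACEI duration is at least the
case's, drawn uniformly at random with a seed; cases are processed in
descending duration order so the longest cases face the pool before it
thins. Neither the processing order nor the sampling rule was stated in
the design we follow; greedy descending matching with seeded uniform draws
is deterministic, reproducible, and leaves the fewest long cases
unmatched. Unmatched cases are reported, not dropped silently from the
bookkeeping.

## The synthetic cohort generator

`generate_cohort()` draws, per patient: an ACEI start uniform over the
study window with entry far enough back to satisfy the lookback; a refill
chain from a 30/90-day supply mixture with 0-10-day refill delays;
exponential censoring by death and moving; a latent ADR
(probability `p_adr`, exponential onset) whose action is switch-to-ARB,
switch-to-other, stop, or tolerate-and-continue; non-ADR discontinuation
(no need, not effective) with its own switch/stop split; one long refill
interruption (uniform 91-270 days) for a fraction of committed continuers,
so the 90- and 180-day settings genuinely disagree on part of the cohort;
and a recording model — an ADR that ended treatment is documented as
definite with one probability, with probable phrasing otherwise, or not at
all, tolerated ADRs are documented more rarely, non-ADR reasons leave a
definite non-ADR note with their own probability, and a background Poisson
process scatters probable-looking (bronchitis-type) and clearly unrelated
events over the whole follow-up.

Default parameter values were chosen once so that a default cohort roughly
matches the published marginal frequencies at the 180-day gap (about 16%
ARB switchers, a quarter stoppers, half continuers, ARB-switch definite
PPV near 56%, continuation definite fraction near 5%) and were not
revisited afterwards. The generator's purpose is statistical structure,
not pharmacological realism: doses, titration, comorbidity, seasonality
and multi-drug episodes are deliberately absent, so passing tests say the
*pipeline arithmetic* is right under the assumed structure — not that the
structure captures any particular real population.

Two modelling simplifications keep the generator's branch structure
enumerable: a patient who tolerates an ADR is a committed continuer (no
later non-ADR discontinuation), and spurious interruptions happen only to
plain continuers. Both are documented assumptions, not claims about
practice.

## Closed-form expected values and their validity

`expected_ppv()` enumerates the discrete branches — (ADR x action),
non-ADR discontinuation x action, spurious interruption — times the
recording probabilities and the background-event probability over the
271-day adjudication window, and returns the conditional level probability
within a classified group. It is exact when censoring is absent. With
censoring, every discontinuation branch is thinned by the probability that
the index date precedes exit; the defaults give ADR and non-ADR
discontinuation the *same* exponential latency mean, so the thinning
cancels in the within-group mixture and the closed form stays accurate.
The parameter-recovery tests check empirical PPVs on cohorts of 20,000
patients against these values within three binomial standard errors, both
censor-free and under the default censoring.

`expected_npv()` exists only at the at-least-possible level: background
events never generate a definite ADR, so the definite fraction among
continuers is a single branch product. At the at-least-probable level the
background probability depends on each patient's episode length and has no
closed form; it is checked empirically instead. Near the end of the study
window a small edge effect exists (a discontinuation whose index falls
within one gap of the study end is classified as continuation), which the
enumeration ignores; it is far below the test tolerance at the sizes used.

## Numerical and degenerate-input choices

* Supply duration: half-up rounding, minimum one covered day.
* All windows are closed at both endpoints; the switch scan is open at the
  index date itself (the index is the first uncovered day).
* Empty dispensing input is an error for episode construction but a
  graceful "no starters" result for the pipeline.
* Zero denominators raise errors rather than returning NaN estimates.
* A zero-duration matched window still catches events on the start day.
* Matching, generation and the pipeline take explicit integer seeds;
  global RNG state is saved and restored around every internal draw.

## Problem sizes used by the test suite

The suite cross-checks the episode classifier against a brute-force
day-by-day coverage oracle on 1,000 randomised patients at two gap
settings, runs parameter recovery on cohorts of 20,000, and exercises the
remaining properties on cohorts of a few hundred to a few thousand. These
sizes give comfortable statistical resolution (binomial standard errors
under one percentage point on the main groups) while keeping the default
test run fast.

## Limitations

* The adjudication input is already coded; the hard problem of reading GP
  notes is upstream of this package.
* The generator does not model dose changes, partial adherence, concurrent
  antihypertensive co-medication outside the switch scan, or calendar
  trends in prescribing.
* Counts-mode reproduction validates the accuracy arithmetic against the
  published aggregate table; data-dependent published quantities (cohort
  size, matched-set sensitivity, reclassification counts) are not
  reproducible without the original records and are checked only as
  internal-consistency properties on synthetic data.
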