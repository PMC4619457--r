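# adrproxy

Validation of prescription-pattern proxies for ACE-inhibitor (ACEI)
adverse drug reactions (ADRs) in dispensing databases.

Dispensing records carry no ADR information, but the way a patient's ACEI
therapy evolves does: guidelines replace an ACEI with an angiotensin
receptor blocker (ARB) when an ADR (typically dry cough, rarely
angioedema) occurs. `adrproxy` builds ACEI treatment episodes from pharmacy
dispensing lines, classifies new users into six mutually exclusive
prescription patterns, adjudicates coded primary-care events around the
switch/stop date, and quantifies how well each pattern predicts a
chart-documented ADR.

For a test-positive group (switchers, stoppers) with `n` members of whom
`x` fall in an ascertainment level (definite; at-least-probable;
at-least-possible), the positive predictive value is `x/n` with a
two-sided Wilson score interval

```
(p̂ + z²/2n ± z √(p̂(1−p̂)/n + z²/4n²)) / (1 + z²/n),  z = Φ⁻¹((1+γ)/2)
```

Negative predictive values deduct recorded definite (and probable) ADR
mentions from the continuation subgroups. Sensitivity and specificity are
computed on definite ADRs over duration-matched case/control pairs: each
test-positive case is matched to an unused continuer whose ACEI duration is
at least the case's, and the control's records are reviewed from ACEI start
for exactly the case's treatment duration.

The pipeline stages:

1. **Episodes** — a dispensing covers `max(1, round(units/daily_number))`
   days; dispensings chain into an episode while each renewal falls within
   `gap_days` (90 and 180 by default) of the running theoretical end of
   supply.
2. **Patterns** — continuation (subdivided by end of study / moved out /
   death) versus stop, switch-to-ARB, switch-to-other, decided by scanning
   the window after the index date (the episode's theoretical end).
3. **Adjudication** — coded GP events in the closed window from 180 days
   before to 90 days after the index date, with precedence
   `DEFINITE_ADR > DEFINITE_NON_ADR > PROBABLE_ADR > NON_PROBABLE_HP`.
4. **Metrics** — PPV/NPV per group and level (plus a cough-restricted
   PPV), matched sensitivity/specificity, Wilson/Clopper-Pearson/Wald
   intervals.

Because the original patient-level cohort is protected, the package ships
a synthetic longitudinal cohort generator (`generate_cohort()`) with latent
ADR ground truth and closed-form expected predictive values
(`expected_ppv()`), and the published six-month contingency table
(`table2_fixture()`) so every published accuracy estimate can be
recomputed exactly from aggregate counts.

## Worked example

Counts mode — recompute the published six-month estimates from the
published contingency table:

```r
library(adrproxy)
cts <- table2_fixture()
ppv(cts, "SWITCH_ARB", "DEFINITE")
#> PPV SWITCH_ARB DEFINITE: 101/180 = 56.1% (95% CI 48.8-63.2, wilson)
ppv(cts, "SWITCH_ARB", "AT_LEAST_POSSIBLE")
#> PPV SWITCH_ARB AT_LEAST_POSSIBLE: 163/180 = 90.6% (95% CI 85.4-94.0, wilson)
npv(cts, "CONTINUATION_TOTAL", "AT_LEAST_POSSIBLE")
#> NPV CONTINUATION_TOTAL AT_LEAST_POSSIBLE: 557/585 = 95.2% (95% CI 93.2-96.7, wilson)
```

So 56.1% of patients who switched from an ACEI to an ARB had a definite
chart-documented ADR, rising to 90.6% once probable and possible cases are
included, while 95.2% of continuers had no definite ADR mention —
switching to an ARB is the strongest dispensing-data marker of an
ACEI-induced ADR.

Patient-level mode on a synthetic cohort:

```r
co  <- generate_cohort(cohort_params(), seed = 1132)   # 1,132 starters
pat <- classify_patterns(co$dispensing, co$followup, gap_days = 180)
adj <- adjudicate_cohort(pat, co$gp_events)
tab <- tabulate_validation(pat, adj)
ppv(tab, "SWITCH_ARB", "DEFINITE")
#> PPV SWITCH_ARB DEFINITE: 75/132 = 56.8% (95% CI 48.3-65.0, wilson)
```

The numbered scripts under `analysis/` run the same workflow as a narrated
sequence — `01_simulate_cohort.R` (writes the synthetic cohort CSVs),
`02_run_validation_pipeline.R` (classification at both gaps, adjudication,
all metrics, reclassification report), `03_reproduce_published_tables.R`
(counts mode), `04_parameter_recovery.R` (empirical versus closed-form
PPVs at n = 20,000) — and write their tables under `results/`.

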