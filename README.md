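# triagetree

Authoring, validation and deterministic execution of Boolean decision-tree
clinical algorithms — the computational core of an electronic clinical
decision support algorithm (CDSA) stack for pediatric primary care.

Guideline content of the IMCI family is increasingly digitalized: a staged
consultation (danger signs → complaints → signs and measurements →
point-of-care tests) feeds Boolean classification rules that propose
diagnoses severity-first, trigger referrals, and compute weight-banded drug
doses. The content is written by clinicians, revised per country and
version, and must be verifiable by automated tooling. `triagetree` is for
the people who build and QA such content: it provides

- **algorithm model** — a schema-versioned document format (YAML for
  authoring, canonical JSON for exchange) with full structural validation
  (reference resolution, acyclic display-condition dependencies, numeric
  threshold intervals that exactly partition their admissible range,
  severity/referral invariants), exact serialization round trips, and
  deterministic terminology-code assignment;
- **engine** — a deterministic, functional consultation executor: staged
  questioning under three-valued (Kleene) logic, an always-available
  emergency interrupt, severity-first diagnosis proposal with minimal
  explanation traces, accept/refuse review with an audit trail, and
  treatment proposal with stockout alternatives;
- **dosing** — practical dispensable doses from per-kg rules
  (closest-to-target within tolerated bounds, never exceeding the absolute
  maximum) and whole-table verification across the weight × age grid;
- **bayes design** — the likelihood-ratio algebra used to design test
  cutoffs: post-test probability, required LR, ROC-grid cutoff selection
  (including the comorbidity rule), and empirical branch
  sensitivity/specificity with Wilson intervals;
- **casegen** — a packaged demo algorithm and a seeded generator of
  labelled synthetic patient cases, plus single-defect injection;
- **qa** — static lint (with exhaustive diagnosis-reachability checking),
  batch corpus replay, expectation-based unit checks, and automated
  non-regression diffing between content versions.

The core design mathematics, in standard notation: with pre-test odds
`o = p/(1-p)` and a test of sensitivity *Se* and specificity *Sp*,

    LR+ = Se / (1 - Sp),   post-test odds = o · LR,
    post-test probability = o·LR / (1 + o·LR)

so the LR required to reach a target post-test probability is the ratio of
target odds to pre-test odds — strictly decreasing in prevalence. That is
why a low-prevalence indication needs a high-specificity branch, and why a
comorbid child (higher pre-test probability) can use a lower, more
sensitive CRP cutoff for the same post-test probability:

```r
required_lr(0.05, 0.5)   # 19   (5% prevalence needs LR+ = 19 for 50%)
required_lr(0.20, 0.5)   # 4
post_test_probability(0.1, 9)   # 0.5
```

## Worked example

A 2-year-old (10 kg) with fever and cough, fast breathing (46/min,
estimated rather than counted), CRP 52 mg/L, no danger signs, amoxicillin
stocked out:

```r
library(triagetree)
alg <- build_fixture_algorithm()
st <- start_consultation(alg, list(age_days = 730, weight_kg = 10))
st <- record_answer(st, "comorbidity", FALSE)
for (n in danger_sign_nodes(alg)) st <- record_answer(st, n, FALSE)
st <- record_answer(st, "fever", TRUE)
st <- record_answer(st, "cough", TRUE)
st <- record_answer(st, "chest_indrawing", FALSE)
st <- record_answer(st, "muac", 13.8)
st <- record_answer(st, "spo2", 96)
st <- record_answer(st, "resp_rate", 46, estimated = TRUE)
st <- record_answer(st, "crp", 52)
st <- propose_diagnoses(st)
st <- propose_treatments(st, stockout = "amoxicillin")
```

This prints (via the loop in `?propose_diagnoses` / `?propose_treatments`):

```
pneumonia            moderate  cough=present & age_band=age_1_5y & resp_rate=rr_high
bacterial_fever      moderate  fever=present & crp=crp_high
cotrimoxazole for pneumonia: 2 tablet(s) = 240 mg (24.0 mg/kg) [substituted for amoxicillin]
referral: FALSE | warnings: 1
```

Reading it: both moderate branches fire — fast breathing is age-banded
(46/min is "fast" at 1–5 years), and CRP 52 clears the standard 40 mg/L
cutoff — each with the minimal answer set that explains it. The shared
first-line drug is dispensed once; with amoxicillin stocked out the listed
alternative is dosed instead (2 × 120 mg tablets = 24 mg/kg, inside the
tolerated 15–36 mg/kg) and flagged. No referral-carrying diagnosis was
proposed, and the estimated respiratory rate left a sub-optimal-measurement
warning that stays in the final record.

The same machinery powers the QA surface:

```r
lint_algorithm(alg)                                  # 0 findings on the demo
lint_algorithm(corrupt_algorithm(alg, "band_gap"))   # exactly one class
non_regression(alg, build_fixture_algorithm(crp_cutoffs = c(10, 60),
                                            version_id = "demo-1.1.0"),
               generate_cases(n = 500, seed = 1))
```

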