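---
title: "Methods: representing, executing and verifying clinical decision-tree algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representing, executing and verifying clinical decision-tree algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagetree)
```

# The problem

Electronic clinical decision support algorithms (CDSAs) for pediatric
primary care encode IMCI-style guidance as Boolean decision trees: a staged
consultation collects complaints, signs, measurements and point-of-care
tests, and classification rules over those answers propose diagnoses,
referrals and weight-banded treatments. Such content is authored by
clinicians, revised frequently per country and version, and executed on
devices at the point of care — so the representation must be both
human-auditable and machine-executable, and the content must be verifiable
by automated tooling rather than by manual review alone.

`triagetree` implements that stack: a validated document model, a
deterministic consultation engine, dosing computation and table-wide
verification, the likelihood-ratio algebra used to design test cutoffs, a
synthetic content/case generator, and a QA harness (lint, corpus replay,
expectation checks, non-regression diffs).

# The content model

An algorithm is a set of registries — nodes (questions), diagnoses,
managements, drugs, dosing rules — plus ordered stages and metadata.
Conditions are Boolean expression trees over atoms `(node, answer)` with
`AND`, `OR`, `NOT` and `AT_LEAST(k, atoms)`. `AT_LEAST` exists because
composite clinical-impression items ("any danger sign", "2 of 4 signs of
respiratory distress") are idiomatic in this content and clumsy to expand
into plain `AND`/`OR`.

Numeric questions carry a unit, an admissible range and threshold-interval
answers under a **half-open `[lo, hi)` convention**: clinical thresholds
are printed as strict upper cutoffs ("MUAC < 12.5 cm", "SpO2 < 90%"), so a
value exactly on a threshold belongs to the upper category. Validation
requires the intervals to be pairwise disjoint and to cover the admissible
range exactly.

Units are fixed: ages in **days** (months are ambiguous in length and the
population spans young infants to teenagers), weights in kg, temperatures
in °C. Terminology codes for nodes and diagnoses are auto-assigned when
absent, as a 32-bit FNV-1a hash of `id@version`: stable, deterministic, and
namespaced per content version. Mapping to external code systems (ICD etc.)
is out of scope.

Two serialization dialects render one canonical document: YAML for
authoring, JSON for exchange. The canonical form has fixed key order and
explicit optional fields, so equal algorithms serialize byte-identically
and `from_document(serialize(...))` is an exact round trip. Validation
reports **every** violated invariant at once — content authors need the
full defect list, not a fail-fast first error.

# Consultation semantics

Answers accumulate monotonically; the engine is purely functional (every
operation returns an updated state), which makes replay and diffing
trivial.

**Three-valued logic.** Unanswered atoms are *unknown*; unknowns propagate
through the connectives by Kleene semantics (`AT_LEAST` is true once `k`
atoms are definitely true, false once too few can ever be true, unknown
otherwise). A node is askable only when its display condition is
*definitely* true — a condition still unknown keeps its question hidden
rather than prematurely pruning or prematurely asking.

**Gating at diagnosis time.** Once all stages are exhausted, a node whose
display condition resolved false was legitimately never asked; its atoms
count as **false**, not unknown, in diagnosis conditions. This mirrors tree
semantics where a skipped branch cannot contribute. Any remaining genuinely
unresolved atom is an error naming the nodes, never a silent guess.

**Question order** is stage order, then topological order of the
display-condition dependency graph (which validation requires to be
acyclic), then authoring order. The ordering is a presentation choice; a
package invariant (checked exhaustively in the tests) is that recording
order never changes any clinical output.

**Severity first.** Proposals are ordered emergency > severe > moderate >
mild, ties by authoring order. Each severe/emergency diagnosis must carry a
referral management. Exclusion lists implement the severity-first
architecture: in the demo content every emergency/severe diagnosis
suppresses the non-severe specific-treatment branches, so antimicrobial
logic only applies once severe disease is ruled out. Exclusions are applied
in priority order: a diagnosis already suppressed cannot suppress others.

**Explanations.** Every proposal carries the minimal set of answers that
made its condition true (for `OR`, the first true disjunct; for
`AT_LEAST(k)`, the first `k` true atoms; for a negation, the actual answer
that falsifies the negated atom; for a gated-off node, an explicit "branch
not taken" entry). Replaying only the trace against the condition yields
true — a tested invariant.

**Clinician autonomy with an audit trail.** Proposed diagnoses may be
accepted or refused; unreviewed ones default to accepted at treatment time
(the tool proposes — inaction must not silently drop care). Refusing a
referral-carrying diagnosis removes its treatments but *keeps a prominent
warning in the export*: the engine respects the decision and preserves the
trail. Estimated (rather than measured) values enter the logic identically
and are only flagged with a sub-optimal warning, because estimation exists
to keep consultations moving, not to change semantics. The emergency
interrupt returns guidance at any moment and is side-effect-free on all
clinical outputs (also a tested invariant).

# Dosing

A dosing rule applies over a half-open age × weight band and specifies a
target dose (mg/kg/dose), a tolerated interval `[min, max]`, an absolute
per-dose ceiling, frequency and duration. `compute_dose` picks the multiple
of the formulation's smallest dispensable increment (half tablets; whole or
half ml) whose achieved mg/kg is **closest to the target among in-bounds
candidates**, capped at the absolute maximum, ties resolved toward the
lower quantity. This objective is a design choice: it minimizes dosing
error and never silently exceeds a bound — if no dispensable quantity is in
bounds, that is an error (and a lint finding), not a rounded-up dose.

`verify_posology` automates whole-table verification: for every
(drug, indication, formulation) and every grid point it checks that exactly
one band applies and that an in-bounds dose exists. The default grid is
2.0–25.0 kg in 0.1 kg steps and ages in 30-day steps: achieved-dose curves
are piecewise in weight with sparse switch points, so 0.1 kg bounds the
miss risk cheaply; finer grids are a flag away. The implementation
vectorizes over the weight × candidate-quantity matrix per rule, and tests
pin it to an independent brute-force minimizer over all dispensable
quantities.

# Branch-design mathematics

The design questions are (1) *does the child need referral?* — a
sensitivity problem on severe disease — and (2) *does the child need a
specific treatment?* — where the pre-test probability (prevalence) of e.g.
bacterial disease governs how specific a branch must be. The package
implements the standard odds form of Bayes' theorem:

  post-test odds = pre-test odds × LR,  LR⁺ = sens / (1 − spec)

`required_lr(pretest, target)` is the exact inverse and is strictly
decreasing in prevalence: a low-prevalence condition needs a much higher
likelihood ratio for the same post-test probability (e.g. 19 at 5%
prevalence vs 4 at 20% for a 50% target). `choose_cutoff` scans an ROC grid
for the lowest cutoff reaching the target post-test probability; because
post-test probability rises with pre-test probability, the chosen cutoff is
non-increasing in prevalence — the comorbidity rule: a child with
comorbidities has a higher pre-test probability of needing antibiotics, so
a lower, more sensitive CRP cutoff reaches the same post-test probability.
With an unreachable target the best achievable cutoff is returned and
flagged rather than failing.

`branch_performance` measures a branch empirically: labelled cases are
replayed through the engine and the 2×2 table of "diagnosis proposed"
(pre-review — the algorithm is measured, not the clinician) against gold
labels yields sensitivity, specificity and LRs with 95% Wilson score
intervals. A zero cell makes an LR undefined and it is reported as `NA`,
never fabricated.

# The demo content and case generator

No real country content ships with the package; `build_fixture_algorithm()`
is invented demo content, except the two canonical screening thresholds it
deliberately reuses (MUAC 12.5 cm, SpO2 90%). It exercises every feature:
four danger signs, an `AT_LEAST(2 of 3)` clinical-impression item, a
CRP-like test with a standard (40 mg/L) and a lowered comorbidity
(10 mg/L) cutoff gated on fever, age-banded fast-breathing thresholds
realized through an auto-answered age-band background node, three
first-line drugs with alternatives and weight-band dosing tables, and a
supportive-care catch-all. The fixture is deliberately small: its full
assignment space (8 boolean nodes and 4 interval-answer nodes, 49,152
complete assignments) fits under 2^16, so the severity-first property and
diagnosis reachability are checked **exhaustively**, not sampled.

`generate_cases` draws labelled synthetic patients from six condition
profiles (well child 50%, viral URTI 25%, pneumonia-like 10%, malnutrition
7%, severe febrile illness 5%, hypoxaemic illness 3%) — prevalences skewed
toward non-severe presentations, matching an outpatient population where
few non-severe children need antibiotics. Booleans are Bernoulli; MUAC and
SpO2 are truncated normals; CRP is truncated log-normal; respiratory rate
is normal with age-band-shifted means. Draws are truncated to each node's
admissible range by inverse-CDF sampling, rounded to one decimal and
clamped off the excluded upper bound; ages are uniform over 2 months–5
years with a simple linear growth model for weight. Generator fidelity is
checked against closed-form post-truncation means (`expected_numeric_means`),
not against the untruncated parameters.

What the generator does *not* emulate: real epidemiology (the prevalences
are round demo values), correlated measurement error, missingness beyond
the estimated-value flag, or clinician behavior. Passing tests therefore
certify the *machinery* — determinism, order-invariance, severity-first
logic, dosing optimality, QA sensitivity — on realistic-shaped data, not
clinical performance of any real content.

`corrupt_algorithm` injects exactly one defect of a named class (cycle,
dangling reference, interval gap/overlap, unreachable diagnosis,
out-of-bounds dose, dosing band gap); each corrupted variant must trigger
exactly its finding class and the clean fixture none, which is how the QA
harness's sensitivity and false-positive rate are both pinned.

# QA harness

`lint_algorithm` aggregates structural validation, diagnosis reachability
and the posology sweep into one deterministic finding list. Reachability is
decided exactly by enumerating all answer assignments (with display gating
applied topologically) whenever the assignment space is at most 2^20 rows;
beyond that a per-atom heuristic runs and an explicit warning finding says
so — exactness where affordable, honesty elsewhere.

`non_regression` replays one corpus through two content versions and diffs
per case the items asked, proposed diagnoses, treatments and referral flag
— separably, since content review cares about different deltas (a
threshold change must never touch question flow or referral status; adding
a mild diagnosis must never touch referral flags). The tests verify exact
localization: raising the demo CRP cutoff from 40 to 60 mg/L changes
exactly the febrile, non-comorbid, non-severe cases with CRP in [40, 60) —
a predicted set recomputed directly from raw case inputs.

# Numerical and design choices

- Probabilities for odds algebra must be strictly inside (0, 1); domain
  violations are errors, not clamps.
- Dose tie-breaks go to the lower quantity; band membership is half-open,
  so a patient exactly on a boundary takes the upper band.
- The enumeration bound (2^20) and the verification grid (0.1 kg / 30
  days) trade exactness against runtime; both are arguments, not constants.
- Serialization normalizes all numerics to doubles so round trips are
  exact `identical()` matches; YAML is parsed with answer ids kept as
  strings (`present`/`absent` rather than YAML-boolean-prone `yes`/`no`).
- Problem sizes in the packaged checks — 49,152-assignment sweeps, 1,000
  cases × 5 answer-order permutations, 100,000-draw Bernoulli simulations
  per Bayes triple, 10,000-case generator-fidelity runs — were chosen as
  the smallest sizes at which the properties are sharp (3 standard errors,
  99% exact-binomial intervals).

# Known limitations

- Conditions cannot reference demographics directly; age-dependent logic
  goes through auto-answered background nodes.
- Unanswered-but-askable nodes block diagnosis with an error; there is no
  partial-information proposal mode.
- Re-answering a question updates its value but never deletes answers that
  later become gated-off (they simply stop contributing if their node is
  gated); a full dependency-driven retraction model is out of scope.
- The dosing model is per-dose with frequency metadata, without
  pharmacokinetics, renal/hepatic adjustment or interaction checking.
- `choose_cutoff` consumes a given ROC grid; fitting ROC curves from raw
  marker data is out of scope.
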