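---
title: "Grading bodies of prognostic evidence: the model behind prognograde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading bodies of prognostic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognograde)
options(prognograde.log_level = "error")
```

## Why a separate framework for prognosis

Evidence about prognostic factors — characteristics associated with the
course of an existing condition — comes almost exclusively from
observational cohorts. Study design therefore cannot discriminate quality
the way it does in intervention research; what matters instead is the
*phase of investigation* (is the study hunting for associations, confirming
an independent association, or testing an explanatory model?), the internal
validity of each cohort, and a set of cross-study judgments: consistency,
directness, precision, publication bias, effect magnitude, and
exposure-response behaviour. `prognograde` encodes one defensible
operationalization of each judgment as a deterministic rule with a recorded
rationale, so a review team can see — and, with a justification, override —
every step between the extracted data and the final grade.

The unit of grading is the **body of evidence**: all included studies for
one prognostic factor and one outcome. The final grade lives on the usual
four-level scale (very low `+` to high `++++`), with the standard
confidence definitions attached (`grade_scale()`).

## The grading arithmetic

The engine computes `level = clamp(start + sum(deltas), 1, 4)`.

* **Start**: 4 when a strict majority of studies is phase 2/3, else 3. A
  tie resolves to 3, the conservative choice. The value 3 for phase-1
  evidence is the only starting point under which the published example
  gradings we replay in the test suite are arithmetically consistent with
  −1 per serious concern, −2 per very serious concern and +1 per upgrade;
  the package documents this reconstruction rather than leaving it
  implicit.
* **Deltas**: serious −1, very serious −2, upgrades +1 by default. How far
  a single factor should move a grade is explicitly unsettled in the
  framework this package implements, so the magnitudes are exposed in
  `grade_deltas()` rather than hard-coded.
* **Clamping**: applied once, after summation. Upgrades can in principle
  lift a phase-1 body to high; nothing in the framework forbids it, and a
  team that disagrees can cap it via an override.

`grade()` runs the assessors in a fixed order (study limitations,
inconsistency, indirectness, imprecision, publication bias, effect size,
dose-response) and keeps every `factor_assessment` in an ordered ledger;
`grade_from_flags()` applies the same arithmetic to externally supplied
ratings, which is how a published summary-of-findings row can be replayed
and audited.

## The assessors and their tunable parameters

All numeric rules live in `grade_thresholds()`; every default is
overridable there or from a JSON/YAML config file, and the applied values
are echoed into logs. The defaults, with units:

| Parameter | Default | Meaning |
|---|---|---|
| `or_moderate`, `or_large` | 2.5, 4.25 (odds ratio) | magnitude rules of thumb for ratio measures |
| `smd_moderate`, `smd_large` | 0.5, 0.8 (SMD) | magnitude rules of thumb for standardized differences |
| `i2_substantial` | 50 (%) | I² from which heterogeneity is substantial |
| `events_per_variable` | 10 (events/variable) | power rule of thumb, dichotomous outcomes |
| `continuous_endpoint_cases` | 100 (cases) | power rule of thumb, continuous or indeterminable outcomes |
| `min_studies_no_pub_bias` | 4 (studies) | repetition waiving the publication-bias default |
| `few_studies` | 3 (studies) | "few studies" in across-study imprecision |
| `overlap_minimal` | 0.10 (fraction) | pairwise CI overlap below this is "minimal" |
| `rob_majority` | 0.5 (fraction) | a share above this is a "majority" (strict) |

All boundaries are inclusive: an OR of exactly 4.25 is large, I² of exactly
50 is substantial, exactly 10 events per variable is adequate. Published
guidance phrases the moderate cut-offs as "around" 2.5 / 0.5; treating them
as inclusive boundaries keeps the classifier total and symmetric.
Protective ratio effects classify by the reciprocal (`max(x, 1/x)`), which
makes `classify_effect_magnitude` invariant under `x → 1/x` — a property
the suite tests on a grid.

Decisions the framework leaves genuinely open, and how this package
resolves them:

* **"Most" studies/domains** means a strict majority by count;
  participant-weighted majorities are available
  (`weight_by = "participants"`) because the framework says "most
  evidence" without committing to a weighting.
* **Unclear QUIPS ratings** pool with moderate during aggregation, since
  the serious-limitations rule is phrased over "moderate or unclear risk".
  Per study, high risk on ≥ 5 of six domains is "almost all"; a 3–3
  low/moderate split is not "mostly low" and counts as moderate —
  conservative on purpose.
* **The clinical-meaningfulness gate on inconsistency** applies only when
  the reviewer supplies the judgment. If
  `clinical_meaningfulness_of_differences` is `FALSE` the statistical
  signals are moot; when it is absent the signals decide alone. Requiring
  an affirmative judgment before ever downgrading would make the assessor
  inert in fully automated runs, which contradicts the default-skeptical
  posture of the rest of the framework.
* **Very serious inconsistency** is an escalation, not an independent
  trigger: a body that already meets the downgrade conditions is escalated
  to very serious when point estimates straddle the null *and* some pair of
  intervals is disjoint. Letting straddle-plus-disjoint fire on its own
  would downgrade roughly one homogeneous 10-study body in eight purely by
  chance (pairwise extremes among 45 pairs), which the calibration
  simulations in the suite would expose.
* **Single-study bodies** always downgrade for inconsistency — not because
  inconsistency is observable with one study, but because a lone study
  means the literature is not established. The same body typically also
  carries the publication-bias default, and, when nothing is reported to
  judge precision, an *unclear* imprecision rating: unclear never moves
  the grade but is preserved in the ledger, the table cell, and a
  footnote.
* **The events-per-variable discrepancy**: a study can be described in its
  own report as well powered while failing the 10-events-per-variable
  rule (e.g. 134 events against 14 candidate variables = 9.6). The
  assessor follows the rule and attaches a note naming the failing
  studies instead of guessing intent.
* **The publication-bias waiver** is count-based (no funnel-plot or
  regression statistics — the framework's rule is about repetition, not
  asymmetry). `min_studies_no_pub_bias = 4` is the only split consistent
  with the replayed example table, where the four-study body is exempt and
  every two- or three-study body is downgraded. When the repetition is
  purely phase-1 the rationale records that the phase penalty is not
  applied twice.

## Meta-analytic machinery and numerical choices

Ratio measures pool on the log scale; SMDs pool on their own scale; mixing
the two families within one body is an error, never a silent conversion.
The null is 1 for ratios and 0 for differences, handled uniformly by the
log transform. Standard errors are recovered from confidence intervals as
`(upper − lower) / (2 z)` on the analysis scale, with `z` derived from the
stated confidence level via the normal quantile (1.959964 at 95%), not
hard-coded.

Fixed-effect pooling is inverse-variance; the random-effects estimator is
DerSimonian–Laird, chosen as the method-of-moments standard with a closed
form (`tau² = max(0, (Q − df) / (Σw − Σw²/Σw))`); alternative τ²
estimators are out of scope. Q and I² are always computed from fixed-effect
weights, so the heterogeneity diagnostics do not depend on the pooling
method; I² is floored at 0 and bounded below 100 by construction.
Degenerate 2×2 cells receive the +0.5 continuity correction (Woolf); a
fully empty margin is an error, because the odds ratio is genuinely
undefined there. Pairwise CI overlap is measured as intersection length
over the *shorter* interval, which makes "one interval nested in a much
wider one" count as full overlap — the quantity the minimal-overlap
judgment cares about. Gradient detection demands strict monotonicity
(ties break the gradient) over at least three doses; fewer levels are
reported as not assessable rather than as absent.

## The synthetic-evidence generator

`generate_body()` emulates exactly the statistical structure the
inconsistency and imprecision rules assume: study *i* has a true log odds
ratio `θᵢ ~ Normal(true_theta, tau²)`; participants split evenly into
exposed and unexposed; events are binomial with the unexposed risk at
`baseline_risk` and the exposed odds multiplied by `exp(θᵢ)`; the observed
estimate is the 2×2-table odds ratio with its Woolf interval. Phase,
risk-of-bias profile, indirectness flags and significance votes are drawn
from explicit per-study profiles. Seeds are explicit and the caller's RNG
state is restored, so identical specs give identical bodies.

What this emulates well: sampling error, between-study heterogeneity,
event-rate-driven precision, and the interaction of all three with the
rule thresholds. What it does not emulate: time-to-event outcomes,
attrition processes, covariate-adjustment effects (the "adjusted" estimate
is generated unadjusted), correlated risk-of-bias domains, or selective
reporting. Passing the property suite therefore shows the rules behave
correctly *under the framework's own statistical model*, not that the
thresholds are clinically optimal for any particular literature.

Simulation scale in the shipped tests: calibration checks use 200–500
replicates at k = 10–30 studies of 1,500–2,000 participants, sizes at
which the binomial noise is small relative to the heterogeneity being
tested while the whole suite stays interactive. At τ = 0 the heterogeneity
test rejects in 3–8% of replicates and the pooled 95% interval covers the
truth in 93–97%; at τ = 0.3 with 30 studies the DL estimate recovers τ²
within 25% at the median; at τ = 1 the inconsistency assessor downgrades
in over 80% of replicates while staying under 10% at τ = 0.

## Input documents and tables

JSON is the canonical dialect (reading and re-writing a document is
byte-identical); YAML carries the same tree; a flat per-study CSV covers
the common extraction workflow but holds at most one univariate and one
multivariate estimate per study and cannot express overrides. Reading is
all-or-nothing: unknown keys and invariant violations are reported with
the study and field named, and nothing partial-loads. Missing numbers are
explicitly absent (`NA`/`null`), never zero — a study that did not report
a confidence interval is a different scientific fact from one that
reported a zero-width interval, and the imprecision rules treat them
differently.

Summary-of-findings output renders the ledger as glyph cells (✓ / ✕ / ✕✕ /
Unclear / NA, with an ASCII vocabulary in CSV), one footnote per
downgrade, unclear rating, or override. The table is a pure view: every
cell is reconstructible from the `quality_grade` ledger, and the narrative
vote columns (+ / 0 / −) are extracted inputs reproduced verbatim, never
recomputed from the estimates. Blank vote cells are preserved as "not
reported".

## Known limitations

* The rules are a faithful operationalization of one adapted-GRADE
  proposal; they are not a validated instrument, and the framework's own
  authors leave the one-versus-two-level question to review teams.
* Narrative-mode imprecision depends on a participant floor
  (`min_total_participants`, default 400) that the framework only
  gestures at ("small number of participants"); teams should set it per
  review.
* Item-level QUIPS scoring is out of scope: domain-level ratings are
  inputs, extracted by the review team.
* No funnel-plot statistics, meta-regression, or subgroup machinery; when
  heterogeneity is explained by subgroups the framework recommends
  separate pooled estimates, which here means grading separate bodies.
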