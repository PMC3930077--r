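# prognograde

Systematic reviews of **prognostic factor research** — studies asking which
baseline characteristics are associated with the later course of an existing
health condition — need a way to say how much confidence a body of evidence
deserves. The GRADE framework does this for intervention research; prognosis
evidence needs an adapted set of rules, because the primary studies are
observational cohorts at varying phases of investigation, estimates are often
unadjusted or unreported, and publication bias must be presumed rather than
tested. `prognograde` implements such an adapted framework as a
deterministic, auditable grading engine: structured per-study evidence goes
in, a four-level quality grade with a complete ledger of every applied
adjustment comes out, alongside meta-analytic diagnostics and
summary-of-findings tables.

Built for evidence-synthesis methodologists and review teams grading bodies
of prognostic evidence (one factor × one outcome), and for anyone who wants
the judgment rules to be explicit, reproducible, and overridable only with a
recorded justification.

## The grading model

Each body of evidence starts at a level set by the **phase of
investigation** of its studies:

- majority phase 2 (confirmatory) or phase 3 (explanatory, model-driven) →
  start **high** (4),
- majority phase 1 (hypothesis-generating association finding) → start
  **moderate** (3), since such studies are particularly vulnerable to
  false-positive findings.

Five factors can lower the level (−1 when serious, −2 when very serious) and
two can raise it (+1):

| Factor | Default rule |
|---|---|
| Study limitations | serious when most studies are at moderate/unclear risk of bias on most of the six QUIPS domains; very serious when most are at high risk on ≥ 5 of 6 |
| Inconsistency | single study always downgrades; with meta-analysis, downgrade when ≥ 2 of {directions straddle the null with minimal CI overlap, heterogeneity test p < 0.05, I² ≥ 50%}; narratively, when directions vary and CIs overlap minimally or are unavailable |
| Indirectness | majority of studies indirect in population, factor, or outcome; very serious on ≥ 2 dimensions |
| Imprecision | pooled CI spanning the null plus both appreciable regions; narratively, most studies imprecise (no sample-size justification and < 10 events per candidate variable, or < 100 endpoint cases) with few studies and few participants; *unclear* when nothing reported permits a judgment |
| Publication bias | downgrade by default — prognosis research is presumed affected — waived from 4 studies |
| Moderate/large effect | pooled (or majority same-direction) OR ≥ 2.5 moderate, ≥ 4.25 large; SMD ≥ 0.5 / ≥ 0.8; protective ratios judged by reciprocal |
| Exposure-response gradient | strictly monotone effect over ≥ 3 exposure levels, consistent across reporting studies |

The final grade is `clamp(start + Σ deltas, 1, 4)`, printed as `+` (very
low) through `++++` (high). Every assessment records its rating, delta, and
a machine-generated rationale; downgrades become table footnotes. Reviewer
overrides are honoured anywhere, but only with a nonempty justification, and
are marked as overrides in the ledger.

Under the hood the package carries its own inverse-variance machinery:
log-scale conversion of OR/RR/HR (SMD pools on its own scale), fixed-effect
and DerSimonian–Laird random-effects pooling, Cochran's Q, I² =
max(0, (Q − df)/Q) × 100, pairwise CI-overlap profiles, direction splits,
2×2-table odds ratios with Woolf intervals, and a monotone
exposure-gradient detector.

## Worked example

Four phase-1 cohort studies of sex as a prognostic factor for headache
persistence, all at moderate risk of bias on four of six QUIPS domains,
three reporting moderate same-direction adjusted odds ratios:

```r
library(prognograde)
rob4 <- rob_profile("moderate", "moderate", "moderate", "moderate", "low", "low")
mk <- function(id, or, lo, hi, n, uv, mv)
  study_record(id, phase = 1L, design = "prospective_cohort", n_participants = n,
               rob = rob4,
               effects = list(effect_estimate("OR", or, lo, hi, adjusted = TRUE)),
               uni_vote = uv, mv_vote = mv)
sex <- body_of_evidence("sex", "headache persistence", list(
  mk("stanford2008", 2.6, 1.30, 5.20, 818L, "positive", "positive"),
  mk("monastero2006", 2.7, 0.95, 7.70, 818L, "null", "null"),
  mk("termine2004",  2.9, 0.98, 8.60, 818L, "null", "null"),
  mk("wang2007",     1.2, 0.80, 1.80, 818L, NA, "null")))
grade(sex)
```

```
Quality of evidence: +++ (moderate, level 3 of 4; started at 3)
phase              serious       (delta +0)  4 of 4 studies are phase 1 (hypothesis-generating): start moderate
study_limitations  serious       (delta -1)  most of 4 studies are at moderate or unclear risk of bias for most QUIPS domains
inconsistency      no_concern    (delta +0)  results are consistent in direction or intervals overlap substantially
indirectness       no_concern    (delta +0)  studies represent the review population, factor and outcome directly
imprecision        no_concern    (delta +0)  the majority of studies report precise estimates
publication_bias   no_concern    (delta +0)  factor repetitively investigated (4 studies >= 4): default downgrade waived; repetition is purely phase 1, already penalized at the starting level (no double-downgrade with phase)
effect_size        present       (delta +1)  most studies report moderate or large same-direction (risk) effects
dose_response      not_applicable (delta +0)  no study reports effect estimates at multiple exposure levels
Footnotes:
  a. study limitations (serious): most of 4 studies are at moderate or unclear risk of bias for most QUIPS domains
```

Reading it: the body starts at moderate (all phase 1), loses one level for
risk of bias, is exempt from the publication-bias default (four studies),
and gains one level back because three of four studies report a moderate
same-direction effect — net `+++`, moderate quality.
`write_sof(list(sex), list(grade(sex)), layout = "narrative")` renders the
same ledger as a summary-of-findings table row
(`✕^a^ ✓ ✓ ✓ ✓ ✓ ✕ → +++`) with footnote *a* spelled out below the table.

## Command line

```sh
inst/cli/prognograde grade --layout narrative bodies/*.json   # SoF table on stdout
inst/cli/prognograde check body.yaml                          # validate only
inst/cli/prognograde simulate --preset heterogeneous --seed 7 # synthetic body JSON
inst/cli/prognograde thresholds                               # effective config
```

Bodies are JSON/YAML documents or flat per-study CSV; thresholds load from a
JSON/YAML config file (`--thresholds`). Exit codes: 0 ok, 1 validation
failure, 2 usage error.

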