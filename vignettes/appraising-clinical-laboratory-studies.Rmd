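---
title: "Appraising clinical laboratory studies: the model behind roblab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising clinical laboratory studies: the model behind roblab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roblab)
```

## The appraisal problem

Clinical laboratory studies relate laboratory parameters — blood or tissue
markers measured on patient samples — to clinical findings, and are often
the only evidence behind a proposed disease mechanism or treatment
rationale. Unlike randomized trials (RoB 2) or non-randomized intervention
studies (ROBINS-I), they had no dedicated risk-of-bias instrument, so
evidence syntheses either excluded them or appraised them informally.
`roblab` implements a pilot instrument, developed by expert consensus for
exactly this study design, as a reproducible assessment engine: the
instrument is machine-readable data, the judgement rules are code, and
every derived artifact (judgements, agreement statistics, traffic-light
summaries) is deterministic given the recorded answers.

## The instrument

The bundled tool, `pilot_lab_tool()`, has three bias domains:

1. **Collection and handling of samples** (5 questions) — participant
   selection, sample-size planning, contemporaneity, matching, and
   consistent sample preparation.
2. **Experimental methods** (5 questions) — validated methodology, normal
   ranges, prespecified statistical comparisons, blinding of evaluators,
   and internal/external controls.
3. **Reporting of the results** (4 questions) — quantification, data
   completeness, appropriate statistical tests, and data availability.

Every signalling question is answered `yes` / `no` / `no_information`, at
the **outcome level**: one assessment record covers one outcome of one
study as appraised by one assessor. The tool applies to both comparative
(controlled) and single-arm (uncontrolled) studies; four questions whose
wording references a comparison group (`D1.Q4`, `D1.Q5`, `D2.Q3`,
`D3.Q3`) are flagged `controlled_only` and omitted for single-arm studies.

Two flag assignments deserve comment, because the tool's published form
does not enumerate which questions are "control-group" questions:

* The four flagged questions each explicitly mention groups or controls in
  their wording; no other question does.
* The normal-range question (`D2.Q2`) is deliberately *not* flagged: a
  normal range refers to a healthy reference population distribution, not
  to the study's own control arm, so it remains answerable for single-arm
  studies.

The flags are instrument *data*, not code: users who read the tool
differently can edit the YAML (`inst/extdata/pilot_clinlab_tool.yaml`) and
load their variant with `read_instrument()`. Question identifiers
(`D<i>.Q<j>`) follow row order in the published table, which itself assigns
none.

## The judgement model

Let $k$ be the number of a domain's applicable questions answered `no` or
`no_information`. The domain judgement is

$$
J(k) \;=\;
\begin{cases}
\text{Low} & k = 0\\
\text{Some concerns} & k = 1\\
\text{High} & k \ge 2
\end{cases}
$$

and the overall judgement is the maximum of the domain judgements on the
ordinal scale $\text{Low} < \text{Some concerns} < \text{High}$.

Interpretation choices embedded here, where the published wording leaves
room:

* "If one question is answered no" is read as **exactly one** ($k = 1$);
  this is the only reading under which the rule's sentences partition all
  outcomes.
* The overall rule's published sentences cover only the any-High and
  all-Low cases. A worst domain of Some concerns therefore yields overall
  Some concerns, by the "highest domain judgement" principle. This is an
  interpretation, surfaced here rather than buried.
* For uncontrolled studies the thresholds (1, 2) are **not rescaled** to
  the smaller applicable-question count: omission of control questions is
  described as omission, not as a renormalization. The thresholds are
  nonetheless per-domain parameters (`some_concerns_at`, `high_at`) so
  sensitivity analyses can vary them.
* A domain left with zero applicable questions is an **error**, not an
  automatic Low: absence of evidence is not low risk.
* `no` and `no_information` are interchangeable in effect, and the rule is
  invariant to answer order — both properties are enforced by tests over
  the exhaustively enumerated answer space ($3^n$ vectors,
  `exhaustive_domain_vectors()`), where the level counts have the closed
  form $(1,\; 2n,\; 3^n - 1 - 2n)$.

```{r rule}
judge_domain(c("yes", "yes", "yes", "yes", "yes"))
judge_domain(c("yes", "no", "yes", "yes", "yes"))
enumerate_rule_distribution(5)
```

## Assessment records and validation

Records travel as long-format CSV (one row per study x outcome x assessor
x question) or nested JSON. The long format was chosen because
per-question justification quotes — standard systematic-review practice —
do not fit a wide layout. Answer tokens are matched case-insensitively
with the synonyms `NI` and `no information`. Validation classifies
problems as `missing-answer`, `unknown-question`, or
`inapplicable-question-answered`; a missing answer is never imputed.
Inapplicable questions are *absent* from a record rather than stored as a
fourth answer value, which keeps the judgement rule's denominator
well-defined.

## Dual-assessor agreement

The intended workflow has two assessors apply the tool independently,
compare, and resolve disagreements to a consensus record
(`compare_assessors()`, `consensus_merge()`). Agreement is reported at
three granularities — per question, per domain, per overall judgement —
because question-level disagreement can vanish at domain level under the
counting rule (two assessors flagging *different* single questions both
reach Some concerns). Chance-corrected agreement uses Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, plus a weighted variant on the 3-level
ordinal scale. Linear weights are the default (quadratic available):
with only three levels, quadratic weighting makes a
Low-vs-Some-concerns disagreement count only a quarter of a Low-vs-High
one, which overstates partial credit for this coarse scale.

When both raters are constant and identical, $p_e = 1$ and kappa is 0/0.
This is common in small appraisals (e.g., every study judged High). It is
reported as an explicit undefined sentinel (`defined = FALSE`,
`kappa = NA`) alongside the observed agreement of 1 — never as silent
`NaN` propagation. The pilot's own application reported no quantitative
agreement figure, so there is no published value to reproduce; the
statistics here are standard machinery around the workflow.

## Synthetic data

`simulate_assessments()` draws every answer independently from a
categorical distribution (`answer_model()`), with a configurable
proportion of uncontrolled units and full determinism under an integer
seed (base R Mersenne-Twister). Independence across questions is a
deliberate simplification: real assessments correlate strongly within a
study (a sloppy study tends to fail many questions at once). Passing
tests on simulated data therefore demonstrate the *engine's* correctness
— rule application, validation, round-trips, agreement algebra — not
calibration of the instrument against real study quality, which no
simulation of this kind could show.

The independence assumption buys a useful check: with $P(\text{yes}) = p$
per question, a five-question domain judges Low with probability exactly
$p^5$. At 2000 simulated studies the empirical Low fraction must sit
within three standard errors of $p^5$; this is verified in the test suite
at $p = 0.8$ and in the acceptance script.

The packaged example set (`inst/extdata/synthetic_five_studies.csv`) is
**synthetic**: five controlled studies whose per-question answers were
constructed so the overall pattern is four High and one Some concerns —
the judgement shape reported when the tool was first applied in a
Cochrane review of five laboratory studies. The real per-question answers
live in that review's appendix and are not reproduced here; only the
pattern is mirrored.

## Reporting

`plot_traffic_light()` follows the community convention: units as rows,
domains as columns, overall rightmost, green/yellow/red for
Low/Some concerns/High, with `+` / `?` / `-` symbols overlaid so the
figure survives greyscale and colour-blind viewing (an Okabe-Ito palette
is available via `palette = "colorblind"`). Rendering never recomputes
judgements — cells are taken verbatim from `judge_set()` output, and a
test asserts cell-by-cell equality. Row order is lexicographic by study
then outcome unless an explicit order is supplied, so output is
deterministic. Reports are Markdown with CSV side-tables.

```{r traffic, fig.width = 7, fig.height = 3}
tool <- pilot_lab_tool()
five <- read_assessments(
  system.file("extdata", "synthetic_five_studies.csv", package = "roblab"),
  tool)
j <- judge_set(five, tool)
traffic_light_table(j, tool)
plot_traffic_light(j, tool)
```

## Numerical and design notes

* Proportions in `summarize_distribution()` sum to 1 within 1e-12 per
  domain (they are exact ratios of integers; the tolerance guards only
  floating-point accumulation).
* `enumerate_rule_distribution()` guards enumeration at $n \le 10$
  ($3^{10} = 59049$ vectors) — beyond any plausible domain size.
* Problem sizes in the test suite (500-2000 simulated studies for the
  invariant and calibration checks, 100 seeded sets for round-trips,
  exhaustive enumeration to $n = 8$) were chosen to give the Monte-Carlo
  checks three-standard-error resolution while keeping the suite quick to
  run during development.
* The schema can express other domain/question instruments (RoB 2,
  ROBINS-I) but none is bundled; no attempt is made to encode their
  bespoke per-domain decision algorithms, which are not simple counting
  rules.
* Assessor override of an algorithmic judgement (which RoB 2 permits) is
  not implemented; the pilot tool does not describe one.
* Whether sibling outcomes of one study may be appraised under different
  designs is unspecified in the tool; the schema permits it per record,
  but a single record never mixes designs.

## Limitations

The engine is faithful to a *pilot* instrument: the tool itself has had
limited validation, its domain-2 questions may need study-specific
adaptation (what counts as a "validated assay" varies by field), and the
counting rule weighs all questions equally, which is a modelling choice of
the instrument, not of this package. The agreement module covers exactly
two raters; multi-rater generalizations (Fleiss kappa) are out of scope.
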