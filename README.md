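# roblab — risk-of-bias appraisal engine for clinical laboratory studies

Clinical laboratory studies — studies that relate blood or tissue markers
measured on patient samples to clinical findings — are increasingly cited
as the mechanistic rationale for treatments, yet until recently had no
dedicated risk-of-bias instrument for use in systematic reviews. `roblab`
implements a pilot appraisal tool for this study design, developed by
expert consensus in the RoB 2 / ROBINS-I tradition, as a complete
assessment engine for systematic reviewers and methodologists:

* the **instrument** itself (3 bias domains, 14 signalling questions,
  per-question guidance) shipped as machine-readable YAML and as the
  constructor `pilot_lab_tool()`;
* validated **assessment records** at the outcome level (one record per
  study x outcome x assessor), in long-format CSV or nested JSON;
* deterministic **judgement aggregation**;
* **dual-assessor agreement** (percent agreement at question, domain and
  overall granularity; Cohen's kappa, unweighted and linearly weighted)
  and consensus merging;
* **traffic-light** tables/plots, judgement-distribution summaries, and
  narrative Markdown reports;
* a **simulator** for synthetic assessment sets, and a **command-line
  interface** covering the whole workflow.

## The model

Each of the three domains — collection and handling of samples (D1, 5
questions), experimental methods (D2, 5 questions), reporting of the
results (D3, 4 questions) — is judged from its signalling-question answers
(`yes` / `no` / `no_information`) by a counting rule. With *k* the number
of applicable questions not answered `yes`:

    J(k) = Low            if k = 0
           Some concerns  if k = 1
           High           if k >= 2

The overall judgement is the **maximum** (worst) domain judgement on the
ordinal scale Low < Some concerns < High. For uncontrolled (single-arm)
studies the four questions referencing a comparison group (D1.Q4, D1.Q5,
D2.Q3, D3.Q3) are omitted; the thresholds are not rescaled. Over all 3^n
answer vectors of an n-question domain the rule yields exactly 1 Low,
2n Some concerns, and 3^n − 1 − 2n High — an identity the test suite
verifies by exhaustive enumeration for n = 1…8.

## Worked example

Appraise the packaged synthetic five-study set (five controlled studies
whose answers were constructed to mirror the judgement pattern of the
tool's first real application — four studies at high risk of bias, one
with some concerns):

```r
library(roblab)
tool <- pilot_lab_tool()
tool
#> <rob_instrument> clinlab-pilot v1.0
#>   D1: Collection and handling of samples (5 questions; rule 1/2)
#>   D2: Experimental methods (5 questions; rule 1/2)
#>   D3: Reporting of the results (4 questions; rule 1/2)
#>   14 questions total, 4 controlled-only

five <- read_assessments(
  system.file("extdata", "synthetic_five_studies.csv", package = "roblab"),
  tool)
j <- judge_set(five, tool)
traffic_light_table(j, tool, symbols = TRUE)
#>   study_id outcome_id assessor_id                D1                D2                D3           Overall
#> 1       S1         O1          A1          High (-) Some concerns (?)           Low (+)          High (-)
#> 2       S2         O1          A1 Some concerns (?)          High (-) Some concerns (?)          High (-)
#> 3       S3         O1          A1 Some concerns (?)          High (-)           Low (+)          High (-)
#> 4       S4         O1          A1 Some concerns (?)           Low (+)          High (-)          High (-)
#> 5       S5         O1          A1           Low (+) Some concerns (?)           Low (+) Some concerns (?)
```

Each row is one study x outcome unit; a `High (-)` cell means at least two
of that domain's questions were answered `no` or `no information`, and the
rightmost column is the worst domain judgement — here 4 of the 5 studies
are at high overall risk of bias. A single record prints its full
derivation:

```r
judge_record(set_records(five)[[5]], tool)
#> <rob_judgement> S5 / O1 / A1 (controlled)
#>   D1: Low (0 non-yes)
#>   D2: Some concerns (1 non-yes)
#>   D3: Low (0 non-yes)
#>   Overall: Some concerns
```

`plot_traffic_light(j, tool)` renders the same table as the conventional
green/yellow/red figure, and `render_report(five, j, tool)` produces a
Markdown report with per-question answers and justifications.

## Command line

A launcher script is installed with the package
(`system.file("cli", "roblab", package = "roblab")`):

```sh
roblab template --design uncontrolled            # blank 10-row CSV template
roblab judge    --input answers.csv              # judgements (CSV/JSON)
roblab agree    --input answers.csv --assessor-a TF --assessor-b RK
roblab plot     --input answers.csv --output fig # fig.png + fig.svg + fig.csv
roblab simulate --studies 20 --seed 7            # synthetic set
```

Exit codes: 0 success, 2 input error, 3 validation failure.

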