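instrument_id: clinlab-pilot
version: '1.0'
provenance: Pilot consensus risk-of-bias tool for clinical laboratory studies; outcome-level
  appraisal across three bias domains.
domains:
- domain_id: D1
  name: Collection and handling of samples
  rule:
    some_concerns_at: 1
    high_at: 2
  questions:
  - question_id: D1.Q1
    text: Have patients been clinically evaluated to ensure they fulfil the criteria
      for inclusion?
    guidance: This question is used to ensure that appropriate diagnostic tests been
      performed to ensure that participants providing samples meet the criteria for
      the exposure and control groups. Samples taken from participants who have not
      been formally diagnosed may not accurately represent the population group.
    controlled_only: no
  - question_id: D1.Q2
    text: Have statistical calculations been performed to determine an appropriate
      sample size?
    guidance: This is required to ensure the sample size is large enough to detect
      a difference between the groups. Underpowered studies may yield significant
      results more easily and lead to the publishing of experiments that were never
      necessarily intended to be published.
    controlled_only: no
    note: This signaling question was added in November 2023 after the development
      of the original tool, following a discussion with the panel.
  - question_id: D1.Q3
    text: Are samples contemporaneous?
    guidance: The integrity of samples obtained at different time points will be affected
      by the time spent in storage.
    controlled_only: no
  - question_id: D1.Q4
    text: Have patients been matched on non-investigational characteristics that may
      introduce confounding?
    guidance: Matching characteristics across groups that are not being investigated,
      such as age, sex, and health status, reduces confounding bias.
    controlled_only: yes
  - question_id: D1.Q5
    text: Have samples from both groups been collected and prepared in the same way?
    guidance: Samples should be consistently handled to ensure this does not influence
      how they respond in laboratory experiments, e.g., test and control samples should
      be subjected to the same number of freeze-thaw cycles and sampling to avoid
      biased degradation or contamination.
    controlled_only: yes
- domain_id: D2
  name: Experimental methods
  rule:
    some_concerns_at: 1
    high_at: 2
  questions:
  - question_id: D2.Q1
    text: Is a validated methodology used? If not, is the methodology well described?
    guidance: Methods used may be widely accepted, or new methods can be used that
      are adequately described and justified.
    controlled_only: no
  - question_id: D2.Q2
    text: Has a normal range been calculated?
    guidance: This study design requires appropriate statistical calculations to establish
      a normal range (typically considered a range of values that you would expect
      to see for 95% of a healthy population when conducting a specific test).
    controlled_only: no
  - question_id: D2.Q3
    text: Have statistical methods been planned to compare the values of experimental
      groups with controls?
    guidance: Prespecified methods for comparing the values of experimental groups
      with controls ensures that a statistical plan is followed.
    controlled_only: yes
  - question_id: D2.Q4
    text: Are the people evaluating the data blind to the source of the samples?
    guidance: Knowledge of the group from which the samples have been obtained may
      introduce bias in evaluation of the data.
    controlled_only: no
  - question_id: D2.Q5
    text: Is an internal and external control used?
    guidance: An internal control is used to monitor and assure the reproducibility
      of results. An external control is a real, positive clinical sample used to
      monitor for errors in the experimental process.
    controlled_only: no
- domain_id: D3
  name: Reporting of the results
  rule:
    some_concerns_at: 1
    high_at: 2
  questions:
  - question_id: D3.Q1
    text: Are the results quantified and with appropriate analysis?
    guidance: Results should be fully quantified to allow appropriate analysis.
    controlled_only: no
  - question_id: D3.Q2
    text: Are all, or nearly all, data available?
    guidance: An appropriate analysis should include data from all samples that were
      included.
    controlled_only: no
  - question_id: D3.Q3
    text: Are appropriate statistical tests used to test for differences between groups?
    guidance: This allows validated comparison between values.
    controlled_only: yes
  - question_id: D3.Q4
    text: Are the data available in a repository and accessible to others?
    guidance: Laboratory data should be made publicly available to allow external
      analysis and comparison. Coefficients of inter and intra assay variation should
      be made available.
    controlled_only: no

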