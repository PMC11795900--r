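# Shared fixtures built in code.

pilot <- pilot_lab_tool()
pilot_qt <- question_table(pilot)

# A complete record on the pilot tool: all "yes" except the named overrides.
make_record <- function(study = "S1", outcome = "O1", assessor = "A1",
                        design = "controlled", overrides = character(),
                        justifications = NULL) {
  qt <- applicable_questions(pilot, design)
  ans <- stats::setNames(rep("yes", nrow(qt)), qt$question_id)
  stopifnot(all(names(overrides) %in% names(ans)))
  ans[names(overrides)] <- overrides
  rob_record(study, outcome, assessor, design, ans,
             justifications = justifications)
}

# Independent closed form for the domain-rule level distribution over all
# 3^n answer vectors under the default thresholds: a vector is Low only when
# every answer is yes (1 way); Some concerns needs exactly one non-yes
# question (n positions x 2 non-yes values); everything else is High.
closed_form_counts <- function(n) {
  c(Low = 1, `Some concerns` = 2 * n, High = 3^n - 1 - 2 * n)
}

# Minimal single-domain instrument for edge cases.
tiny_instrument <- function(n_questions = 2L, controlled_only = FALSE) {
  qs <- lapply(seq_len(n_questions), function(i)
    rob_question(paste0("D1.Q", i), paste("Question", i),
                 paste("Guidance", i),
                 controlled_only = controlled_only))
  rob_instrument("tiny", "0.1",
                 list(rob_domain("D1", "Single domain", qs)))
}
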