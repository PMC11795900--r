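test_that("the domain rule reproduces the published sentences", {
  # all yes -> low risk
  expect_equal(as.character(judge_domain(rep("yes", 5))), "Low")
  # exactly one no / no-information -> some concerns
  expect_equal(as.character(judge_domain(c("yes", "no", "yes", "yes",
                                           "yes"))), "Some concerns")
  expect_equal(as.character(judge_domain(c("yes", "yes", "yes",
                                           "no_information"))),
               "Some concerns")
  # more than one non-yes -> high risk
  expect_equal(as.character(judge_domain(c("no", "no_information", "yes",
                                           "yes"))), "High")
  # single-question domain can never reach High under the default rule
  expect_equal(as.character(judge_domain("yes")), "Low")
  expect_equal(as.character(judge_domain("no")), "Some concerns")
  # guards
  expect_error(judge_domain(character()), "zero applicable questions")
  expect_error(judge_domain("yes", some_concerns_at = 0), "thresholds")
})

test_that("the overall rule is the maximum over the ordinal scale", {
  expect_equal(as.character(judge_overall(c(D1 = "High", D2 = "Low",
                                            D3 = "Low"))), "High")
  expect_equal(as.character(judge_overall(c(D1 = "Low", D2 = "Low",
                                            D3 = "Low"))), "Low")
  expect_equal(as.character(judge_overall(c(D1 = "Some concerns",
                                            D2 = "Low", D3 = "Low"))),
               "Some concerns")
  expect_error(judge_overall(character()), "zero domain judgements")
  expect_error(judge_overall("Moderate"), "unknown risk level")
})

test_that("judge_record composes the two rules over applicable questions", {
  all_yes <- judge_record(make_record(), pilot)
  expect_true(all(all_yes$per_domain == "Low"))
  expect_equal(as.character(all_yes$overall), "Low")
  expect_equal(unname(all_yes$non_yes_counts), c(0L, 0L, 0L))

  one_ni <- judge_record(make_record(overrides = c(D2.Q2 =
                                                     "no_information")),
                         pilot)
  expect_equal(as.character(one_ni$per_domain),
               c("Low", "Some concerns", "Low"))
  expect_equal(as.character(one_ni$overall), "Some concerns")

  mixed <- judge_record(
    make_record(overrides = c(D1.Q1 = "no", D1.Q3 = "no", D3.Q2 = "no")),
    pilot)
  expect_equal(as.character(mixed$per_domain),
               c("High", "Low", "Some concerns"))
  expect_equal(as.character(mixed$overall), "High")
  expect_equal(unname(mixed$non_yes_counts), c(2L, 0L, 1L))

  # uncontrolled: thresholds apply to the smaller applicable set unchanged
  unc <- judge_record(
    make_record(design = "uncontrolled",
                overrides = c(D1.Q1 = "no", D1.Q2 = "no")), pilot)
  expect_equal(as.character(unc$per_domain["D1"]), "High")

  # invalid record refuses to judge
  incomplete <- make_record()
  incomplete$answers <- incomplete$answers[-1]
  expect_error(judge_record(incomplete, pilot), "D1.Q1")
})

test_that("a domain emptied by the design filter is an explicit error", {
  ctrl_only <- tiny_instrument(2L, controlled_only = TRUE)
  qt <- applicable_questions(ctrl_only, "uncontrolled")
  expect_equal(nrow(qt), 0L)
  rec <- rob_record("S1", "O1", "A1", "uncontrolled",
                    stats::setNames(character(), character()))
  expect_error(judge_record(rec, ctrl_only), "D1")
})

test_that("enumeration over all answer vectors matches the closed form", {
  for (n in 1:8) {
    expect_equal(enumerate_rule_distribution(n), closed_form_counts(n),
                 info = paste("n =", n))
  }
  expect_equal(unname(enumerate_rule_distribution(5)), c(1, 10, 232))
  expect_equal(unname(enumerate_rule_distribution(4)), c(1, 8, 72))
  expect_equal(unname(enumerate_rule_distribution(1)), c(1, 2, 0))
  expect_error(enumerate_rule_distribution(0), "1..10")
})

test_that("degrading any single answer never lowers the domain level", {
  vecs <- exhaustive_domain_vectors(5)
  base_levels <- apply(vecs, 1, function(a) as.integer(judge_domain(a)))
  violations <- 0L
  for (i in seq_len(nrow(vecs))) {
    a <- vecs[i, ]
    for (j in which(a == "yes")) {
      for (worse in c("no", "no_information")) {
        b <- a
        b[j] <- worse
        if (as.integer(judge_domain(b)) < base_levels[i]) {
          violations <- violations + 1L
        }
      }
    }
  }
  expect_identical(violations, 0L)
})

test_that("the rule is symmetric in answer order and non-yes identity", {
  vecs <- exhaustive_domain_vectors(4)
  for (i in seq_len(nrow(vecs))) {
    a <- vecs[i, ]
    expect_identical(judge_domain(sample(a)), judge_domain(a))
    swapped <- a
    swapped[a == "no"] <- "no_information"
    swapped[a == "no_information"] <- "no"
    expect_identical(judge_domain(swapped), judge_domain(a))
  }
})

test_that("overall equals the max domain level across random sets", {
  set <- simulate_assessments(
    pilot, n_studies = 250, outcomes_per_study = 2, assessors = c("A1", "A2"),
    model = answer_model(0.6, 0.25, 0.15, design_mix = 0.4), seed = 42)
  j <- judge_set(set, pilot)
  jd <- as.data.frame(j)
  key <- paste(jd$study_id, jd$outcome_id, jd$assessor_id)
  for (u in unique(key)) {
    rows <- jd[key == u, ]
    expect_equal(as.character(rows$level[rows$domain_id == "OVERALL"]),
                 as.character(max(risk_level(
                   rows$level[rows$domain_id != "OVERALL"]))))
  }
  # and judge_set agrees with per-record judging
  rec <- set_records(set)[[7]]
  jr <- judge_record(rec, pilot)
  rows <- jd[jd$study_id == rec$study_id & jd$outcome_id == rec$outcome_id &
               jd$assessor_id == rec$assessor_id, ]
  expect_equal(stats::setNames(as.character(rows$level), rows$domain_id),
               c(as.character(jr$per_domain) |>
                   stats::setNames(names(jr$per_domain)),
                 OVERALL = as.character(jr$overall)))
})

test_that("judgement exports carry levels and counts in both formats", {
  set <- rob_set(list(make_record(overrides = c(D1.Q1 = "no",
                                                D1.Q2 = "no"))), pilot)
  j <- judge_set(set, pilot)
  csv <- write_judgements(j, format = "csv")
  df <- utils::read.csv(textConnection(csv), stringsAsFactors = FALSE)
  expect_equal(names(df), c("study_id", "outcome_id", "assessor_id",
                            "design", "domain_id", "level",
                            "non_yes_count"))
  expect_equal(df$level[df$domain_id == "D1"], "High")
  expect_equal(df$level[df$domain_id == "OVERALL"], "High")
  js <- jsonlite::fromJSON(write_judgements(j, format = "json"))
  expect_equal(js$non_yes_count[js$domain_id == "OVERALL"], 2L)
})
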