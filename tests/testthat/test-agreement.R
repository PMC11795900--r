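# Build a two-assessor set whose per-unit overall levels follow a given
# pattern ("Low" = all yes; "High" = two "no" in D1).
patterned_set <- function(levels_a, levels_b) {
  stopifnot(length(levels_a) == length(levels_b))
  mk <- function(level, study, assessor) {
    ov <- switch(level,
                 Low = character(),
                 High = c(D1.Q1 = "no", D1.Q2 = "no"))
    make_record(study = study, assessor = assessor, overrides = ov)
  }
  recs <- c(
    lapply(seq_along(levels_a), function(i)
      mk(levels_a[i], paste0("S", i), "A")),
    lapply(seq_along(levels_b), function(i)
      mk(levels_b[i], paste0("S", i), "B")))
  rob_set(recs, pilot)
}

test_that("identical duplicate assessors agree perfectly with kappa 1", {
  set <- patterned_set(c("Low", "High", "Low", "High"),
                       c("Low", "High", "Low", "High"))
  rep <- compare_assessors(set, pilot, "A", "B")
  expect_equal(rep$n_units, 4L)
  expect_true(all(rep$question_agreement == 1))
  expect_true(all(rep$domain_agreement == 1))
  expect_equal(rep$overall_agreement, 1)
  expect_true(rep$kappa_overall$defined)
  expect_equal(rep$kappa_overall$kappa, 1)
  expect_equal(rep$kappa_weighted$kappa, 1)
  expect_equal(nrow(rep$disagreements), 0L)
})

test_that("the independence-structured pattern gives kappa exactly 0", {
  # overall levels A = (Low, Low, High, High), B = (Low, High, Low, High):
  # observed agreement 2/4, marginals 1/2 each, p_e = 1/2, kappa = 0
  set <- patterned_set(c("Low", "Low", "High", "High"),
                       c("Low", "High", "Low", "High"))
  rep <- compare_assessors(set, pilot, "A", "B")
  expect_equal(rep$overall_agreement, 0.5)
  expect_equal(rep$kappa_overall$p_expected, 0.5)
  expect_equal(rep$kappa_overall$kappa, 0)
  expect_equal(rep$kappa_weighted$kappa, 0)
})

test_that("constant identical raters are the documented degenerate case", {
  set <- patterned_set(c("Low", "Low", "Low"), c("Low", "Low", "Low"))
  rep <- compare_assessors(set, pilot, "A", "B")
  expect_equal(rep$overall_agreement, 1)
  expect_false(rep$kappa_overall$defined)
  expect_true(is.na(rep$kappa_overall$kappa))
  expect_equal(rep$kappa_overall$p_observed, 1)
})

test_that("agreement statistics are symmetric in the two assessors", {
  set <- simulate_assessments(
    pilot, n_studies = 6, assessors = c("R1", "R2"),
    model = answer_model(0.6, 0.2, 0.2, design_mix = 0.5), seed = 11)
  ab <- compare_assessors(set, pilot, "R1", "R2")
  ba <- compare_assessors(set, pilot, "R2", "R1")
  expect_equal(ab$question_agreement, ba$question_agreement)
  expect_equal(ab$domain_agreement, ba$domain_agreement)
  expect_equal(ab$overall_agreement, ba$overall_agreement)
  expect_equal(ab$kappa_overall$kappa, ba$kappa_overall$kappa)
  expect_equal(ab$kappa_weighted$kappa, ba$kappa_weighted$kappa)
})

test_that("kappa matches an independent implementation on random ratings", {
  skip_if_not_installed("caret")
  set.seed(99)
  for (i in 1:5) {
    a <- sample(RISK_LEVELS, 40, replace = TRUE)
    b <- sample(RISK_LEVELS, 40, replace = TRUE)
    ours <- cohen_kappa(a, b, weights = "none")
    ref <- caret::confusionMatrix(
      factor(a, levels = RISK_LEVELS), factor(b, levels = RISK_LEVELS))
    expect_equal(ours$kappa, unname(ref$overall["Kappa"]),
                 tolerance = 1e-10)
  }
})

test_that("mismatched designs and missing overlap raise errors", {
  recs <- list(
    make_record(study = "S1", assessor = "A"),
    make_record(study = "S1", assessor = "B", design = "uncontrolled"))
  set <- rob_set(recs, pilot)
  expect_error(compare_assessors(set, pilot, "A", "B"),
               "design mismatch.*S1")
  lonely <- rob_set(list(make_record(study = "S1", assessor = "A"),
                         make_record(study = "S2", assessor = "B")), pilot)
  expect_error(compare_assessors(lonely, pilot, "A", "B"),
               "no study x outcome units")
})

test_that("question-level disagreement can vanish at domain level", {
  # A answers "no" on D1.Q1, B answers "no" on D1.Q3: both domains judge
  # Some concerns although no single question agrees everywhere.
  set <- rob_set(list(
    make_record(assessor = "A", overrides = c(D1.Q1 = "no")),
    make_record(assessor = "B", overrides = c(D1.Q3 = "no"))), pilot)
  rep <- compare_assessors(set, pilot, "A", "B")
  expect_lt(min(rep$question_agreement), 1)
  expect_true(all(rep$domain_agreement == 1))
  expect_equal(rep$overall_agreement, 1)
})

test_that("consensus_merge passes agreement through and applies resolutions", {
  agree_set <- patterned_set(c("Low", "High"), c("Low", "High"))
  merged <- consensus_merge(agree_set, NULL, pilot)
  expect_equal(unique(merged$data$assessor_id), "consensus")
  expect_equal(nrow(merged$data), 28L)  # two controlled units
  expect_identical(nrow(validate_set(merged, pilot)), 0L)

  # one disagreement, resolved to "no"
  set <- rob_set(list(make_record(assessor = "A"),
                      make_record(assessor = "B",
                                  overrides = c(D2.Q5 = "no_information"))),
                 pilot)
  res <- data.frame(study_id = "S1", outcome_id = "O1",
                    question_id = "D2.Q5", answer = "no")
  merged <- consensus_merge(set, res, pilot)
  ans <- merged$data$answer[merged$data$question_id == "D2.Q5"]
  expect_equal(ans, "no")

  # unresolved disagreement errors naming the pair
  expect_error(consensus_merge(set, NULL, pilot),
               "unresolved disagreement.*S1, O1, D2.Q5")
})

test_that("agreement reports export to JSON, text, and CSV", {
  set <- patterned_set(c("Low", "High"), c("High", "High"))
  rep <- compare_assessors(set, pilot, "A", "B")
  js <- jsonlite::fromJSON(write_agreement(rep, format = "json"))
  expect_equal(js$n_units, 2L)
  expect_equal(js$overall_agreement, rep$overall_agreement)
  txt <- write_agreement(rep, format = "text")
  expect_match(txt, "kappa")
  csv <- utils::read.csv(textConnection(write_agreement(rep,
                                                        format = "csv")))
  expect_true(all(c("granularity", "item_id") %in% names(csv)))
})
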