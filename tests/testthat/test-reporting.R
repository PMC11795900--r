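fixture_set <- function() {
  path <- system.file("extdata", "synthetic_five_studies.csv",
                      package = "roblab")
  read_assessments(path, pilot)
}

test_that("the packaged five-study fixture shows the 4 High + 1 Some concerns pattern", {
  set <- fixture_set()
  expect_length(set_records(set), 5L)
  j <- judge_set(set, pilot)
  tl <- traffic_light_table(j, pilot)
  expect_equal(nrow(tl), 5L)
  expect_equal(sum(tl$Overall == "High"), 4L)
  expect_equal(sum(tl$Overall == "Some concerns"), 1L)
})

test_that("rendered cells equal the judgement output exactly", {
  set <- fixture_set()
  j <- judge_set(set, pilot)
  tl <- traffic_light_table(j, pilot)
  jd <- as.data.frame(j)
  for (i in seq_len(nrow(tl))) {
    for (dom in c("D1", "D2", "D3", "Overall")) {
      did <- if (dom == "Overall") "OVERALL" else dom
      expect_equal(
        tl[[dom]][i],
        as.character(jd$level[jd$study_id == tl$study_id[i] &
                                jd$outcome_id == tl$outcome_id[i] &
                                jd$assessor_id == tl$assessor_id[i] &
                                jd$domain_id == did]))
    }
  }
  # symbols variant decorates but preserves the level text
  tls <- traffic_light_table(j, pilot, symbols = TRUE)
  expect_match(tls$Overall[tls$study_id == "S5"], "^Some concerns \\(\\?\\)")
})

test_that("minimal and invalid traffic-light inputs behave as specified", {
  one <- judge_set(rob_set(list(make_record()), pilot), pilot)
  tl <- traffic_light_table(one, pilot)
  expect_equal(nrow(tl), 1L)
  expect_equal(unname(unlist(tl[1, c("D1", "D2", "D3", "Overall")])),
               rep("Low", 4))
  expect_error(traffic_light_table(one[0, ], pilot), "non-empty")
  # judgements from a different instrument are refused
  tiny <- tiny_instrument(2L)
  jt <- judge_set(rob_set(list(rob_record("S1", "O1", "A1", "controlled",
                                          c(D1.Q1 = "yes",
                                            D1.Q2 = "yes"))),
                          tiny), tiny)
  expect_error(traffic_light_table(jt, pilot), "different instrument")
})

test_that("judgement distributions are proportions summing to one", {
  set <- fixture_set()
  j <- judge_set(set, pilot)
  tab <- summarize_distribution(j)
  for (dom in unique(tab$domain_id)) {
    expect_equal(sum(tab$proportion[tab$domain_id == dom]), 1,
                 tolerance = 1e-12)
  }
  # hand-derived case: D2 levels (Low, Low, Some concerns, High)
  recs <- list(
    make_record(study = "S1"),
    make_record(study = "S2"),
    make_record(study = "S3", overrides = c(D2.Q1 = "no")),
    make_record(study = "S4", overrides = c(D2.Q1 = "no", D2.Q2 = "no")))
  jd <- judge_set(rob_set(recs, pilot), pilot)
  tab2 <- summarize_distribution(jd)
  d2 <- tab2[tab2$domain_id == "D2", ]
  expect_equal(d2$proportion[match(c("Low", "Some concerns", "High"),
                                   d2$level)],
               c(0.5, 0.25, 0.25))
  # unanimous: unit vector
  solo <- summarize_distribution(judge_set(rob_set(list(make_record()),
                                                   pilot), pilot))
  for (dom in unique(solo$domain_id)) {
    expect_equal(sort(solo$proportion[solo$domain_id == dom]), c(0, 0, 1))
  }
  expect_error(summarize_distribution(jd[0, ]), "non-empty")
})

test_that("plots are ggplot objects with the level scale attached", {
  j <- judge_set(fixture_set(), pilot)
  p <- plot_traffic_light(j, pilot)
  expect_s3_class(p, "ggplot")
  expect_identical(levels(p$data$domain), c("D1", "D2", "D3", "Overall"))
  pc <- plot_traffic_light(j, pilot, palette = "colorblind")
  expect_s3_class(pc, "ggplot")
  p2 <- plot_distribution(j)
  expect_s3_class(p2, "ggplot")
  # deterministic: same input builds identical plot data
  expect_identical(plot_traffic_light(j, pilot)$data,
                   plot_traffic_light(j, pilot)$data)
})

test_that("the narrative report contains the specified sections", {
  set <- rob_set(list(
    make_record(overrides = c(D2.Q4 = "no_information"),
                justifications = c(D2.Q4 = "Blinding not described"))),
    pilot)
  j <- judge_set(set, pilot)
  md <- render_report(set, j, pilot)
  expect_match(md, "## Methods")
  # exactly one per-study table
  expect_equal(lengths(regmatches(md, gregexpr("assessor A1", md))), 1L)
  # justification text passes through verbatim
  expect_match(md, "Blinding not described", fixed = TRUE)
  expect_no_match(md, "Inter-assessor agreement")

  # agreement section is conditional
  two <- rob_set(list(make_record(assessor = "A"),
                      make_record(assessor = "B")), pilot)
  j2 <- judge_set(two, pilot)
  agr <- compare_assessors(two, pilot, "A", "B")
  md2 <- render_report(two, j2, pilot, agreement = agr)
  expect_match(md2, "Inter-assessor agreement")

  # mismatched judgements are refused
  expect_error(render_report(two, j, pilot), "do not correspond")
})
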