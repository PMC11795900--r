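# Ordinal risk-of-bias scale; comparisons use this order.
RISK_LEVELS <- c("Low", "Some concerns", "High")

#' Risk-of-bias level
#'
#' Constructs the ordinal judgement scale `Low < Some concerns < High`.
#'
#' @param x Character vector over the three level names.
#' @return An ordered factor with levels `Low < Some concerns < High`.
#' @export
risk_level <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% RISK_LEVELS
  if (any(bad)) {
    stop("unknown risk level(s): ", paste(sQuote(unique(x[bad])),
                                          collapse = ", "), call. = FALSE)
  }
  factor(x, levels = RISK_LEVELS, ordered = TRUE)
}

#' Judge one domain from its answers
#'
#' Implements the count-based domain rule: with `k` the number of applicable
#' questions answered `no` or `no_information`, the domain is at `Low` risk
#' when `k = 0`, raises `Some concerns` when `k = 1`, and is at `High` risk
#' when `k >= 2` (thresholds configurable via `some_concerns_at` / `high_at`;
#' the published rule is 1/2). `no` and `no_information` are interchangeable
#' in effect and the answer order is irrelevant.
#'
#' @param answers Character vector of answers (`yes` / `no` /
#'   `no_information`, synonyms accepted) for the domain's applicable
#'   questions; must be non-empty — a domain with zero applicable questions
#'   cannot be judged.
#' @param some_concerns_at,high_at Rule thresholds,
#'   `1 <= some_concerns_at <= high_at`.
#' @return A length-1 ordered factor (see [risk_level()]).
#' @examples
#' judge_domain(c("yes", "yes", "yes", "yes", "yes"))      # Low
#' judge_domain(c("yes", "no", "yes", "yes", "yes"))       # Some concerns
#' judge_domain(c("no", "no_information", "yes", "yes"))   # High
#' @export
judge_domain <- function(answers, some_concerns_at = 1L, high_at = 2L) {
  if (length(answers) == 0L) {
    stop("cannot judge a domain with zero applicable questions",
         call. = FALSE)
  }
  some_concerns_at <- as.integer(some_concerns_at)
  high_at <- as.integer(high_at)
  if (is.na(some_concerns_at) || is.na(high_at) || some_concerns_at < 1L ||
      some_concerns_at > high_at) {
    stop("rule thresholds must satisfy 1 <= some_concerns_at <= high_at",
         call. = FALSE)
  }
  k <- sum(normalize_answers(answers) != "yes")
  level_from_count(k, some_concerns_at, high_at)
}

level_from_count <- function(k, some_concerns_at, high_at) {
  risk_level(ifelse(k >= high_at, "High",
                    ifelse(k >= some_concerns_at, "Some concerns", "Low")))
}

#' Combine domain judgements into the overall judgement
#'
#' The overall risk of bias is the highest domain judgement: high risk in
#' one or more domains makes the overall judgement `High`; all domains at
#' low risk make it `Low`; otherwise `Some concerns`.
#'
#' @param per_domain Non-empty vector of domain levels (character or
#'   [risk_level()]).
#' @return A length-1 ordered factor.
#' @export
judge_overall <- function(per_domain) {
  if (length(per_domain) == 0L) {
    stop("cannot judge overall risk from zero domain judgements",
         call. = FALSE)
  }
  lv <- risk_level(as.character(per_domain))
  if (anyNA(lv)) stop("missing domain level", call. = FALSE)
  max(lv)
}

#' Judge a single assessment record
#'
#' Applies the domain rule to each domain's applicable questions and the
#' overall (worst-domain) rule on top, after validating the record against
#' the instrument.
#'
#' @param record An [rob_record()].
#' @param instrument An [rob_instrument()].
#' @return An object of class `rob_judgement`: a list with the record
#'   identifiers, `per_domain` (named ordered factor), `overall` (ordered
#'   factor), and `non_yes_counts` (named integer vector of non-`yes`
#'   answers among each domain's applicable questions).
#' @export
judge_record <- function(record, instrument) {
  validate_record(record, instrument, strict = TRUE)
  qt <- applicable_questions(instrument, record$design)
  empty <- setdiff(vapply(instrument$domains, `[[`, character(1),
                          "domain_id"),
                   unique(qt$domain_id))
  if (length(empty)) {
    stop("domain(s) ", paste(empty, collapse = ", "),
         " have zero applicable questions under the ", record$design,
         " design and cannot be judged", call. = FALSE)
  }
  per_domain <- vapply(instrument$domains, function(d) {
    ids <- qt$question_id[qt$domain_id == d$domain_id]
    as.character(judge_domain(record$answers[ids],
                              d$rule$some_concerns_at, d$rule$high_at))
  }, character(1))
  names(per_domain) <- vapply(instrument$domains, `[[`, character(1),
                              "domain_id")
  counts <- vapply(instrument$domains, function(d) {
    ids <- qt$question_id[qt$domain_id == d$domain_id]
    sum(record$answers[ids] != "yes")
  }, integer(1))
  names(counts) <- names(per_domain)
  structure(
    list(study_id = record$study_id, outcome_id = record$outcome_id,
         assessor_id = record$assessor_id, design = record$design,
         per_domain = stats::setNames(risk_level(per_domain),
                                      names(per_domain)),
         overall = judge_overall(per_domain),
         non_yes_counts = counts),
    class = "rob_judgement"
  )
}

#' @export
print.rob_judgement <- function(x, ...) {
  cat("<rob_judgement> ", x$study_id, " / ", x$outcome_id, " / ",
      x$assessor_id, " (", x$design, ")\n", sep = "")
  for (d in names(x$per_domain)) {
    cat("  ", d, ": ", as.character(x$per_domain[d]),
        " (", x$non_yes_counts[d], " non-yes)\n", sep = "")
  }
  cat("  Overall: ", as.character(x$overall), "\n", sep = "")
  invisible(x)
}

#' Judge every record in an assessment set
#'
#' Vectorized application of [judge_record()] semantics to a whole set.
#'
#' @param set An [rob_set()].
#' @param instrument An [rob_instrument()].
#' @return A data frame of class `rob_judgements` in long form: one row per
#'   record per domain plus an `"OVERALL"` row per record, with columns
#'   `study_id`, `outcome_id`, `assessor_id`, `design`, `domain_id`, `level`
#'   (ordered factor) and `non_yes_count` (for `"OVERALL"`, the total across
#'   applicable questions).
#' @export
judge_set <- function(set, instrument) {
  stopifnot(inherits(set, "rob_set"), inherits(instrument, "rob_instrument"))
  validate_set(set, instrument, strict = TRUE)
  if (nrow(set$data) == 0L) {
    stop("cannot judge an empty assessment set", call. = FALSE)
  }
  qt <- question_table(instrument)
  d <- dplyr::inner_join(set$data,
                         qt[, c("question_id", "domain_id",
                                "some_concerns_at", "high_at")],
                         by = "question_id")
  per_domain <- d |>
    dplyr::group_by(.data$study_id, .data$outcome_id, .data$assessor_id,
                    .data$design, .data$domain_id) |>
    dplyr::summarise(
      non_yes_count = sum(.data$answer != "yes"),
      level = as.character(level_from_count(non_yes_count,
                                            .data$some_concerns_at[1L],
                                            .data$high_at[1L])),
      .groups = "drop")
  overall <- per_domain |>
    dplyr::group_by(.data$study_id, .data$outcome_id, .data$assessor_id,
                    .data$design) |>
    dplyr::summarise(domain_id = "OVERALL",
                     level = as.character(judge_overall(.data$level)),
                     non_yes_count = sum(.data$non_yes_count),
                     .groups = "drop")
  out <- as.data.frame(dplyr::bind_rows(per_domain, overall))
  # stable layout: units sorted, domains in id order, OVERALL last
  out <- out[order(out$study_id, out$outcome_id, out$assessor_id,
                   out$domain_id == "OVERALL", out$domain_id), ]
  out <- out[, c("study_id", "outcome_id", "assessor_id", "design",
                 "domain_id", "level", "non_yes_count")]
  out$level <- risk_level(out$level)
  rownames(out) <- NULL
  class(out) <- c("rob_judgements", "data.frame")
  out
}

#' Export judgements to CSV or JSON
#'
#' @param judgements An `rob_judgements` data frame from [judge_set()].
#' @param path Optional output path; when `NULL` the text is returned.
#' @param format `"csv"` or `"json"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_judgements <- function(judgements, path = NULL,
                             format = c("csv", "json")) {
  stopifnot(inherits(judgements, "data.frame"))
  format <- match.arg(format)
  df <- as.data.frame(judgements)
  df$level <- as.character(df$level)
  if (format == "csv") {
    con <- textConnection("csvout", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
    txt <- paste(csvout, collapse = "\n")
  } else {
    txt <- as.character(jsonlite::toJSON(df, dataframe = "rows",
                                         pretty = TRUE))
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Distribution of domain judgements over all answer vectors
#'
#' Enumerates every `3^n` vector of answers to `n` questions, judges each
#' with [judge_domain()], and tabulates the resulting levels. Useful as a
#' brute-force oracle for the rule: under the default thresholds the counts
#' have the closed form `Low = 1`, `Some concerns = 2n`,
#' `High = 3^n - 1 - 2n`.
#'
#' @param n_questions Number of questions (1..10).
#' @param some_concerns_at,high_at Rule thresholds.
#' @return Named integer vector with elements `Low`, `Some concerns`,
#'   `High`, summing to `3^n_questions`.
#' @export
enumerate_rule_distribution <- function(n_questions, some_concerns_at = 1L,
                                        high_at = 2L) {
  vecs <- exhaustive_domain_vectors(n_questions)
  lv <- apply(vecs, 1L, function(a)
    as.character(judge_domain(a, some_concerns_at, high_at)))
  counts <- table(factor(lv, levels = RISK_LEVELS))
  stats::setNames(as.integer(counts), RISK_LEVELS)
}
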