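# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Answer-generating model for synthetic assessments
#'
#' Answers are drawn independently per question from a categorical
#' distribution over `yes` / `no` / `no_information`. Real assessments
#' correlate across questions of a study; this independence is a deliberate
#' modelling simplification for testing and calibration.
#'
#' @param p_yes,p_no,p_no_information Global answer probabilities; must be
#'   nonnegative and sum to 1 (within 1e-12).
#' @param design_mix Proportion of records assessed under the uncontrolled
#'   design (0 = all controlled).
#' @param per_question Optional named list of per-question probability
#'   overrides, each a numeric vector `c(p_yes, p_no, p_no_information)`.
#' @return An object of class `rob_answer_model`.
#' @export
answer_model <- function(p_yes = 0.8, p_no = 0.1, p_no_information = 0.1,
                         design_mix = 0, per_question = NULL) {
  check_probs <- function(p, what) {
    if (length(p) != 3L || anyNA(p) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-12) {
      stop(what, ": probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
    p
  }
  check_probs(c(p_yes, p_no, p_no_information), "answer model")
  if (!is.numeric(design_mix) || length(design_mix) != 1L ||
      is.na(design_mix) || design_mix < 0 || design_mix > 1) {
    stop("design_mix must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(per_question)) {
    if (is.null(names(per_question)) || !all(nzchar(names(per_question)))) {
      stop("per_question overrides must be named by question_id",
           call. = FALSE)
    }
    for (q in names(per_question)) {
      check_probs(per_question[[q]], paste0("per_question['", q, "']"))
    }
  }
  structure(
    list(p = c(yes = p_yes, no = p_no, no_information = p_no_information),
         design_mix = design_mix, per_question = per_question,
         generator = "base R Mersenne-Twister (set.seed)"),
    class = "rob_answer_model"
  )
}

#' Simulate a synthetic assessment set
#'
#' Generates complete, valid assessment records for
#' `n_studies x outcomes_per_study x length(assessors)` units, drawing every
#' answer independently from `model`. Each study x outcome unit is assigned
#' one design (uncontrolled with probability `model$design_mix`), shared by
#' all assessors of that unit so that dual-assessor comparisons are
#' well-defined.
#'
#' @param instrument An [rob_instrument()].
#' @param n_studies Number of studies (>= 1).
#' @param outcomes_per_study Outcomes assessed per study.
#' @param assessors Character vector of assessor ids.
#' @param model An [answer_model()].
#' @param seed Integer seed; identical inputs and seed give identical sets.
#' @return An [rob_set()] that validates against `instrument`.
#' @export
simulate_assessments <- function(instrument, n_studies,
                                 outcomes_per_study = 1L,
                                 assessors = "A1",
                                 model = answer_model(),
                                 seed = 1L) {
  stopifnot(inherits(instrument, "rob_instrument"),
            inherits(model, "rob_answer_model"))
  n_studies <- as.integer(n_studies)
  outcomes_per_study <- as.integer(outcomes_per_study)
  if (is.na(n_studies) || n_studies < 1L) {
    stop("n_studies must be >= 1", call. = FALSE)
  }
  if (is.na(outcomes_per_study) || outcomes_per_study < 1L) {
    stop("outcomes_per_study must be >= 1", call. = FALSE)
  }
  stopifnot(is.character(assessors), length(assessors) >= 1L)
  qt <- question_table(instrument)

  with_seed(seed, {
    pad <- function(i, n) formatC(i, width = nchar(n), flag = "0")
    units <- expand.grid(outcome = seq_len(outcomes_per_study),
                         study = seq_len(n_studies))[, c("study", "outcome")]
    units$study_id <- paste0("S", pad(units$study, n_studies))
    units$outcome_id <- paste0("O", pad(units$outcome, outcomes_per_study))
    units$design <- ifelse(stats::runif(nrow(units)) < model$design_mix,
                           "uncontrolled", "controlled")
    rows <- lapply(seq_len(nrow(units)), function(i) {
      u <- units[i, ]
      qs <- if (u$design == "uncontrolled") qt[!qt$controlled_only, ] else qt
      do.call(rbind, lapply(assessors, function(a) {
        probs <- vapply(qs$question_id, function(qid) {
          ov <- model$per_question[[qid]]
          if (is.null(ov)) model$p else ov
        }, numeric(3))
        ans <- vapply(seq_len(nrow(qs)), function(j)
          sample(ANSWER_LEVELS, 1L, prob = probs[, j]), character(1))
        data.frame(study_id = u$study_id, outcome_id = u$outcome_id,
                   assessor_id = a, design = u$design,
                   question_id = qs$question_id, answer = ans,
                   justification = NA_character_, stringsAsFactors = FALSE)
      }))
    })
    rob_set(do.call(rbind, rows), instrument)
  })
}

#' All answer vectors for a domain of n questions
#'
#' Enumerates the full answer space `{yes, no, no_information}^n` in a
#' deterministic (odometer) order. Guarded to `n <= 10` (3^10 = 59049 rows).
#'
#' @param n_questions Number of questions, 1..10.
#' @return A character matrix with `3^n_questions` rows and `n_questions`
#'   columns.
#' @export
exhaustive_domain_vectors <- function(n_questions) {
  n_questions <- as.integer(n_questions)
  if (is.na(n_questions) || n_questions < 1L || n_questions > 10L) {
    stop("n_questions must be an integer in 1..10", call. = FALSE)
  }
  grid <- expand.grid(rep(list(ANSWER_LEVELS), n_questions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, paste0("Q", seq_len(n_questions)))
  m
}

#' Randomly flip answers to create controlled disagreement
#'
#' Each answer is independently replaced, with probability
#' `flip_probability`, by one of the two other answer values chosen
#' uniformly. `flip_probability = 0` is the identity; `1` changes every
#' answer. Useful for constructing dual-assessor disagreement patterns with
#' a known rate.
#'
#' @param set An [rob_set()].
#' @param flip_probability Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An [rob_set()] with the same structure and possibly different
#'   answers.
#' @export
perturb_assessments <- function(set, flip_probability, seed = 1L) {
  stopifnot(inherits(set, "rob_set"))
  if (!is.numeric(flip_probability) || length(flip_probability) != 1L ||
      is.na(flip_probability) || flip_probability < 0 ||
      flip_probability > 1) {
    stop("flip_probability must be a probability in [0, 1]", call. = FALSE)
  }
  out <- set
  with_seed(seed, {
    n <- nrow(out$data)
    flip <- stats::runif(n) < flip_probability
    if (any(flip)) {
      out$data$answer[flip] <- vapply(out$data$answer[flip], function(a)
        sample(setdiff(ANSWER_LEVELS, a), 1L), character(1),
        USE.NAMES = FALSE)
    }
  })
  out
}
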