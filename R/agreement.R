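#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with the
#' expected agreement `p_e` computed from the two raters' marginal category
#' distributions. For ordinal scales, `weights = "linear"` (or
#' `"quadratic"`) credits partial agreement:
#' `kappa_w = 1 - sum(v * p) / sum(v * e)` with disagreement weights
#' `v_ij = |i - j|` (linear) or `(i - j)^2` (quadratic).
#'
#' When both raters are constant (`p_e = 1`), kappa is undefined (0/0); it
#' is reported as `NA` with `defined = FALSE` and the observed agreement
#' still carries the information (1 if the constants coincide).
#'
#' @param a,b Equal-length vectors of ratings on the same categorical scale.
#' @param levels Category levels in (ordinal) order; defaults to the risk
#'   scale `Low < Some concerns < High`.
#' @param weights `"none"` (classic kappa), `"linear"`, or `"quadratic"`.
#' @return A list with `kappa`, `p_observed`, `p_expected`, `defined`, and
#'   `n`.
#' @export
cohen_kappa <- function(a, b, levels = RISK_LEVELS,
                        weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  a <- factor(as.character(a), levels = levels)
  b <- factor(as.character(b), levels = levels)
  if (length(a) != length(b)) stop("ratings differ in length", call. = FALSE)
  if (length(a) == 0L) stop("no ratings to compare", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("ratings outside the scale", call. = FALSE)
  k <- length(levels)
  p <- table(a, b) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  e <- outer(pa, pb)
  idx <- seq_len(k) - 1L
  v <- switch(weights,
              none = 1 - diag(k),
              linear = abs(outer(idx, idx, "-")),
              quadratic = outer(idx, idx, "-")^2)
  obs_dis <- sum(v * p)
  exp_dis <- sum(v * e)
  p_o <- sum(diag(p))
  p_e <- sum(diag(e))
  if (exp_dis <= .Machine$double.eps) {
    return(list(kappa = NA_real_, p_observed = p_o, p_expected = p_e,
                defined = FALSE, n = length(a)))
  }
  list(kappa = 1 - obs_dis / exp_dis, p_observed = p_o, p_expected = p_e,
       defined = TRUE, n = length(a))
}

#' Compare two assessors' independent applications of the tool
#'
#' Mirrors the dual-assessor workflow in which two researchers apply the
#' instrument independently to the same studies. Agreement is computed over
#' the study x outcome units both assessors rated, at three granularities:
#' per signalling question (raw answers), per domain (judged levels), and
#' overall (judged levels), plus Cohen's kappa (unweighted and weighted) on
#' the overall levels. Question-level disagreement can vanish at domain
#' level under the counting rule, which is why all three are reported.
#'
#' @param set An [rob_set()] containing records from both assessors.
#' @param instrument An [rob_instrument()].
#' @param assessor_a,assessor_b Assessor ids to compare.
#' @param weights Weighting for the ordinal kappa (`"linear"` default,
#'   `"quadratic"` available).
#' @return An object of class `rob_agreement`: a list with `n_units`,
#'   `question_agreement`, `domain_agreement`, `overall_agreement`,
#'   `kappa_overall`, `kappa_weighted` (each as returned by
#'   [cohen_kappa()]), and a `disagreements` data frame (columns
#'   `study_id`, `outcome_id`, `granularity`, `item_id`, `value_a`,
#'   `value_b`).
#' @export
compare_assessors <- function(set, instrument, assessor_a, assessor_b,
                              weights = c("linear", "quadratic")) {
  stopifnot(inherits(set, "rob_set"), inherits(instrument, "rob_instrument"))
  weights <- match.arg(weights)
  d <- set$data
  da <- d[d$assessor_id == assessor_a, , drop = FALSE]
  db <- d[d$assessor_id == assessor_b, , drop = FALSE]
  units_a <- unique(da[, c("study_id", "outcome_id", "design")])
  units_b <- unique(db[, c("study_id", "outcome_id", "design")])
  common <- merge(units_a[, 1:2], units_b[, 1:2])
  if (nrow(common) == 0L) {
    stop("assessors ", assessor_a, " and ", assessor_b,
         " share no study x outcome units", call. = FALSE)
  }
  common <- merge(common, stats::setNames(units_a, c("study_id", "outcome_id",
                                                     "design_a")))
  common <- merge(common, stats::setNames(units_b, c("study_id", "outcome_id",
                                                     "design_b")))
  mism <- common[common$design_a != common$design_b, , drop = FALSE]
  if (nrow(mism) > 0L) {
    stop("design mismatch between assessors on unit(s): ",
         paste(paste0("(", mism$study_id, ", ", mism$outcome_id, ")"),
               collapse = ", "), call. = FALSE)
  }
  common <- common[order(common$study_id, common$outcome_id), ]
  key <- function(x) paste(x$study_id, x$outcome_id, sep = "\r")
  in_common <- function(x) x[key(x) %in% key(common), , drop = FALSE]
  da <- in_common(da); db <- in_common(db)

  # question-level agreement on raw answers
  qa <- merge(da[, c("study_id", "outcome_id", "question_id", "answer")],
              db[, c("study_id", "outcome_id", "question_id", "answer")],
              by = c("study_id", "outcome_id", "question_id"),
              suffixes = c("_a", "_b"))
  question_agreement <- tapply(qa$answer_a == qa$answer_b, qa$question_id,
                               mean)
  question_agreement <- stats::setNames(as.numeric(question_agreement),
                                        names(question_agreement))

  # domain/overall agreement on judged levels
  sub <- new_rob_set(rbind(da, db), set$instrument_id, set$version)
  j <- judge_set(sub, instrument)
  ja <- j[j$assessor_id == assessor_a, , drop = FALSE]
  jb <- j[j$assessor_id == assessor_b, , drop = FALSE]
  jj <- merge(as.data.frame(ja)[, c("study_id", "outcome_id", "domain_id",
                                    "level")],
              as.data.frame(jb)[, c("study_id", "outcome_id", "domain_id",
                                    "level")],
              by = c("study_id", "outcome_id", "domain_id"),
              suffixes = c("_a", "_b"))
  jj$level_a <- as.character(jj$level_a)
  jj$level_b <- as.character(jj$level_b)
  dom <- jj[jj$domain_id != "OVERALL", , drop = FALSE]
  domain_agreement <- tapply(dom$level_a == dom$level_b, dom$domain_id, mean)
  domain_agreement <- stats::setNames(as.numeric(domain_agreement),
                                      names(domain_agreement))
  ov <- jj[jj$domain_id == "OVERALL", , drop = FALSE]
  ov <- ov[order(ov$study_id, ov$outcome_id), ]
  overall_agreement <- mean(ov$level_a == ov$level_b)
  kappa_overall <- cohen_kappa(ov$level_a, ov$level_b, weights = "none")
  kappa_weighted <- cohen_kappa(ov$level_a, ov$level_b, weights = weights)

  disag_q <- qa[qa$answer_a != qa$answer_b, , drop = FALSE]
  disag_j <- jj[jj$level_a != jj$level_b, , drop = FALSE]
  disagreements <- rbind(
    if (nrow(disag_q)) data.frame(
      study_id = disag_q$study_id, outcome_id = disag_q$outcome_id,
      granularity = "question", item_id = disag_q$question_id,
      value_a = disag_q$answer_a, value_b = disag_q$answer_b,
      stringsAsFactors = FALSE),
    if (nrow(disag_j)) data.frame(
      study_id = disag_j$study_id, outcome_id = disag_j$outcome_id,
      granularity = ifelse(disag_j$domain_id == "OVERALL", "overall",
                           "domain"),
      item_id = disag_j$domain_id,
      value_a = disag_j$level_a, value_b = disag_j$level_b,
      stringsAsFactors = FALSE),
    data.frame(study_id = character(), outcome_id = character(),
               granularity = character(), item_id = character(),
               value_a = character(), value_b = character(),
               stringsAsFactors = FALSE)
  )
  rownames(disagreements) <- NULL
  structure(
    list(assessor_a = assessor_a, assessor_b = assessor_b,
         n_units = nrow(common),
         question_agreement = question_agreement,
         domain_agreement = domain_agreement,
         overall_agreement = overall_agreement,
         kappa_overall = kappa_overall,
         kappa_weighted = kappa_weighted,
         weights = weights,
         disagreements = disagreements),
    class = "rob_agreement"
  )
}

fmt_kappa <- function(k) {
  if (k$defined) sprintf("%.3f", k$kappa)
  else sprintf("undefined (constant raters; observed agreement %.3f)",
               k$p_observed)
}

#' @export
print.rob_agreement <- function(x, ...) {
  cat("<rob_agreement> ", x$assessor_a, " vs ", x$assessor_b, " over ",
      x$n_units, " unit(s)\n", sep = "")
  cat("  overall-level agreement: ", sprintf("%.3f", x$overall_agreement),
      "\n", sep = "")
  cat("  kappa (unweighted):      ", fmt_kappa(x$kappa_overall), "\n",
      sep = "")
  cat("  kappa (", x$weights, "):", strrep(" ", 12 - nchar(x$weights)),
      fmt_kappa(x$kappa_weighted), "\n", sep = "")
  cat("  disagreements: ", nrow(x$disagreements), " (",
      sum(x$disagreements$granularity == "question"), " question-level)\n",
      sep = "")
  invisible(x)
}

#' Export an agreement report
#'
#' @param report An `rob_agreement` from [compare_assessors()].
#' @param path Optional output path; when `NULL` the text is returned.
#' @param format `"json"` (full report), `"text"` (human-readable summary),
#'   or `"csv"` (disagreement list only).
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_agreement <- function(report, path = NULL,
                            format = c("json", "text", "csv")) {
  stopifnot(inherits(report, "rob_agreement"))
  format <- match.arg(format)
  txt <- switch(format,
    json = as.character(jsonlite::toJSON(
      list(assessor_a = report$assessor_a, assessor_b = report$assessor_b,
           n_units = report$n_units,
           question_agreement = as.list(report$question_agreement),
           domain_agreement = as.list(report$domain_agreement),
           overall_agreement = report$overall_agreement,
           kappa_overall = report$kappa_overall,
           kappa_weighted = report$kappa_weighted,
           weights = report$weights,
           disagreements = report$disagreements),
      auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", na = "null")),
    text = paste(utils::capture.output(print(report)), collapse = "\n"),
    csv = {
      con <- textConnection("csvout", "w", local = TRUE)
      utils::write.csv(report$disagreements, con, row.names = FALSE)
      close(con)
      paste(csvout, collapse = "\n")
    })
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Merge two assessors' records into a consensus set
#'
#' Answers on which the assessors agree pass through; every disagreement
#' must be covered by a resolution row, otherwise an error lists all
#' unresolved (unit, question) pairs. The result carries a single assessor
#' id `"consensus"`.
#'
#' @param set An [rob_set()] with records from exactly two assessors on the
#'   compared units.
#' @param resolutions Data frame with columns `study_id`, `outcome_id`,
#'   `question_id`, `answer` giving the agreed answer for each disagreement
#'   (may have zero rows when there are none).
#' @param instrument An [rob_instrument()] (for validation of the result).
#' @return An [rob_set()] with `assessor_id = "consensus"`.
#' @export
consensus_merge <- function(set, resolutions, instrument) {
  stopifnot(inherits(set, "rob_set"), inherits(instrument, "rob_instrument"))
  if (missing(resolutions) || is.null(resolutions)) {
    resolutions <- data.frame(study_id = character(),
                              outcome_id = character(),
                              question_id = character(),
                              answer = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(resolutions),
            all(c("study_id", "outcome_id", "question_id", "answer") %in%
                  names(resolutions)))
  assessors <- unique(set$data$assessor_id)
  if (length(assessors) != 2L) {
    stop("consensus_merge needs a set with exactly two assessors, got ",
         length(assessors), call. = FALSE)
  }
  d <- set$data
  wide <- merge(
    d[d$assessor_id == assessors[1L],
      c("study_id", "outcome_id", "design", "question_id", "answer")],
    d[d$assessor_id == assessors[2L],
      c("study_id", "outcome_id", "question_id", "answer")],
    by = c("study_id", "outcome_id", "question_id"),
    suffixes = c("_a", "_b"))
  if (nrow(wide) == 0L) {
    stop("the two assessors share no answered questions", call. = FALSE)
  }
  res_key <- paste(resolutions$study_id, resolutions$outcome_id,
                   resolutions$question_id, sep = "\r")
  if (anyDuplicated(res_key)) {
    stop("duplicate resolution entries", call. = FALSE)
  }
  wide_key <- paste(wide$study_id, wide$outcome_id, wide$question_id,
                    sep = "\r")
  disag <- wide$answer_a != wide$answer_b
  unresolved <- disag & !(wide_key %in% res_key)
  if (any(unresolved)) {
    u <- wide[unresolved, , drop = FALSE]
    stop("unresolved disagreement(s): ",
         paste(paste0("(", u$study_id, ", ", u$outcome_id, ", ",
                      u$question_id, ")"), collapse = ", "), call. = FALSE)
  }
  answer <- wide$answer_a
  idx <- match(wide_key, res_key)
  take <- disag & !is.na(idx)
  answer[take] <- normalize_answers(resolutions$answer[idx[take]])
  out <- data.frame(study_id = wide$study_id, outcome_id = wide$outcome_id,
                    assessor_id = "consensus", design = wide$design,
                    question_id = wide$question_id, answer = answer,
                    justification = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$study_id, out$outcome_id, out$question_id), ]
  new_rob_set(out, set$instrument_id, set$version)
}
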