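# Canonical answer values; "no information" means the study reports nothing
# that lets the assessor answer yes or no.
ANSWER_LEVELS <- c("yes", "no", "no_information")

ASSESSMENT_COLUMNS <- c("study_id", "outcome_id", "assessor_id", "design",
                        "question_id", "answer", "justification")

#' Normalize answer tokens
#'
#' Matching is case-insensitive and tolerates surrounding whitespace; the
#' synonyms `"NI"` and `"no information"` map to `"no_information"`.
#'
#' @param x Character vector of raw answer tokens.
#' @return Character vector over `c("yes", "no", "no_information")`.
#' @export
normalize_answers <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  tok[tok %in% c("ni", "no information", "no_information")] <- "no_information"
  bad <- !is.na(tok) & !(tok %in% ANSWER_LEVELS)
  if (any(bad)) {
    stop("unrecognized answer token(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         " (expected yes / no / no_information)", call. = FALSE)
  }
  tok
}

new_rob_set <- function(data, instrument_id, version) {
  for (col in setdiff(ASSESSMENT_COLUMNS, names(data))) {
    data[[col]] <- if (col == "justification") NA_character_ else
      stop("assessment data lacks column '", col, "'", call. = FALSE)
  }
  data <- data[, ASSESSMENT_COLUMNS, drop = FALSE]
  data[] <- lapply(data, as.character)
  bad_design <- !data$design %in% DESIGNS
  if (any(bad_design)) {
    stop("invalid design value(s): ",
         paste(sQuote(unique(data$design[bad_design])), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(data$study_id, data$outcome_id, data$assessor_id,
               data$question_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate assessment row for (", d$study_id, ", ", d$outcome_id,
         ", ", d$assessor_id, ", ", d$question_id, ")", call. = FALSE)
  }
  unit <- paste(data$study_id, data$outcome_id, data$assessor_id, sep = "\r")
  mixed <- tapply(data$design, unit, function(d) length(unique(d)) > 1L)
  if (any(mixed)) {
    u <- strsplit(names(mixed)[which(mixed)[1L]], "\r", fixed = TRUE)[[1L]]
    stop("record (", u[1L], ", ", u[2L], ", ", u[3L],
         ") mixes controlled and uncontrolled designs", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(
    list(instrument_id = instrument_id, version = version, data = data),
    class = "rob_set"
  )
}

#' Assessment record for one study x outcome x assessor
#'
#' One assessor's complete set of answers for one outcome of one study,
#' appraised under a stated design. Answers must cover exactly the questions
#' applicable under that design (see [applicable_questions()]); inapplicable
#' questions are absent, never stored as a fourth answer value.
#'
#' @param study_id,outcome_id,assessor_id Identifiers.
#' @param design `"controlled"` or `"uncontrolled"`.
#' @param answers Named character vector, `question_id -> answer token`
#'   (tokens normalized via [normalize_answers()]).
#' @param justifications Optional named character vector,
#'   `question_id -> free-text justification`.
#' @return An object of class `rob_record`.
#' @export
rob_record <- function(study_id, outcome_id, assessor_id, design, answers,
                       justifications = NULL) {
  design <- match.arg(design, DESIGNS)
  if (is.null(names(answers)) || any(!nzchar(names(answers)))) {
    stop("'answers' must be named by question_id", call. = FALSE)
  }
  if (anyDuplicated(names(answers))) {
    stop("duplicate question_id in 'answers': ",
         paste(unique(names(answers)[duplicated(names(answers))]),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id),
         outcome_id = as.character(outcome_id),
         assessor_id = as.character(assessor_id),
         design = design,
         answers = stats::setNames(normalize_answers(answers), names(answers)),
         justifications = justifications),
    class = "rob_record"
  )
}

record_to_data <- function(r) {
  just <- rep(NA_character_, length(r$answers))
  if (!is.null(r$justifications)) {
    idx <- match(names(r$answers), names(r$justifications))
    just <- ifelse(is.na(idx), NA_character_,
                   as.character(r$justifications)[idx])
  }
  data.frame(study_id = r$study_id, outcome_id = r$outcome_id,
             assessor_id = r$assessor_id, design = r$design,
             question_id = names(r$answers), answer = unname(r$answers),
             justification = just, stringsAsFactors = FALSE)
}

#' Assessment set: a collection of records against one instrument
#'
#' @param records List of [rob_record()] objects (or a long-format data frame
#'   with the columns `study_id`, `outcome_id`, `assessor_id`, `design`,
#'   `question_id`, `answer`, and optionally `justification`).
#' @param instrument The [rob_instrument()] the records reference (used for
#'   its id/version stamp).
#' @return An object of class `rob_set`.
#' @export
rob_set <- function(records, instrument) {
  stopifnot(inherits(instrument, "rob_instrument"))
  if (is.data.frame(records)) {
    data <- records
    data$answer <- normalize_answers(data$answer)
  } else {
    ok <- vapply(records, inherits, logical(1), "rob_record")
    if (!all(ok)) stop("'records' must be rob_record objects", call. = FALSE)
    data <- do.call(rbind, lapply(records, record_to_data))
    if (is.null(data)) {
      data <- data.frame(study_id = character(), outcome_id = character(),
                         assessor_id = character(), design = character(),
                         question_id = character(), answer = character(),
                         justification = character(),
                         stringsAsFactors = FALSE)
    }
  }
  new_rob_set(data, instrument$instrument_id, instrument$version)
}

#' @export
print.rob_set <- function(x, ...) {
  u <- unique(x$data[, c("study_id", "outcome_id", "assessor_id")])
  cat("<rob_set> instrument ", x$instrument_id, " v", x$version, ": ",
      nrow(u), " record(s), ", nrow(x$data), " answers\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rob_set <- function(x, ...) x$data

#' Split an assessment set into records
#'
#' @param set An [rob_set()].
#' @return A list of [rob_record()] objects, ordered by study, outcome,
#'   assessor.
#' @export
set_records <- function(set) {
  stopifnot(inherits(set, "rob_set"))
  d <- set$data
  if (nrow(d) == 0L) return(list())
  key <- paste(d$study_id, d$outcome_id, d$assessor_id, sep = "\r")
  lapply(split(d, factor(key, levels = unique(key))), function(g) {
    just <- stats::setNames(g$justification, g$question_id)
    if (all(is.na(just))) just <- NULL
    rob_record(g$study_id[1L], g$outcome_id[1L], g$assessor_id[1L],
               g$design[1L],
               stats::setNames(g$answer, g$question_id),
               justifications = just)
  }) |> unname()
}

#' Validate a record (or a whole set) against an instrument
#'
#' A record is valid iff its answers cover exactly the questions applicable
#' under its design: no missing answers, no unknown question ids, no answers
#' to questions inapplicable under the design. Problems are returned as
#' findings, never thrown, unless `strict = TRUE`.
#'
#' @param record An [rob_record()].
#' @param instrument The [rob_instrument()] to validate against.
#' @param strict If `TRUE`, any finding is escalated to an error.
#' @return A data frame of findings with columns `finding`
#'   (`missing-answer`, `unknown-question`, `inapplicable-question-answered`),
#'   `question_id` and `message`; zero rows means the record is valid.
#' @export
validate_record <- function(record, instrument, strict = FALSE) {
  stopifnot(inherits(record, "rob_record"),
            inherits(instrument, "rob_instrument"))
  findings <- validate_answers(names(record$answers), record$design,
                               instrument)
  if (strict && nrow(findings) > 0L) {
    stop("invalid record (", record$study_id, ", ", record$outcome_id, ", ",
         record$assessor_id, "): ",
         paste(findings$message, collapse = "; "), call. = FALSE)
  }
  findings
}

validate_answers <- function(answered_ids, design, instrument) {
  applicable <- applicable_questions(instrument, design)$question_id
  all_ids <- question_table(instrument)$question_id
  missing <- setdiff(applicable, answered_ids)
  unknown <- setdiff(answered_ids, all_ids)
  inapplicable <- intersect(setdiff(answered_ids, applicable), all_ids)
  rbind(
    if (length(missing)) data.frame(
      finding = "missing-answer", question_id = missing,
      message = paste0("no answer for applicable question ", missing)),
    if (length(unknown)) data.frame(
      finding = "unknown-question", question_id = unknown,
      message = paste0("answer for unknown question ", unknown)),
    if (length(inapplicable)) data.frame(
      finding = "inapplicable-question-answered", question_id = inapplicable,
      message = paste0("answer for question ", inapplicable,
                       " inapplicable under ", design, " design")),
    data.frame(finding = character(), question_id = character(),
               message = character(), stringsAsFactors = FALSE)
  )
}

#' @rdname validate_record
#' @param set An [rob_set()].
#' @return For `validate_set()`: a findings data frame with additional
#'   `study_id`, `outcome_id`, `assessor_id` columns.
#' @export
validate_set <- function(set, instrument, strict = FALSE) {
  stopifnot(inherits(set, "rob_set"), inherits(instrument, "rob_instrument"))
  d <- set$data
  key <- paste(d$study_id, d$outcome_id, d$assessor_id, sep = "\r")
  groups <- split(d, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(g) {
    f <- validate_answers(g$question_id, g$design[1L], instrument)
    if (nrow(f) == 0L) return(NULL)
    cbind(data.frame(study_id = g$study_id[1L], outcome_id = g$outcome_id[1L],
                     assessor_id = g$assessor_id[1L],
                     stringsAsFactors = FALSE)[rep(1L, nrow(f)), ,
                                               drop = FALSE],
          f, row.names = NULL)
  }))
  if (is.null(out)) {
    out <- data.frame(study_id = character(), outcome_id = character(),
                      assessor_id = character(), finding = character(),
                      question_id = character(), message = character(),
                      stringsAsFactors = FALSE)
  }
  if (strict && nrow(out) > 0L) {
    stop("assessment set failed validation with ", nrow(out),
         " finding(s):\n  ",
         paste(paste0("(", out$study_id, ", ", out$outcome_id, ", ",
                      out$assessor_id, ") ", out$message),
               collapse = "\n  "), call. = FALSE)
  }
  out
}

# ---- file I/O ------------------------------------------------------------

#' Read assessment records from long-format CSV or nested JSON
#'
#' The CSV dialect is one row per study x outcome x assessor x question with
#' the header `study_id, outcome_id, assessor_id, design, question_id,
#' answer, justification` (justification optional). The JSON dialect nests
#' `records -> answers` under an `instrument_ref`. Answer tokens are matched
#' case-insensitively with the synonyms accepted by [normalize_answers()].
#'
#' @param path Path to a `.csv` or `.json` file, or literal content.
#' @param instrument The [rob_instrument()] the records reference.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @param strict If `TRUE` (default) the set must validate completely against
#'   the instrument; with `FALSE`, structural errors (bad tokens, duplicate
#'   rows) still throw but completeness findings are tolerated.
#' @return An [rob_set()].
#' @export
read_assessments <- function(path, instrument,
                             format = c("auto", "csv", "json"),
                             strict = TRUE) {
  stopifnot(inherits(instrument, "rob_instrument"))
  format <- match.arg(format)
  is_file <- length(path) == 1L && !grepl("\n", path) && file.exists(path)
  if (format == "auto") {
    format <- if (is_file && grepl("\\.json$", path, ignore.case = TRUE))
      "json"
    else if (!is_file && grepl("^\\s*[{[]", path)) "json"
    else "csv"
  }
  if (format == "csv") {
    con <- if (is_file) path else textConnection(path)
    df <- utils::read.csv(con, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- setdiff(ASSESSMENT_COLUMNS, "justification")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("assessment CSV lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!"justification" %in% names(df)) df$justification <- NA_character_
    df$justification[!nzchar(trimws(df$justification))] <- NA_character_
    df$answer <- check_tokens_with_rows(df$answer)
    set <- new_rob_set(df, instrument$instrument_id, instrument$version)
  } else {
    raw <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n")
           else paste(path, collapse = "\n")
    lst <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                    error = function(e)
                      stop("assessment JSON failed to parse: ",
                           conditionMessage(e), call. = FALSE))
    recs <- lapply(lst$records, function(r) {
      answers <- vapply(r$answers, function(a) as.character(a), character(1))
      just <- if (!is.null(r$justifications) && length(r$justifications))
        vapply(r$justifications, as.character, character(1)) else NULL
      rob_record(r$study_id, r$outcome_id, r$assessor_id, r$design,
                 answers, justifications = just)
    })
    set <- rob_set(recs, instrument)
    if (!is.null(lst$instrument_ref$instrument_id)) {
      set$instrument_id <- lst$instrument_ref$instrument_id
      set$version <- as.character(lst$instrument_ref$version)
    }
  }
  if (strict) validate_set(set, instrument, strict = TRUE)
  set
}

check_tokens_with_rows <- function(tokens) {
  out <- tryCatch(normalize_answers(tokens), error = function(e) e)
  if (!inherits(out, "error")) return(out)
  norm <- tolower(trimws(tokens))
  norm[norm %in% c("ni", "no information", "no_information")] <-
    "no_information"
  bad <- which(!norm %in% ANSWER_LEVELS)
  stop("unparseable answer token ", sQuote(tokens[bad[1L]]),
       " in data row ", bad[1L],
       if (length(bad) > 1L) paste0(" (and ", length(bad) - 1L,
                                    " further row(s))"),
       call. = FALSE)
}

#' Write an assessment set to CSV or JSON
#'
#' `read_assessments(write_assessments(s), instrument)` reproduces `s`
#' exactly, for both dialects; justification text containing delimiters or
#' newlines is quoted safely by the CSV writer.
#'
#' @param set An [rob_set()].
#' @param path Optional output path; when `NULL` the serialized text is
#'   returned.
#' @param format `"csv"` (long format) or `"json"` (nested).
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_assessments <- function(set, path = NULL, format = c("csv", "json")) {
  stopifnot(inherits(set, "rob_set"))
  format <- match.arg(format)
  if (format == "csv") {
    con <- textConnection("csvout", "w", local = TRUE)
    utils::write.csv(set$data, con, row.names = FALSE, na = "")
    close(con)
    txt <- paste(csvout, collapse = "\n")
  } else {
    recs <- lapply(set_records(set), function(r) {
      out <- list(study_id = r$study_id, outcome_id = r$outcome_id,
                  assessor_id = r$assessor_id, design = r$design,
                  answers = as.list(r$answers))
      if (!is.null(r$justifications)) {
        j <- r$justifications[!is.na(r$justifications)]
        if (length(j)) out$justifications <- as.list(j)
      }
      out
    })
    txt <- as.character(jsonlite::toJSON(
      list(instrument_ref = list(instrument_id = set$instrument_id,
                                 version = set$version),
           records = recs),
      auto_unbox = TRUE, pretty = TRUE, na = "null"))
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
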