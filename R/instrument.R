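#' @keywords internal
#' @importFrom dplyr .data
"_PACKAGE"

# Study designs an instrument can be applied under.
DESIGNS <- c("controlled", "uncontrolled")

#' Signalling question constructor
#'
#' A signalling question elicits information about one bias mechanism and is
#' answered `yes` / `no` / `no_information`. Questions that reference a
#' comparison group carry `controlled_only = TRUE` and are omitted when a
#' single-arm (uncontrolled) study is appraised.
#'
#' @param question_id Identifier, unique within an instrument. Canonical form
#'   is `"D<domain>.Q<ordinal>"`, e.g. `"D1.Q3"`.
#' @param text Full question wording (non-empty).
#' @param guidance Explanatory text telling the assessor how to interpret and
#'   answer the question (non-empty).
#' @param controlled_only Logical; omit this question for uncontrolled designs?
#' @param note Optional free-text annotation (metadata only, no behavioural
#'   effect).
#' @return An object of class `rob_question`.
#' @export
rob_question <- function(question_id, text, guidance, controlled_only = FALSE,
                         note = NULL) {
  stopifnot(is.character(question_id), length(question_id) == 1L)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("question ", question_id, ": 'text' must be a non-empty string",
         call. = FALSE)
  }
  if (!is.character(guidance) || length(guidance) != 1L ||
      !nzchar(trimws(guidance))) {
    stop("question ", question_id, ": 'guidance' must be a non-empty string",
         call. = FALSE)
  }
  stopifnot(is.logical(controlled_only), length(controlled_only) == 1L,
            !is.na(controlled_only))
  structure(
    list(question_id = question_id, text = text, guidance = guidance,
         controlled_only = controlled_only, note = note),
    class = "rob_question"
  )
}

#' Bias domain constructor
#'
#' A domain groups the signalling questions addressing one mechanism by which
#' bias can enter a study, together with the thresholds of the count-based
#' judgement rule: with `k` the number of applicable questions answered `no`
#' or `no_information`, the domain is at low risk if `k < some_concerns_at`,
#' raises some concerns if `some_concerns_at <= k < high_at`, and is at high
#' risk if `k >= high_at`. The defaults (1, 2) encode the published rule:
#' all-yes is low risk, exactly one non-yes raises some concerns, more than
#' one is high risk.
#'
#' @param domain_id Identifier, e.g. `"D1"`.
#' @param name Domain title.
#' @param questions List of [rob_question()] objects, in presentation order.
#' @param some_concerns_at,high_at Integer thresholds of the judgement rule;
#'   must satisfy `1 <= some_concerns_at <= high_at`.
#' @return An object of class `rob_domain`.
#' @export
rob_domain <- function(domain_id, name, questions,
                       some_concerns_at = 1L, high_at = 2L) {
  stopifnot(is.character(domain_id), length(domain_id) == 1L,
            is.character(name), length(name) == 1L)
  if (!is.list(questions) || length(questions) == 0L) {
    stop("domain ", domain_id, ": needs at least one question", call. = FALSE)
  }
  ok <- vapply(questions, inherits, logical(1), what = "rob_question")
  if (!all(ok)) stop("domain ", domain_id,
                     ": 'questions' must all be rob_question objects",
                     call. = FALSE)
  some_concerns_at <- as.integer(some_concerns_at)
  high_at <- as.integer(high_at)
  if (is.na(some_concerns_at) || is.na(high_at) ||
      some_concerns_at < 1L || some_concerns_at > high_at) {
    stop("domain ", domain_id,
         ": rule thresholds must satisfy 1 <= some_concerns_at <= high_at",
         call. = FALSE)
  }
  structure(
    list(domain_id = domain_id, name = name, questions = questions,
         rule = list(some_concerns_at = some_concerns_at, high_at = high_at)),
    class = "rob_domain"
  )
}

#' Appraisal instrument constructor
#'
#' @param instrument_id Short identifier for the instrument.
#' @param version Version string.
#' @param domains List of [rob_domain()] objects in presentation order.
#' @param provenance Free-text citation of where the instrument comes from.
#' @return An object of class `rob_instrument`.
#' @seealso [pilot_lab_tool()] for the bundled instrument,
#'   [read_instrument()] / [write_instrument()] for (de)serialization.
#' @export
rob_instrument <- function(instrument_id, version, domains, provenance = "") {
  stopifnot(is.character(instrument_id), length(instrument_id) == 1L,
            is.character(version), length(version) == 1L)
  if (!is.list(domains) || length(domains) == 0L) {
    stop("an instrument needs at least one domain", call. = FALSE)
  }
  ok <- vapply(domains, inherits, logical(1), what = "rob_domain")
  if (!all(ok)) stop("'domains' must all be rob_domain objects", call. = FALSE)
  ids <- unlist(lapply(domains, function(d)
    vapply(d$questions, `[[`, character(1), "question_id")))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate question_id in instrument: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  did <- vapply(domains, `[[`, character(1), "domain_id")
  if (anyDuplicated(did)) {
    stop("duplicate domain_id in instrument: ",
         paste(unique(did[duplicated(did)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(instrument_id = instrument_id, version = version,
         provenance = provenance, domains = domains),
    class = "rob_instrument"
  )
}

#' @export
print.rob_instrument <- function(x, ...) {
  qt <- question_table(x)
  cat("<rob_instrument> ", x$instrument_id, " v", x$version, "\n", sep = "")
  for (d in x$domains) {
    cat("  ", d$domain_id, ": ", d$name, " (", length(d$questions),
        " questions; rule ", d$rule$some_concerns_at, "/", d$rule$high_at,
        ")\n", sep = "")
  }
  cat("  ", nrow(qt), " questions total, ",
      sum(qt$controlled_only), " controlled-only\n", sep = "")
  invisible(x)
}

#' Flatten an instrument to one row per signalling question
#'
#' @param instrument An [rob_instrument()].
#' @return A data frame with columns `domain_id`, `domain_name`,
#'   `question_id`, `text`, `guidance`, `controlled_only`, `note`,
#'   `some_concerns_at`, `high_at`, in instrument order.
#' @export
question_table <- function(instrument) {
  stopifnot(inherits(instrument, "rob_instrument"))
  rows <- lapply(instrument$domains, function(d) {
    data.frame(
      domain_id = d$domain_id,
      domain_name = d$name,
      question_id = vapply(d$questions, `[[`, character(1), "question_id"),
      text = vapply(d$questions, `[[`, character(1), "text"),
      guidance = vapply(d$questions, `[[`, character(1), "guidance"),
      controlled_only = vapply(d$questions, `[[`, logical(1),
                               "controlled_only"),
      note = vapply(d$questions, function(q)
        if (is.null(q$note)) NA_character_ else q$note, character(1)),
      some_concerns_at = d$rule$some_concerns_at,
      high_at = d$rule$high_at,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Questions applicable under a study design
#'
#' For a controlled design every question applies; for an uncontrolled
#' (single-arm) design the questions flagged `controlled_only` are omitted,
#' preserving instrument order.
#'
#' @inheritParams question_table
#' @param design `"controlled"` or `"uncontrolled"`.
#' @return A data frame as in [question_table()], restricted to the
#'   applicable questions.
#' @export
applicable_questions <- function(instrument, design) {
  design <- match.arg(design, DESIGNS)
  qt <- question_table(instrument)
  if (design == "uncontrolled") qt <- qt[!qt$controlled_only, , drop = FALSE]
  rownames(qt) <- NULL
  qt
}

#' The bundled pilot risk-of-bias tool for clinical laboratory studies
#'
#' Returns the pilot appraisal instrument developed by expert consensus for
#' clinical laboratory studies (studies relating blood or tissue markers to
#' clinical findings). It has three bias domains -- collection and handling
#' of samples, experimental methods, and reporting of the results -- with
#' five, five and four signalling questions respectively, each answered
#' `yes` / `no` / `no_information` at the outcome level. Questions that
#' reference a comparison group (`D1.Q4`, `D1.Q5`, `D2.Q3`, `D3.Q3`) are
#' flagged `controlled_only` and omitted when appraising single-arm studies.
#'
#' The same instrument is installed as YAML package data at
#' `system.file("extdata", "pilot_clinlab_tool.yaml", package = "roblab")`.
#'
#' @return An [rob_instrument()] with 3 domains and 14 questions.
#' @examples
#' tool <- pilot_lab_tool()
#' nrow(question_table(tool))                       # 14
#' nrow(applicable_questions(tool, "uncontrolled")) # 10
#' @export
pilot_lab_tool <- function() {
  d1 <- rob_domain(
    "D1", "Collection and handling of samples",
    list(
      rob_question(
        "D1.Q1",
        "Have patients been clinically evaluated to ensure they fulfil the criteria for inclusion?",
        paste("This question is used to ensure that appropriate diagnostic",
              "tests been performed to ensure that participants providing",
              "samples meet the criteria for the exposure and control groups.",
              "Samples taken from participants who have not been formally",
              "diagnosed may not accurately represent the population group.")
      ),
      rob_question(
        "D1.Q2",
        "Have statistical calculations been performed to determine an appropriate sample size?",
        paste("This is required to ensure the sample size is large enough to",
              "detect a difference between the groups. Underpowered studies",
              "may yield significant results more easily and lead to the",
              "publishing of experiments that were never necessarily intended",
              "to be published."),
        note = paste("This signaling question was added in November 2023",
                     "after the development of the original tool, following a",
                     "discussion with the panel.")
      ),
      rob_question(
        "D1.Q3",
        "Are samples contemporaneous?",
        paste("The integrity of samples obtained at different time points",
              "will be affected by the time spent in storage.")
      ),
      rob_question(
        "D1.Q4",
        "Have patients been matched on non-investigational characteristics that may introduce confounding?",
        paste("Matching characteristics across groups that are not being",
              "investigated, such as age, sex, and health status, reduces",
              "confounding bias."),
        controlled_only = TRUE
      ),
      rob_question(
        "D1.Q5",
        "Have samples from both groups been collected and prepared in the same way?",
        paste("Samples should be consistently handled to ensure this does not",
              "influence how they respond in laboratory experiments, e.g.,",
              "test and control samples should be subjected to the same",
              "number of freeze-thaw cycles and sampling to avoid biased",
              "degradation or contamination."),
        controlled_only = TRUE
      )
    )
  )
  d2 <- rob_domain(
    "D2", "Experimental methods",
    list(
      rob_question(
        "D2.Q1",
        "Is a validated methodology used? If not, is the methodology well described?",
        paste("Methods used may be widely accepted, or new methods can be",
              "used that are adequately described and justified.")
      ),
      rob_question(
        "D2.Q2",
        "Has a normal range been calculated?",
        paste("This study design requires appropriate statistical",
              "calculations to establish a normal range (typically considered",
              "a range of values that you would expect to see for 95% of a",
              "healthy population when conducting a specific test).")
      ),
      rob_question(
        "D2.Q3",
        "Have statistical methods been planned to compare the values of experimental groups with controls?",
        paste("Prespecified methods for comparing the values of experimental",
              "groups with controls ensures that a statistical plan is",
              "followed."),
        controlled_only = TRUE
      ),
      rob_question(
        "D2.Q4",
        "Are the people evaluating the data blind to the source of the samples?",
        paste("Knowledge of the group from which the samples have been",
              "obtained may introduce bias in evaluation of the data.")
      ),
      rob_question(
        "D2.Q5",
        "Is an internal and external control used?",
        paste("An internal control is used to monitor and assure the",
              "reproducibility of results. An external control is a real,",
              "positive clinical sample used to monitor for errors in the",
              "experimental process.")
      )
    )
  )
  d3 <- rob_domain(
    "D3", "Reporting of the results",
    list(
      rob_question(
        "D3.Q1",
        "Are the results quantified and with appropriate analysis?",
        "Results should be fully quantified to allow appropriate analysis."
      ),
      rob_question(
        "D3.Q2",
        "Are all, or nearly all, data available?",
        paste("An appropriate analysis should include data from all samples",
              "that were included.")
      ),
      rob_question(
        "D3.Q3",
        "Are appropriate statistical tests used to test for differences between groups?",
        "This allows validated comparison between values.",
        controlled_only = TRUE
      ),
      rob_question(
        "D3.Q4",
        "Are the data available in a repository and accessible to others?",
        paste("Laboratory data should be made publicly available to allow",
              "external analysis and comparison. Coefficients of inter and",
              "intra assay variation should be made available.")
      )
    )
  )
  rob_instrument(
    instrument_id = "clinlab-pilot",
    version = "1.0",
    domains = list(d1, d2, d3),
    provenance = paste("Pilot consensus risk-of-bias tool for clinical",
                       "laboratory studies; outcome-level appraisal across",
                       "three bias domains.")
  )
}

# ---- serialization -------------------------------------------------------

instrument_to_list <- function(x) {
  list(
    instrument_id = x$instrument_id,
    version = x$version,
    provenance = x$provenance,
    domains = lapply(x$domains, function(d) {
      list(
        domain_id = d$domain_id,
        name = d$name,
        rule = list(some_concerns_at = d$rule$some_concerns_at,
                    high_at = d$rule$high_at),
        questions = lapply(d$questions, function(q) {
          out <- list(question_id = q$question_id, text = q$text,
                      guidance = q$guidance,
                      controlled_only = q$controlled_only)
          if (!is.null(q$note)) out$note <- q$note
          out
        })
      )
    })
  )
}

instrument_from_list <- function(x) {
  need <- function(obj, field, where) {
    if (is.null(obj[[field]])) {
      stop("instrument config: missing field '", field, "' in ", where,
           call. = FALSE)
    }
    obj[[field]]
  }
  domains <- lapply(need(x, "domains", "instrument"), function(d) {
    where <- paste0("domain '", if (is.null(d$domain_id)) "?" else d$domain_id,
                    "'")
    qs <- need(d, "questions", where)
    if (length(qs) == 0L) {
      stop("instrument config: ", where, " has no questions", call. = FALSE)
    }
    rule <- d$rule
    rob_domain(
      domain_id = need(d, "domain_id", where),
      name = need(d, "name", where),
      questions = lapply(qs, function(q) {
        qwhere <- paste0("question '",
                         if (is.null(q$question_id)) "?" else q$question_id,
                         "'")
        rob_question(
          question_id = need(q, "question_id", qwhere),
          text = need(q, "text", qwhere),
          guidance = need(q, "guidance", qwhere),
          controlled_only = isTRUE(q$controlled_only),
          note = q$note
        )
      }),
      some_concerns_at = if (is.null(rule$some_concerns_at)) 1L
                         else rule$some_concerns_at,
      high_at = if (is.null(rule$high_at)) 2L else rule$high_at
    )
  })
  rob_instrument(
    instrument_id = need(x, "instrument_id", "instrument"),
    version = as.character(need(x, "version", "instrument")),
    domains = domains,
    provenance = if (is.null(x$provenance)) "" else x$provenance
  )
}

#' Read an appraisal instrument from YAML or JSON
#'
#' The config dialect mirrors the instrument structure: top-level
#' `instrument_id`, `version`, `provenance` and a `domains` list, each domain
#' carrying `domain_id`, `name`, an optional `rule`
#' (`some_concerns_at`, `high_at`; defaults 1 and 2) and a `questions` list of
#' `question_id` / `text` / `guidance` / `controlled_only` / `note` entries.
#' All instrument invariants (non-empty domains, unique question ids, ordered
#' rule thresholds) are enforced on load. `read_instrument(write_instrument(x))`
#' is the identity.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a literal config
#'   string.
#' @param format `"auto"` (default: by file extension, YAML for literal
#'   strings), `"yaml"`, or `"json"`.
#' @return An [rob_instrument()].
#' @export
read_instrument <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  is_file <- length(path) == 1L && !grepl("\n", path) && file.exists(path)
  if (format == "auto") {
    format <- if (is_file && grepl("\\.json$", path, ignore.case = TRUE))
      "json" else "yaml"
  }
  raw <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n")
         else paste(path, collapse = "\n")
  parsed <- tryCatch(
    switch(format,
           yaml = yaml::yaml.load(raw),
           json = jsonlite::fromJSON(raw, simplifyVector = FALSE)),
    error = function(e) {
      stop("instrument config failed to parse as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  instrument_from_list(parsed)
}

#' Serialize an appraisal instrument
#'
#' @param instrument An [rob_instrument()].
#' @param path Optional output path; when `NULL` the serialized text is
#'   returned.
#' @param format `"yaml"` (primary, diff-friendly) or `"json"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_instrument <- function(instrument, path = NULL,
                             format = c("yaml", "json")) {
  stopifnot(inherits(instrument, "rob_instrument"))
  format <- match.arg(format)
  lst <- instrument_to_list(instrument)
  txt <- switch(format,
    yaml = yaml::as.yaml(lst),
    json = jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE)
  )
  txt <- as.character(txt)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
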