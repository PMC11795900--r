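# Level -> colour and accessibility symbol, robvis-style conventions.
LEVEL_SYMBOLS <- c("Low" = "+", "Some concerns" = "?", "High" = "-")

level_palette <- function(palette = c("default", "colorblind")) {
  palette <- match.arg(palette)
  switch(palette,
    default = c("Low" = "forestgreen", "Some concerns" = "gold",
                "High" = "firebrick"),
    colorblind = c("Low" = "#009E73", "Some concerns" = "#E69F00",
                   "High" = "#D55E00")  # Okabe-Ito
  )
}

check_judgements <- function(judgements) {
  if (!inherits(judgements, "data.frame") || nrow(judgements) == 0L) {
    stop("'judgements' must be a non-empty rob_judgements data frame",
         call. = FALSE)
  }
  judgements
}

#' Traffic-light table of judgements
#'
#' One row per judged study x outcome unit (and assessor, if several),
#' domains as columns in instrument order with the overall judgement
#' rightmost. Cell values are taken verbatim from the judgement input;
#' rendering never recomputes levels.
#'
#' @param judgements An `rob_judgements` data frame from [judge_set()].
#' @param instrument An [rob_instrument()]; its domain set must match the
#'   judgements.
#' @param symbols If `TRUE`, cells are `"level (symbol)"` strings with the
#'   accessibility symbols `+` (Low), `?` (Some concerns), `-` (High);
#'   otherwise plain level names.
#' @return A data frame with columns `study_id`, `outcome_id`,
#'   `assessor_id`, one column per domain, and `Overall`.
#' @export
traffic_light_table <- function(judgements, instrument, symbols = FALSE) {
  check_judgements(judgements)
  stopifnot(inherits(instrument, "rob_instrument"))
  dom_ids <- vapply(instrument$domains, `[[`, character(1), "domain_id")
  jd <- as.data.frame(judgements)
  jd$level <- as.character(jd$level)
  seen <- setdiff(unique(jd$domain_id), "OVERALL")
  if (!setequal(seen, dom_ids)) {
    stop("judgements cover domains (", paste(sort(seen), collapse = ", "),
         ") but the instrument defines (", paste(dom_ids, collapse = ", "),
         "); were they produced with a different instrument?", call. = FALSE)
  }
  if (symbols) {
    jd$level <- paste0(jd$level, " (", LEVEL_SYMBOLS[jd$level], ")")
  }
  wide <- tidyr::pivot_wider(
    jd[, c("study_id", "outcome_id", "assessor_id", "domain_id", "level")],
    names_from = "domain_id", values_from = "level")
  wide <- as.data.frame(wide)
  wide <- wide[order(wide$study_id, wide$outcome_id, wide$assessor_id), ]
  names(wide)[names(wide) == "OVERALL"] <- "Overall"
  wide <- wide[, c("study_id", "outcome_id", "assessor_id", dom_ids,
                   "Overall")]
  rownames(wide) <- NULL
  wide
}

#' Traffic-light plot
#'
#' The conventional risk-of-bias summary figure: units as rows, domains as
#' columns (overall rightmost), cells coloured green / yellow / red for
#' Low / Some concerns / High, with accessibility symbols overlaid. Output
#' is deterministic for fixed input: rows are ordered by `study_id` then
#' `outcome_id` unless `unit_order` supplies an explicit ordering of
#' `"study_id:outcome_id"` labels.
#'
#' @inheritParams traffic_light_table
#' @param palette `"default"` or `"colorblind"` (Okabe-Ito).
#' @param unit_order Optional character vector of `"study:outcome"` labels
#'   giving a custom row order.
#' @return A `ggplot` object.
#' @export
plot_traffic_light <- function(judgements, instrument,
                               palette = c("default", "colorblind"),
                               unit_order = NULL) {
  check_judgements(judgements)
  stopifnot(inherits(instrument, "rob_instrument"))
  cols <- level_palette(match.arg(palette))
  dom_ids <- vapply(instrument$domains, `[[`, character(1), "domain_id")
  jd <- as.data.frame(judgements)
  jd$level <- as.character(jd$level)
  jd$unit <- paste(jd$study_id, jd$outcome_id, sep = ":")
  if (length(unique(jd$assessor_id)) > 1L) {
    jd$unit <- paste(jd$unit, jd$assessor_id, sep = ":")
  }
  lev <- if (is.null(unit_order)) sort(unique(jd$unit), method = "radix")
         else unit_order
  jd$unit <- factor(jd$unit, levels = rev(lev))
  jd$domain <- factor(ifelse(jd$domain_id == "OVERALL", "Overall",
                             jd$domain_id),
                      levels = c(dom_ids, "Overall"))
  jd$symbol <- LEVEL_SYMBOLS[jd$level]
  ggplot2::ggplot(jd, ggplot2::aes(x = .data$domain, y = .data$unit,
                                   fill = .data$level)) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), size = 4) +
    ggplot2::scale_fill_manual(values = cols, breaks = RISK_LEVELS,
                               name = "Risk of bias", drop = FALSE) +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Distribution of judgement levels per domain
#'
#' @param judgements An `rob_judgements` data frame from [judge_set()].
#' @return A data frame with one row per domain (plus `"OVERALL"`) and level,
#'   columns `domain_id`, `level`, `n`, `proportion`; proportions sum to 1
#'   within each domain (to within 1e-12).
#' @export
summarize_distribution <- function(judgements) {
  check_judgements(judgements)
  jd <- as.data.frame(judgements)
  jd$level <- factor(as.character(jd$level), levels = RISK_LEVELS)
  tab <- as.data.frame(table(domain_id = jd$domain_id, level = jd$level),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  totals <- stats::ave(tab$n, tab$domain_id, FUN = sum)
  tab$proportion <- tab$n / totals
  tab <- tab[order(tab$domain_id != "OVERALL", tab$domain_id,
                   match(tab$level, RISK_LEVELS)), ]
  # domains first, OVERALL last
  tab <- tab[order(tab$domain_id == "OVERALL"), ]
  tab <- tab[order(tab$domain_id == "OVERALL",
                   ifelse(tab$domain_id == "OVERALL", "", tab$domain_id),
                   match(tab$level, RISK_LEVELS)), ]
  rownames(tab) <- NULL
  tab
}

#' Stacked-bar plot of the judgement distribution
#'
#' @inheritParams summarize_distribution
#' @param palette `"default"` or `"colorblind"`.
#' @return A `ggplot` object: one horizontal stacked bar per domain (and
#'   overall), segment widths equal to the level proportions.
#' @export
plot_distribution <- function(judgements,
                              palette = c("default", "colorblind")) {
  tab <- summarize_distribution(judgements)
  cols <- level_palette(match.arg(palette))
  doms <- unique(tab$domain_id)
  tab$domain_id <- factor(tab$domain_id, levels = rev(doms))
  tab$level <- factor(tab$level, levels = rev(RISK_LEVELS))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$proportion,
                                    y = .data$domain_id,
                                    fill = .data$level)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = cols, breaks = RISK_LEVELS,
                               name = "Risk of bias", drop = FALSE) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Proportion of judged units", y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a narrative appraisal report (Markdown)
#'
#' Emits a structured Markdown document: instrument citation, a short
#' methods blurb, a traffic-light summary table, one per-study table with
#' every question's answer and justification, and (if supplied) an
#' agreement section. Deterministic for fixed input.
#'
#' @param set The [rob_set()] behind the judgements.
#' @param judgements The `rob_judgements` for `set` (from [judge_set()]).
#' @param instrument The [rob_instrument()] used.
#' @param agreement Optional `rob_agreement` from [compare_assessors()].
#' @param path Optional output path; when `NULL` the Markdown text is
#'   returned.
#' @return Markdown text, invisibly when written to `path`.
#' @export
render_report <- function(set, judgements, instrument, agreement = NULL,
                          path = NULL) {
  stopifnot(inherits(set, "rob_set"), inherits(instrument, "rob_instrument"))
  check_judgements(judgements)
  jd <- as.data.frame(judgements)
  set_units <- unique(paste(set$data$study_id, set$data$outcome_id,
                            set$data$assessor_id, sep = "\r"))
  j_units <- unique(paste(jd$study_id, jd$outcome_id, jd$assessor_id,
                          sep = "\r"))
  if (!setequal(set_units, j_units)) {
    stop("'judgements' do not correspond to the units of 'set'",
         call. = FALSE)
  }
  qt <- question_table(instrument)
  md <- c(
    paste0("# Risk-of-bias assessment report"),
    "",
    paste0("**Instrument:** ", instrument$instrument_id, " v",
           instrument$version, ". ", instrument$provenance),
    "",
    "## Methods",
    "",
    paste0("Each study was appraised at the outcome level by answering the ",
           "instrument's signalling questions (yes / no / no information). ",
           "Within each domain, all answers of \"yes\" give a low risk of ",
           "bias, exactly one answer of \"no\" or \"no information\" gives ",
           "some concerns, and more than one gives a high risk of bias. ",
           "The overall judgement is the highest (worst) domain judgement. ",
           "Questions referring to a control group are omitted for ",
           "uncontrolled studies."),
    "",
    "## Summary of judgements",
    "",
    md_table(traffic_light_table(judgements, instrument, symbols = TRUE)),
    ""
  )
  recs <- set_records(set)
  ord <- order(vapply(recs, function(r)
    paste(r$study_id, r$outcome_id, r$assessor_id), character(1)))
  for (r in recs[ord]) {
    jr <- jd[jd$study_id == r$study_id & jd$outcome_id == r$outcome_id &
               jd$assessor_id == r$assessor_id, , drop = FALSE]
    ov <- as.character(jr$level[jr$domain_id == "OVERALL"])
    tabr <- data.frame(
      question_id = names(r$answers),
      question = qt$text[match(names(r$answers), qt$question_id)],
      answer = unname(r$answers),
      justification = if (is.null(r$justifications)) "" else {
        j <- r$justifications[names(r$answers)]
        ifelse(is.na(j), "", j)
      },
      stringsAsFactors = FALSE)
    md <- c(md,
      paste0("## ", r$study_id, " / ", r$outcome_id, " (assessor ",
             r$assessor_id, ", ", r$design, " design) -- overall: ", ov),
      "",
      md_table(tabr),
      "")
  }
  if (!is.null(agreement)) {
    stopifnot(inherits(agreement, "rob_agreement"))
    md <- c(md,
      "## Inter-assessor agreement",
      "",
      paste0("Assessors ", agreement$assessor_a, " and ",
             agreement$assessor_b, " were compared on ", agreement$n_units,
             " unit(s). Overall-level agreement ",
             sprintf("%.3f", agreement$overall_agreement),
             "; Cohen's kappa ", fmt_kappa(agreement$kappa_overall),
             " (unweighted), ", fmt_kappa(agreement$kappa_weighted),
             " (", agreement$weights, " weights)."),
      "",
      paste0(nrow(agreement$disagreements),
             " disagreement(s) recorded (all granularities)."),
      "")
  }
  txt <- paste(md, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

md_table <- function(df) {
  esc <- function(x) gsub("\n", " ", gsub("|", "\\|", as.character(x),
                                          fixed = TRUE))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(row)
    paste0("| ", paste(esc(row), collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
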