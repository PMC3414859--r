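# PICO query construction and the 15-strategy grid.
#
# Queries follow the PubMed dialect: terms are OR-ed within each PICO
# category, categories are AND-ed together, multiword terms are wrapped in
# parentheses (never quotes) so PubMed's automatic term mapping still
# applies to each word group.

#' Create a structured PICO question
#'
#' A clinical question decomposed into the four PICO categories:
#' population, interventions, comparison, outcomes.  Population and
#' interventions must contain at least one term; the comparison may be
#' empty (for many review questions the comparison shares its terms with
#' the intervention and no separate term is retained).
#'
#' @param question_id opaque label for the question.
#' @param population,interventions,outcomes character vectors of search
#'   terms, at least one non-blank term each.
#' @param comparison character vector of comparison terms, possibly empty.
#' @return an object of class `pico_question`.
#' @examples
#' pico_question("copd-mucolytics",
#'   population = c("chronic bronchitis", "COPD"),
#'   interventions = "mucolytics",
#'   comparison = "placebo",
#'   outcomes = "exacerbations"
#' )
#' @export
pico_question <- function(question_id, population, interventions,
                          comparison = character(), outcomes = character()) {
  check_terms <- function(terms, name, allow_empty) {
    terms <- as.character(terms)
    if (!allow_empty && length(terms) == 0) {
      abort(sprintf("'%s' must contain at least one term", name),
            "invalid_question")
    }
    if (length(terms) > 0 && any(!nzchar(trimws(terms)))) {
      abort(sprintf("'%s' contains a blank term", name), "invalid_term")
    }
    squish(terms)
  }
  structure(
    list(
      question_id = as.character(question_id),
      population = check_terms(population, "population", FALSE),
      interventions = check_terms(interventions, "interventions", FALSE),
      comparison = check_terms(comparison, "comparison", TRUE),
      outcomes = check_terms(outcomes, "outcomes", TRUE)
    ),
    class = "pico_question"
  )
}

#' @export
print.pico_question <- function(x, ...) {
  cat("<pico_question>", x$question_id, "\n")
  fmt <- function(v) if (length(v)) paste(v, collapse = " | ") else "(none)"
  cat("  P:", fmt(x$population), "\n")
  cat("  I:", fmt(x$interventions), "\n")
  cat("  C:", fmt(x$comparison), "\n")
  cat("  O:", fmt(x$outcomes), "\n")
  invisible(x)
}

#' Build the Boolean clause for one PICO category
#'
#' Terms within a category are combined with OR to maximise sensitivity.
#' Multiword terms are wrapped in parentheses (not quotes, so PubMed's
#' automatic term mapping is preserved); when several terms are joined the
#' whole clause gets one outer pair of parentheses.
#'
#' @param terms character vector of search terms; may be empty.
#' @return a single string, or `""` for an empty category (the category is
#'   then omitted from the query).
#' @examples
#' build_category_clause(c("chronic bronchitis", "COPD"))
#' #> "((chronic bronchitis) OR COPD)"
#' build_category_clause("mucolytics")
#' #> "mucolytics"
#' @export
build_category_clause <- function(terms) {
  terms <- as.character(terms)
  if (length(terms) == 0) {
    return("")
  }
  if (any(!nzchar(trimws(terms)))) {
    abort("blank search term in category", "invalid_term")
  }
  terms <- squish(terms)
  wrapped <- ifelse(grepl(" ", terms, fixed = TRUE),
                    paste0("(", terms, ")"), terms)
  if (length(wrapped) == 1) {
    return(wrapped)
  }
  paste0("(", paste(wrapped, collapse = " OR "), ")")
}

#' Compose the base PubMed query for a question
#'
#' Joins the non-empty category clauses with AND in P, I, C, O order.  The
#' truncated PIC form drops the outcomes clause: outcomes are the PICO
#' element least often present in abstracts or index terms, so omitting
#' them trades precision for sensitivity.  An empty comparison is silently
#' omitted.
#'
#' @param question a [pico_question()].
#' @param form `"PICO"` (all four categories) or `"PIC"` (outcomes
#'   dropped).
#' @param date_cap optional `Date` (or `"YYYY-MM-DD"` string): the search
#'   horizon, normally the date the gold-standard review was up to date.
#'   Carried on the query and rendered by [render_strategy_query()].
#' @return an object of class `query_string` with fields `text`, `form`
#'   and `date_cap`.
#' @examples
#' q <- pico_question("copd-mucolytics",
#'   population = c("chronic bronchitis", "COPD"),
#'   interventions = "mucolytics", comparison = "placebo",
#'   outcomes = "exacerbations"
#' )
#' compose_query(q, "PICO")$text
#' #> "((chronic bronchitis) OR COPD) AND mucolytics AND placebo AND exacerbations"
#' @export
compose_query <- function(question, form = c("PICO", "PIC"),
                          date_cap = NULL) {
  form <- match.arg(form)
  if (!inherits(question, "pico_question")) {
    abort("'question' must be a pico_question", "invalid_question")
  }
  categories <- list(question$population, question$interventions,
                     question$comparison)
  if (form == "PICO") {
    categories <- c(categories, list(question$outcomes))
  }
  clauses <- vapply(categories, build_category_clause, character(1))
  clauses <- clauses[nzchar(clauses)]
  if (!is.null(date_cap)) {
    date_cap <- as.Date(date_cap)
  }
  structure(
    list(text = paste(clauses, collapse = " AND "), form = form,
         date_cap = date_cap),
    class = "query_string"
  )
}

#' @export
print.query_string <- function(x, ...) {
  cat("<query_string>", x$form,
      if (!is.null(x$date_cap)) paste0("(up to ", format(x$date_cap), ")"),
      "\n  ", x$text, "\n", sep = "")
  invisible(x)
}

#' Load the Clinical Queries filter and limit texts
#'
#' The methodological filter and limit strings are configuration, not
#' constants: PubMed's Clinical Queries wording has been revised over time.
#' The packaged default carries the 2005-revision therapy filters (narrow:
#' publication-type randomized controlled trial, or
#' randomized/controlled/trial in title or abstract; broad: the six-clause
#' sensitivity-maximising disjunction) and the usual limit expansions
#' (`English[lang]`, `humans[MeSH Terms]`, `jsubsetaim` for the Abridged
#' Index Medicus journal subset).
#'
#' @param path optional path to a YAML file with keys `therapy_broad`,
#'   `therapy_narrow`, `english`, `human`, `aim`; defaults to the packaged
#'   configuration.
#' @return named list of filter/limit clause texts.
#' @export
filter_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "clinical_queries_filters.yaml",
                        package = "searcheval", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("therapy_broad", "therapy_narrow", "english", "human", "aim")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    abort(paste("filter config missing keys:",
                paste(missing, collapse = ", ")), "invalid_config")
  }
  lapply(cfg[needed], squish)
}

#' Enumerate the 15 point-of-care search strategies
#'
#' The grid crosses the query form (PIC or PICO) with the Clinical Queries
#' therapy filters (none, broad, narrow) and cumulative search limits
#' (English; + humans; + Abridged Index Medicus journals).  Three further
#' strategies take the ranked related-articles output seeded from the 1st,
#' 2nd or 3rd most relevant-looking citation of the narrow-filtered PICO
#' search; related-articles outputs come from PubMed itself (or the
#' simulator), so those rows carry no filter or limits.
#'
#' @return a data frame with 15 rows and columns `strategy_id`,
#'   `query_form` (`PIC`, `PICO`, `RELATED`), `cq_filter` (`none`,
#'   `therapy_broad`, `therapy_narrow`), `limits` (list column of
#'   character vectors) and `related_seed_rank` (integer, `NA` unless
#'   `query_form == "RELATED"`).
#' @examples
#' grid <- strategy_grid()
#' nrow(grid)          # 15
#' grid[grid$strategy_id == "S10", c("query_form", "cq_filter")]
#' @export
strategy_grid <- function() {
  lim <- function(...) c(...)
  eh <- c("english", "human")
  eha <- c("english", "human", "aim")
  rows <- list(
    list("S1",  "PIC",     "none",           lim(),  NA_integer_),
    list("S2",  "PIC",     "therapy_broad",  lim(),  NA_integer_),
    list("S3",  "PIC",     "therapy_broad",  eh,     NA_integer_),
    list("S4",  "PIC",     "therapy_narrow", lim(),  NA_integer_),
    list("S5",  "PIC",     "therapy_narrow", eh,     NA_integer_),
    list("S6",  "PICO",    "none",           lim(),  NA_integer_),
    list("S7",  "PICO",    "therapy_broad",  lim(),  NA_integer_),
    list("S8",  "PICO",    "therapy_broad",  eh,     NA_integer_),
    list("S9",  "PICO",    "therapy_broad",  eha,    NA_integer_),
    list("S10", "PICO",    "therapy_narrow", lim(),  NA_integer_),
    list("S11", "PICO",    "therapy_narrow", eh,     NA_integer_),
    list("S12", "PICO",    "therapy_narrow", eha,    NA_integer_),
    list("S13", "RELATED", "none",           lim(),  1L),
    list("S14", "RELATED", "none",           lim(),  2L),
    list("S15", "RELATED", "none",           lim(),  3L)
  )
  out <- data.frame(
    strategy_id = vapply(rows, `[[`, character(1), 1),
    query_form = vapply(rows, `[[`, character(1), 2),
    cq_filter = vapply(rows, `[[`, character(1), 3),
    related_seed_rank = vapply(rows, `[[`, integer(1), 5),
    stringsAsFactors = FALSE
  )
  out$limits <- I(lapply(rows, `[[`, 4))
  out[, c("strategy_id", "query_form", "cq_filter", "limits",
          "related_seed_rank")]
}

#' Render the full query text for one strategy
#'
#' AND-conjoins the base PIC/PICO query with the strategy's Clinical
#' Queries filter clause (if any), each of its limit clauses, and — when
#' the base query carries a date cap — a publication-date range clause up
#' to that date.  Each appended clause is wrapped in its own pair of
#' parentheses.
#'
#' Related-articles strategies have no query text of their own (their
#' ranked output is supplied externally or simulated) and raise an error
#' here.
#'
#' @param base a `query_string` from [compose_query()].
#' @param strategy one row of [strategy_grid()] (a data frame row or an
#'   equivalent list).
#' @param filters filter/limit texts, see [filter_config()].
#' @return a `query_string` with the fully rendered text.
#' @export
render_strategy_query <- function(base, strategy,
                                  filters = filter_config()) {
  if (!inherits(base, "query_string")) {
    abort("'base' must be a query_string", "invalid_query")
  }
  form <- as.character(strategy$query_form)
  if (form == "RELATED") {
    abort("related-articles strategies have no rendered query; supply their output directly",
          "unsupported_strategy")
  }
  if (form != base$form) {
    abort(sprintf("strategy expects a %s query but base query is %s",
                  form, base$form), "form_mismatch")
  }
  limits <- strategy$limits
  if (is.list(limits)) limits <- limits[[1]]
  cq <- as.character(strategy$cq_filter)
  parts <- character()
  if (cq != "none") {
    parts <- c(parts, filters[[cq]])
  }
  parts <- c(parts, unlist(filters[limits], use.names = FALSE))
  if (!is.null(base$date_cap)) {
    parts <- c(parts, sprintf(
      "1900/01/01[Date - Publication] : %s[Date - Publication]",
      format(base$date_cap, "%Y/%m/%d")
    ))
  }
  text <- base$text
  if (length(parts)) {
    text <- paste(c(text, paste0("(", parts, ")")), collapse = " AND ")
  }
  structure(list(text = text, form = base$form, date_cap = base$date_cap),
            class = "query_string")
}

# Split a rendered query on " AND " at parenthesis depth 0; inverse of the
# clause-joining step, used to validate round-tripping.
split_top_level_and <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  n <- length(chars)
  breaks <- integer()
  i <- 1L
  sep <- c(" ", "A", "N", "D", " ")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && ch == " " && i + 4L <= n &&
        identical(chars[i:(i + 4L)], sep)) {
      breaks <- c(breaks, i)
      i <- i + 5L
    } else {
      i <- i + 1L
    }
  }
  starts <- c(1L, breaks + 5L)
  ends <- c(breaks - 1L, n)
  vapply(seq_along(starts), function(k) {
    paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

#' Read PICO questions from a JSON or YAML file
#'
#' Expects a list of objects with fields `question_id`, `population`,
#' `interventions`, `comparison`, `outcomes`, each category a string
#' array (comparison and outcomes may be empty or absent).
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return list of [pico_question()] objects.
#' @export
read_pico_questions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort(sprintf("unsupported question file extension '%s'", ext),
          "invalid_config")
  )
  lapply(raw, function(rec) {
    pico_question(
      question_id = rec$question_id,
      population = unlist(rec$population),
      interventions = unlist(rec$interventions),
      comparison = if (is.null(rec$comparison)) character() else unlist(rec$comparison),
      outcomes = if (is.null(rec$outcomes)) character() else unlist(rec$outcomes)
    )
  })
}
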