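# Performance measures for one ranked search output against one
# gold standard: sensitivity (recall), positive predictive value
# (precision), number needed to read, zero-yield and cumulative
# sensitivity, at a screening cutoff or over the full output.
#
# The gold standard for a question is the set of trials included in its
# systematic review; the evaluation denominator is restricted to the
# subset indexed in PubMed, since no search strategy can retrieve a study
# the database does not hold.  At a screening cutoff the PPV denominator
# is the number of items actually screened, min(cutoff, output length).

#' Create a gold standard for one question
#'
#' @param question_id opaque label.
#' @param included_ids identifiers of all studies included in the review.
#' @param indexed_ids identifiers of the subset retrievable in PubMed;
#'   must be a subset of `included_ids`.  Defaults to all of
#'   `included_ids`.
#' @return object of class `gold_standard`.
#' @export
gold_standard <- function(question_id, included_ids,
                          indexed_ids = included_ids) {
  included_ids <- unique(squish(as.character(included_ids)))
  indexed_ids <- unique(squish(as.character(indexed_ids)))
  if (!all(indexed_ids %in% included_ids)) {
    abort("indexed_ids must be a subset of included_ids", "invalid_gold")
  }
  structure(
    list(question_id = as.character(question_id),
         included_ids = included_ids, indexed_ids = indexed_ids),
    class = "gold_standard"
  )
}

#' Create a ranked search output
#'
#' An ordered list of distinct article identifiers as returned by one
#' strategy for one question; rank 1 is the first item on the first
#' results page.  Identifiers are treated as opaque strings (leading
#' zeros preserved) and compared after whitespace trimming.  Duplicates in
#' the raw list are removed keeping the first (best) rank — PubMed outputs
#' are duplicate-free, incoming files may not be.
#'
#' @param question_id,strategy_id labels.
#' @param ids character vector of article identifiers in rank order.
#' @return object of class `ranked_output`.
#' @export
ranked_output <- function(question_id, strategy_id, ids) {
  ids <- squish(as.character(ids))
  ids <- ids[!duplicated(ids)]
  structure(
    list(question_id = as.character(question_id),
         strategy_id = as.character(strategy_id), ranked_ids = ids),
    class = "ranked_output"
  )
}

#' Evaluate a ranked output against a gold standard
#'
#' Counts the gold-standard (indexed) articles among the first
#' `min(cutoff, length(output))` items.  Sensitivity is that count over
#' the number of indexed gold articles; PPV is the count over the number
#' of items actually screened.  Percentages are reported to one decimal,
#' rounding half away from zero; the returned counts allow exact
#' recomputation.
#'
#' @param output a [ranked_output()].
#' @param gold a [gold_standard()] with at least one indexed id.
#' @param cutoff positive integer screening cutoff (40 = the first two
#'   PubMed pages), or `"full"` for the whole output.
#' @return object of class `metric_result`: a list with
#'   `sensitivity_pct`, `ppv_pct`, `n_relevant_retrieved`, `n_screened`,
#'   `cutoff`, `gold_size`, `degenerate` (TRUE when nothing was screened,
#'   in which case PPV is reported as 0).
#' @examples
#' g <- gold_standard("q", paste0("g", 1:7))
#' o <- ranked_output("q", "S1", c(paste0("g", 1:6), "x1", "x2", "x3"))
#' evaluate(o, g)            # sensitivity 85.7, PPV 66.7
#' @export
evaluate <- function(output, gold, cutoff = "full") {
  if (!inherits(output, "ranked_output") || !inherits(gold, "gold_standard")) {
    abort("evaluate() needs a ranked_output and a gold_standard",
          "invalid_input")
  }
  gold_size <- length(gold$indexed_ids)
  if (gold_size < 1) {
    abort("gold standard has no PubMed-indexed article: not evaluable",
          "not_evaluable")
  }
  if (identical(cutoff, "full")) {
    k <- length(output$ranked_ids)
  } else {
    if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
        cutoff < 1 || cutoff != floor(cutoff)) {
      abort("cutoff must be a positive integer or \"full\"",
            "invalid_cutoff")
    }
    k <- min(as.integer(cutoff), length(output$ranked_ids))
  }
  screened <- output$ranked_ids[seq_len(k)]
  n_rel <- sum(screened %in% gold$indexed_ids)
  degenerate <- k == 0L
  structure(
    list(
      question_id = output$question_id,
      strategy_id = output$strategy_id,
      cutoff = if (identical(cutoff, "full")) "full" else as.integer(cutoff),
      gold_size = gold_size,
      n_screened = k,
      n_relevant_retrieved = n_rel,
      sensitivity_pct = round_half_up(100 * n_rel / gold_size),
      ppv_pct = if (degenerate) 0 else round_half_up(100 * n_rel / k),
      degenerate = degenerate
    ),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf(
    "<metric_result> %s / %s @ %s: sensitivity %.1f%% (%d/%d), PPV %.1f%% (%d/%d)%s\n",
    x$question_id, x$strategy_id, as.character(x$cutoff),
    x$sensitivity_pct, x$n_relevant_retrieved, x$gold_size,
    x$ppv_pct, x$n_relevant_retrieved, x$n_screened,
    if (x$degenerate) " [degenerate: nothing screened]" else ""
  ))
  invisible(x)
}

#' Number needed to read
#'
#' The expected number of output items a reader must screen to find one
#' relevant article: the reciprocal of the PPV, rounded to the nearest
#' integer (half away from zero).
#'
#' @param ppv_fraction PPV as a proportion in (0, 1].
#' @return positive integer.
#' @examples
#' nnr(0.025) # 40
#' nnr(0.321) # 3
#' @export
nnr <- function(ppv_fraction) {
  if (!is.numeric(ppv_fraction) || length(ppv_fraction) != 1 ||
      is.na(ppv_fraction) || ppv_fraction > 1) {
    abort("ppv_fraction must be a single proportion in (0, 1]",
          "invalid_ppv")
  }
  if (ppv_fraction <= 0) {
    abort("NNR is undefined when no relevant article is in the screened output",
          "undefined_nnr")
  }
  as.integer(round_half_up(1 / ppv_fraction, digits = 0))
}

#' Cumulative sensitivity curve
#'
#' Sensitivity as a function of the number of items screened, for ranks 1
#' to `max_rank`.  Beyond the end of the output the curve stays constant
#' at the full-output sensitivity.
#'
#' @inheritParams evaluate
#' @param max_rank largest screening depth to report.
#' @return numeric vector of length `max_rank`; element `k` is the
#'   sensitivity (1-decimal percentage) after screening `k` items.
#' @export
cumulative_curve <- function(output, gold, max_rank) {
  if (!is.numeric(max_rank) || length(max_rank) != 1 || max_rank < 1 ||
      max_rank != floor(max_rank)) {
    abort("max_rank must be a positive integer", "invalid_cutoff")
  }
  gold_size <- length(gold$indexed_ids)
  if (gold_size < 1) {
    abort("gold standard has no PubMed-indexed article: not evaluable",
          "not_evaluable")
  }
  hits <- cumsum(output$ranked_ids %in% gold$indexed_ids)
  k <- seq_len(max_rank)
  padded <- c(hits, rep(if (length(hits)) hits[length(hits)] else 0L,
                        max(0L, max_rank - length(hits))))
  round_half_up(100 * padded[k] / gold_size)
}

#' Did a search find nothing relevant within the screening cutoff?
#'
#' @inheritParams evaluate
#' @param cutoff positive integer screening cutoff.
#' @return `TRUE` when no gold-standard article appears in the first
#'   `cutoff` items.
#' @export
zero_yield <- function(output, gold, cutoff = 40) {
  evaluate(output, gold, cutoff)$n_relevant_retrieved == 0L
}
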