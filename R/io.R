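# Readers and writers for the two CSV schemas, the packaged benchmark
# fixture, dataset assembly, and the end-to-end pipeline.
#
# CSV dialect: UTF-8, comma-separated, header row required, identifiers
# unquoted.  Gold-standard files have columns
# question_id, article_id, in_pubmed (0/1), one row per included study.
# Output files have columns question_id, strategy_id, rank, article_id
# with 1-based gap-free ranks per (question, strategy).

BENCHMARK_MD5 <- "e2296c46aeac060940f35c74a9931d15"

#' Bundle gold standards and ranked outputs into a dataset
#'
#' @param golds list of [gold_standard()] objects, unique question ids.
#' @param outputs list of [ranked_output()] objects; every output's
#'   question must have a gold standard and (question, strategy) pairs
#'   must be unique.
#' @param provenance short description of where the data came from
#'   (`"fixture"`, `"files"`, `"simulation"`, ...).
#' @return object of class `study_dataset`.
#' @export
study_dataset <- function(golds, outputs, provenance = "files") {
  qg <- vapply(golds, `[[`, character(1), "question_id")
  if (anyDuplicated(qg)) {
    abort("duplicate question_id among gold standards", "integrity_error")
  }
  qo <- vapply(outputs, `[[`, character(1), "question_id")
  so <- vapply(outputs, `[[`, character(1), "strategy_id")
  if (!all(qo %in% qg)) {
    abort(sprintf("outputs reference unknown question(s): %s",
                  paste(unique(qo[!qo %in% qg]), collapse = ", ")),
          "integrity_error")
  }
  if (anyDuplicated(paste(qo, so))) {
    abort("duplicate (question_id, strategy_id) pair among outputs",
          "integrity_error")
  }
  names(golds) <- qg
  names(outputs) <- paste(qo, so, sep = ":")
  structure(list(golds = golds, outputs = outputs, provenance = provenance),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d questions, %d outputs [%s]\n",
              length(x$golds), length(x$outputs), x$provenance))
  invisible(x)
}

#' Convert a simulated study to a dataset
#'
#' @param study a [simulate_study()] result.
#' @return a [study_dataset()] with provenance `"simulation"`.
#' @export
as_study_dataset <- function(study) {
  if (!inherits(study, "simulated_study")) {
    abort("'study' must be a simulated_study", "invalid_input")
  }
  golds <- lapply(study$questions, `[[`, "gold")
  outputs <- unlist(lapply(study$questions, `[[`, "outputs"),
                    recursive = FALSE, use.names = FALSE)
  study_dataset(golds, outputs, provenance = "simulation")
}

#' Read / write gold-standard CSV files
#'
#' @param path file path.
#' @return `read_gold_csv()`: list of [gold_standard()] objects.
#' @export
read_gold_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  needed <- c("question_id", "article_id", "in_pubmed")
  if (!all(needed %in% names(df))) {
    abort(sprintf("gold CSV must have columns %s",
                  paste(needed, collapse = ", ")), "parse_error")
  }
  bad <- which(!df$in_pubmed %in% c("0", "1"))
  if (length(bad)) {
    abort(sprintf("gold CSV row %d: in_pubmed must be 0 or 1 (got '%s')",
                  bad[1], df$in_pubmed[bad[1]]), "parse_error")
  }
  dup <- which(duplicated(paste(df$question_id, df$article_id)))
  if (length(dup)) {
    abort(sprintf("gold CSV row %d: duplicate (question_id, article_id)",
                  dup[1]), "integrity_error")
  }
  lapply(split(df, df$question_id), function(q) {
    gold_standard(q$question_id[1], q$article_id,
                  q$article_id[q$in_pubmed == "1"])
  })
}

#' @rdname read_gold_csv
#' @param golds list of [gold_standard()] objects.
#' @export
write_gold_csv <- function(golds, path) {
  rows <- do.call(rbind, lapply(golds, function(g) {
    data.frame(question_id = g$question_id, article_id = g$included_ids,
               in_pubmed = as.integer(g$included_ids %in% g$indexed_ids),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write ranked-output CSV files
#'
#' @param path file path.
#' @return `read_outputs_csv()`: list of [ranked_output()] objects.
#' @export
read_outputs_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  needed <- c("question_id", "strategy_id", "rank", "article_id")
  if (!all(needed %in% names(df))) {
    abort(sprintf("output CSV must have columns %s",
                  paste(needed, collapse = ", ")), "parse_error")
  }
  rank <- suppressWarnings(as.integer(df$rank))
  if (anyNA(rank)) {
    abort(sprintf("output CSV row %d: rank '%s' is not an integer",
                  which(is.na(rank))[1], df$rank[which(is.na(rank))[1]]),
          "parse_error")
  }
  df$rank <- rank
  key <- paste(df$question_id, df$strategy_id)
  lapply(split(df, factor(key, levels = unique(key))), function(o) {
    o <- o[order(o$rank), ]
    if (anyDuplicated(o$rank)) {
      abort(sprintf("duplicate rank for (%s, %s)", o$question_id[1],
                    o$strategy_id[1]), "integrity_error")
    }
    if (!identical(o$rank, seq_len(nrow(o)))) {
      abort(sprintf("ranks for (%s, %s) are not 1-based and gap-free",
                    o$question_id[1], o$strategy_id[1]), "integrity_error")
    }
    if (anyDuplicated(o$article_id)) {
      abort(sprintf("duplicate article_id for (%s, %s)", o$question_id[1],
                    o$strategy_id[1]), "integrity_error")
    }
    ranked_output(o$question_id[1], o$strategy_id[1], o$article_id)
  })
}

#' @rdname read_outputs_csv
#' @param outputs list of [ranked_output()] objects.
#' @export
write_outputs_csv <- function(outputs, path) {
  rows <- do.call(rbind, lapply(outputs, function(o) {
    n <- length(o$ranked_ids)
    data.frame(question_id = rep(o$question_id, n),
               strategy_id = rep(o$strategy_id, n),
               rank = seq_len(n), article_id = o$ranked_ids,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the packaged 30-question benchmark table
#'
#' A transcription of the published per-question benchmark: 30 systematic
#' reviews with, for each, the number of included studies, the number
#' retrievable in PubMed, and the full-output and 2-page (40-item)
#' sensitivity and PPV of the unfiltered PIC strategy (S1) and the
#' narrow-filtered PIC strategy (S4), as 1-decimal percentages.  Integer
#' retrieval counts are derived at load time as
#' `round(pct * denominator / 100)` and checked to round back to the
#' printed percentage.
#'
#' @param path optional path to an alternative transcription; the packaged
#'   file is integrity-checked against an embedded digest.
#' @return data frame of class `benchmark_table` with the printed columns
#'   plus derived counts `s1_full_n_rel`, `s4_full_n_rel`, `s1_p2_n_rel`,
#'   `s4_p2_n_rel`.
#' @export
load_benchmark_table <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "benchmark_cochrane30.csv",
                        package = "searcheval", mustWork = TRUE)
    digest <- unname(tools::md5sum(path))
    if (!identical(digest, BENCHMARK_MD5)) {
      abort("packaged benchmark fixture is corrupted (digest mismatch)",
            "corrupted_fixture")
    }
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) != 30 || ncol(df) != 12) {
    abort("benchmark fixture must have 30 rows and 12 columns",
          "corrupted_fixture")
  }
  if (any(df$n_retrievable > df$n_included) || any(df$n_retrievable < 1)) {
    abort("benchmark fixture: retrievable counts out of range",
          "corrupted_fixture")
  }
  pct_cols <- grep("_(sens|ppv)$", names(df), value = TRUE)
  if (any(df[pct_cols] < 0 | df[pct_cols] > 100)) {
    abort("benchmark fixture: percentages out of [0, 100]",
          "corrupted_fixture")
  }
  derive <- function(pct, denom, label) {
    n <- round_half_up(pct * denom / 100, digits = 0)
    back <- round_half_up(100 * n / denom)
    bad <- which(back != pct)
    if (length(bad)) {
      abort(sprintf(
        "benchmark fixture: %s count inconsistent with printed %% in row %d",
        label, bad[1]), "corrupted_fixture")
    }
    as.integer(n)
  }
  df$s1_full_n_rel <- derive(df$s1_full_sens, df$n_retrievable, "S1 full")
  df$s4_full_n_rel <- derive(df$s4_full_sens, df$n_retrievable, "S4 full")
  df$s1_p2_n_rel <- derive(df$s1_p2_sens, df$n_retrievable, "S1 2-page")
  df$s4_p2_n_rel <- derive(df$s4_p2_sens, df$n_retrievable, "S4 2-page")
  class(df) <- c("benchmark_table", class(df))
  df
}

#' Reconstruct a synthetic dataset from the benchmark table
#'
#' Builds, for every benchmark question, a synthetic gold standard and
#' synthetic S1/S4 ranked outputs whose retrieval counts reproduce the
#' printed percentages: output length is derived from the full-output PPV
#' (`round(n_relevant / ppv)`), the 2-page relevant articles occupy the
#' earliest ranks, and the remaining relevant articles sit beyond rank 40.
#' Identifiers are synthetic (`q01_g001`, ...); only membership and rank
#' structure are meaningful, not the articles themselves.
#'
#' @param fixture a [load_benchmark_table()] result.
#' @return a [study_dataset()] with provenance `"fixture"`.
#' @export
fixture_to_dataset <- function(fixture = load_benchmark_table()) {
  golds <- list()
  outputs <- list()
  for (i in seq_len(nrow(fixture))) {
    row <- fixture[i, ]
    qid <- sprintf("q%02d", row$review_id)
    included <- sprintf("%s_g%03d", qid, seq_len(row$n_included))
    indexed <- included[seq_len(row$n_retrievable)]
    golds[[qid]] <- gold_standard(qid, included, indexed)
    for (s in c("s1", "s4")) {
      n_full <- row[[paste0(s, "_full_n_rel")]]
      n_p2 <- row[[paste0(s, "_p2_n_rel")]]
      full_ppv <- row[[paste0(s, "_full_ppv")]]
      len <- if (full_ppv > 0) {
        as.integer(round_half_up(100 * n_full / full_ppv, digits = 0))
      } else {
        max(40L, n_full)
      }
      len <- max(len, n_full, 1L)
      head_len <- min(40L, len)
      ids <- sprintf("%s_%s_n%04d", qid, s, seq_len(len))
      # 2-page relevant articles at the earliest ranks ...
      if (n_p2 > 0) ids[seq_len(n_p2)] <- indexed[seq_len(n_p2)]
      # ... remaining relevant articles immediately after the 2-page window
      extra <- n_full - n_p2
      if (extra > 0) {
        ids[head_len + seq_len(extra)] <- indexed[n_p2 + seq_len(extra)]
      }
      outputs[[paste(qid, s, sep = ":")]] <-
        ranked_output(qid, toupper(s), ids)
    }
  }
  study_dataset(unname(golds), unname(outputs), provenance = "fixture")
}

# Flatten metric_result objects into a data frame, with NNR where defined.
metrics_to_df <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(
      question_id = m$question_id, strategy_id = m$strategy_id,
      cutoff = as.character(m$cutoff), gold_size = m$gold_size,
      n_screened = m$n_screened,
      n_relevant_retrieved = m$n_relevant_retrieved,
      sensitivity_pct = m$sensitivity_pct, ppv_pct = m$ppv_pct,
      nnr = if (m$ppv_pct > 0) nnr(m$ppv_pct / 100) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the whole evaluation pipeline on a dataset
#'
#' For every (question, strategy) output: metrics at each cutoff.  Per
#' strategy and cutoff: a median/IQR summary.  For each requested strategy
#' pair: a comparison report (at `comparison_cutoff`) with
#' increased/stable/decreased counts, zero-yield counts and the paired
#' Wilcoxon test.  Per strategy: the median cumulative sensitivity curve.
#'
#' @param dataset a [study_dataset()].
#' @param cutoffs list of cutoffs, each a positive integer or `"full"`.
#' @param comparisons list of length-2 character vectors
#'   `c(strategy_a, strategy_b)`; may be empty.
#' @param measure measure for the comparisons, `"sensitivity"` or
#'   `"ppv"`.
#' @param comparison_cutoff cutoff at which comparisons are made
#'   (default 40, the 2-page screening budget).
#' @param max_rank depth of the cumulative curves.
#' @param out_dir optional directory: writes `metrics.csv`,
#'   `summary_<cutoff>.csv`, `comparison_<a>_vs_<b>.json` and
#'   `curves.csv` there.
#' @param verbose emit per-stage progress messages.
#' @return list with `metrics` (data frame), `summaries` (data frame),
#'   `comparisons` (list of `comparison_report`), `curves` (long data
#'   frame `strategy_id, rank, median_sensitivity_pct`).
#' @export
run_pipeline <- function(dataset, cutoffs = list(40, "full"),
                         comparisons = list(), measure = "sensitivity",
                         comparison_cutoff = 40, max_rank = 100,
                         out_dir = NULL, verbose = FALSE) {
  if (!inherits(dataset, "study_dataset")) {
    abort("'dataset' must be a study_dataset", "invalid_input")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  strategies <- unique(vapply(dataset$outputs, `[[`, character(1),
                              "strategy_id"))
  say("evaluating %d outputs at %d cutoff(s)", length(dataset$outputs),
      length(cutoffs))

  all_metrics <- list()
  for (cutoff in cutoffs) {
    for (o in dataset$outputs) {
      m <- evaluate(o, dataset$golds[[o$question_id]], cutoff)
      all_metrics[[length(all_metrics) + 1L]] <- m
    }
  }
  metrics_df <- metrics_to_df(all_metrics)

  summaries <- list()
  for (cutoff in cutoffs) {
    clab <- as.character(if (identical(cutoff, "full")) "full" else cutoff)
    for (s in strategies) {
      keep <- vapply(all_metrics, function(m) {
        m$strategy_id == s && identical(as.character(m$cutoff), clab)
      }, logical(1))
      sizes <- vapply(dataset$outputs[vapply(dataset$outputs, `[[`,
                      character(1), "strategy_id") == s],
                      function(o) length(o$ranked_ids), numeric(1))
      sm <- summarize_strategy(all_metrics[keep], output_sizes = sizes)
      sm$cutoff <- clab
      summaries[[length(summaries) + 1L]] <- sm
      say("summary %s @ %s: median sensitivity %.1f, median PPV %.1f",
          s, clab, sm$sens_median, sm$ppv_median)
    }
  }
  summaries_df <- do.call(rbind, summaries)

  reports <- list()
  for (pair in comparisons) {
    pick <- function(s) {
      keep <- vapply(all_metrics, function(m) {
        m$strategy_id == s &&
          identical(as.character(m$cutoff), as.character(comparison_cutoff))
      }, logical(1))
      all_metrics[keep]
    }
    rep <- compare_strategies(pick(pair[1]), pick(pair[2]), measure)
    reports[[paste(pair, collapse = "_vs_")]] <- rep
    say("comparison %s vs %s: %d/%d/%d, p = %.3g", pair[2], pair[1],
        rep$n_increased, rep$n_stable, rep$n_decreased,
        rep$wilcoxon$p_two_sided)
  }

  curves <- do.call(rbind, lapply(strategies, function(s) {
    keep <- vapply(dataset$outputs, function(o) o$strategy_id == s,
                   logical(1))
    outs <- dataset$outputs[keep]
    golds <- dataset$golds[vapply(outs, `[[`, character(1), "question_id")]
    data.frame(strategy_id = s, rank = seq_len(max_rank),
               median_sensitivity_pct =
                 median_cumulative_curve(outs, golds, max_rank),
               stringsAsFactors = FALSE)
  }))

  bundle <- list(metrics = metrics_df, summaries = summaries_df,
                 comparisons = reports, curves = curves)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    for (clab in unique(summaries_df$cutoff)) {
      utils::write.csv(summaries_df[summaries_df$cutoff == clab, ],
                       file.path(out_dir, paste0("summary_", clab, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    for (nm in names(reports)) {
      rep <- reports[[nm]]
      rep_plain <- rep
      class(rep_plain) <- NULL
      jsonlite::write_json(rep_plain,
                           file.path(out_dir, paste0("comparison_", nm,
                                                     ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE, quote = FALSE)
    say("report bundle written to %s", out_dir)
  }
  bundle
}

#' Offline search adapter
#'
#' The pipeline's pluggable search interface: an adapter is a function
#' `(question_id, strategy_id, date_cap) -> ranked_output`.  A live
#' adapter could execute the rendered query against PubMed's E-utilities
#' and return the identifier list in rank order; no such implementation is
#' shipped (the test and evaluation paths are fully offline).  This stub
#' serves pre-loaded or simulated outputs from a dataset, which is how
#' adapters are exercised here.
#'
#' @param dataset a [study_dataset()] to serve outputs from.
#' @return adapter function; raises `missing_output` for unknown
#'   (question, strategy) pairs.
#' @export
offline_search_adapter <- function(dataset) {
  force(dataset)
  function(question_id, strategy_id, date_cap = NULL) {
    key <- paste(question_id, strategy_id, sep = ":")
    out <- dataset$outputs[[key]]
    if (is.null(out)) {
      abort(sprintf("no stored output for (%s, %s)", question_id,
                    strategy_id), "missing_output")
    }
    out
  }
}
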