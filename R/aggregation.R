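# Cross-question aggregation: per-strategy median/IQR summaries, paired
# strategy comparisons (Wilcoxon signed-rank, increased/stable/decreased
# counts, zero-yield risk) and median cumulative sensitivity curves.

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics, placing
#' quantile p at position 1 + p(n - 1) (`stats::quantile` type 7).
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    abort("median_iqr() needs a non-empty numeric vector without NA",
          "invalid_input")
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests whether paired measurements `y` systematically exceed or fall
#' below `x`.  Differences of exactly zero are dropped (the classical
#' treatment; the Pratt variant is not used), absolute differences are
#' ranked with average ranks for ties, and the statistic is the smaller of
#' the positive- and negative-rank sums.  With at most `exact_limit`
#' nonzero differences the two-sided p-value is exact, computed from the
#' full null distribution of the positive-rank sum over all sign
#' assignments (a dynamic-programming convolution, valid under ties);
#' above that, a normal approximation with tie-corrected variance
#' n(n+1)(2n+1)/24 - sum(t^3 - t)/48 and a 0.5 continuity correction.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @param exact_limit largest number of nonzero differences for which the
#'   exact distribution is enumerated (default 12).
#' @return list with `statistic` (smaller rank sum), `p_two_sided`,
#'   `n_effective` (nonzero differences), `w_pos`, `w_neg`, `method`
#'   (`"exact"`, `"normal"` or `"degenerate"`), `degenerate` flag.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(3, 4, 5, 7, 8, 9))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 12) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("x and y must have equal length", "invalid_input")
  }
  if (length(x) < 2 || anyNA(x) || anyNA(y)) {
    abort("need at least 2 complete pairs", "invalid_input")
  }
  d <- y - x
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(statistic = 0, p_two_sided = 1, n_effective = 0L,
                w_pos = 0, w_neg = 0, method = "degenerate",
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  stat <- min(w_pos, w_neg)

  if (m <= exact_limit) {
    # Null distribution of 2*W+ over the 2^m equiprobable sign
    # assignments; doubled ranks are integers even under average-rank ties.
    d2 <- as.integer(round(2 * r))
    counts <- numeric(sum(d2) + 1L)  # counts[s + 1] = #assignments with 2W+ = s
    counts[1L] <- 1
    for (rk in d2) {
      shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    total <- 2^m
    obs <- as.integer(round(2 * w_pos))
    p_lower <- sum(counts[seq_len(obs + 1L)]) / total
    p_upper <- sum(counts[(obs + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (stat - mu + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal"
  }
  list(statistic = stat, p_two_sided = p, n_effective = m,
       w_pos = w_pos, w_neg = w_neg, method = method, degenerate = FALSE)
}

# Pull one reported measure out of a metric_result list.
measure_vector <- function(metrics, measure) {
  field <- switch(measure, sensitivity = "sensitivity_pct", ppv = "ppv_pct")
  vapply(metrics, `[[`, numeric(1), field)
}

#' Compare two strategies question by question
#'
#' Both metric lists must cover the same questions at the same cutoff.
#' Differences are judged on the reported one-decimal percentages, so
#' questions that differ only below reporting precision count as stable.
#' Zero-yield counts are the number of questions for which the strategy
#' found nothing relevant within the cutoff.  A paired Wilcoxon
#' signed-rank test of b versus a is attached.
#'
#' @param metrics_a,metrics_b lists of [evaluate()] results, one per
#'   question, for the reference strategy (a) and the contrast (b).
#' @param measure `"sensitivity"` or `"ppv"`.
#' @return object of class `comparison_report`: labels, counts
#'   `n_increased` / `n_stable` / `n_decreased` (b vs a),
#'   `zero_yield_a` / `zero_yield_b`, and the `wilcoxon` result.
#' @export
compare_strategies <- function(metrics_a, metrics_b,
                               measure = c("sensitivity", "ppv")) {
  measure <- match.arg(measure)
  qa <- vapply(metrics_a, `[[`, character(1), "question_id")
  qb <- vapply(metrics_b, `[[`, character(1), "question_id")
  if (length(qa) == 0 || !setequal(qa, qb) || anyDuplicated(qa) ||
      anyDuplicated(qb)) {
    abort("the two metric lists must cover the same set of questions",
          "mismatched_questions")
  }
  metrics_b <- metrics_b[match(qa, qb)]
  a <- measure_vector(metrics_a, measure)
  b <- measure_vector(metrics_b, measure)
  rel_a <- vapply(metrics_a, `[[`, numeric(1), "n_relevant_retrieved")
  rel_b <- vapply(metrics_b, `[[`, numeric(1), "n_relevant_retrieved")
  structure(
    list(
      strategy_a = metrics_a[[1]]$strategy_id,
      strategy_b = metrics_b[[1]]$strategy_id,
      measure = measure,
      n_questions = length(qa),
      n_increased = sum(b > a),
      n_stable = sum(b == a),
      n_decreased = sum(b < a),
      zero_yield_a = sum(rel_a == 0),
      zero_yield_b = sum(rel_b == 0),
      wilcoxon = wilcoxon_signed_rank(a, b)
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %s vs %s (%s): %d increased / %d stable / %d decreased of %d questions\n",
    x$strategy_b, x$strategy_a, x$measure,
    x$n_increased, x$n_stable, x$n_decreased, x$n_questions
  ))
  cat(sprintf("  zero-yield: %d (%s) -> %d (%s)\n",
              x$zero_yield_a, x$strategy_a, x$zero_yield_b, x$strategy_b))
  cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.4g (%s, n_eff = %d)\n",
              x$wilcoxon$statistic, x$wilcoxon$p_two_sided,
              x$wilcoxon$method, x$wilcoxon$n_effective))
  invisible(x)
}

#' Summarise one strategy across questions
#'
#' Medians and interquartile ranges of the per-question output sizes,
#' sensitivities and PPVs, plus the median number needed to read derived
#' from the median PPV.
#'
#' @param metrics list of [evaluate()] results for one strategy, one per
#'   question.
#' @param output_sizes optional numeric vector of full output sizes per
#'   question (for the hits column).
#' @return object of class `strategy_summary` (a one-row data frame) with
#'   columns `strategy_id`, `n_questions`, `hits_median`, `hits_q1`,
#'   `hits_q3`, `sens_median`, `sens_q1`, `sens_q3`, `ppv_median`,
#'   `ppv_q1`, `ppv_q3`, `nnr_median`.
#' @export
summarize_strategy <- function(metrics, output_sizes = NULL) {
  if (length(metrics) < 1) {
    abort("summarize_strategy() needs at least one question", "invalid_input")
  }
  sens <- median_iqr(measure_vector(metrics, "sensitivity"))
  ppv <- median_iqr(measure_vector(metrics, "ppv"))
  hits <- if (is.null(output_sizes)) c(median = NA_real_, q1 = NA_real_,
                                       q3 = NA_real_) else median_iqr(output_sizes)
  out <- data.frame(
    strategy_id = metrics[[1]]$strategy_id,
    n_questions = length(metrics),
    hits_median = hits[["median"]], hits_q1 = hits[["q1"]],
    hits_q3 = hits[["q3"]],
    sens_median = sens[["median"]], sens_q1 = sens[["q1"]],
    sens_q3 = sens[["q3"]],
    ppv_median = ppv[["median"]], ppv_q1 = ppv[["q1"]],
    ppv_q3 = ppv[["q3"]],
    nnr_median = if (ppv[["median"]] > 0) nnr(ppv[["median"]] / 100) else NA_integer_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("strategy_summary", class(out))
  out
}

#' Median cumulative sensitivity curve across questions
#'
#' The per-rank median of the per-question cumulative sensitivity curves:
#' how the typical search's recall grows with the number of items
#' screened.
#'
#' @param outputs list of [ranked_output()], one per question.
#' @param golds list of [gold_standard()] covering the same questions.
#' @param max_rank largest screening depth.
#' @return numeric vector of length `max_rank` of median sensitivities.
#' @export
median_cumulative_curve <- function(outputs, golds, max_rank) {
  qo <- vapply(outputs, `[[`, character(1), "question_id")
  qg <- vapply(golds, `[[`, character(1), "question_id")
  if (!setequal(qo, qg) || anyDuplicated(qo) || anyDuplicated(qg)) {
    abort("outputs and golds must cover the same set of questions",
          "mismatched_questions")
  }
  golds <- golds[match(qo, qg)]
  curves <- mapply(cumulative_curve, outputs, golds,
                   MoreArgs = list(max_rank = max_rank))
  apply(matrix(curves, nrow = max_rank), 1, stats::median)
}
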