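# Seeded simulator of complete evaluation studies: per-question gold
# standards (included trials, of which a random subset is PubMed-indexed)
# plus per-strategy ranked outputs with the statistical structure the
# evaluation assumes — retention of relevant trials by query and filter,
# right-skewed output sizes, and concentration of relevant items toward
# the early ranks for specificity-maximising filters.

#' Describe the output process of one simulated strategy
#'
#' @param strategy_id label.
#' @param query_retention probability that an indexed gold article matches
#'   the base query (appears anywhere in the unfiltered output).
#' @param filter_retention probability that a query-matched gold article
#'   survives the methodological filter / limits (1 for no filter).
#' @param size_log_mean,size_log_sd meanlog/sdlog of the log-normal count
#'   of nonrelevant articles in the output (rounded, floored at 0);
#'   `size_log_mean = log(m)` puts the size median near `m`.
#' @param rank_concentration lambda >= 0: relevant items are placed at
#'   positions sampled without replacement with weight proportional to
#'   exp(-lambda * u), u the fractional position.  0 = uniform placement;
#'   larger values pull relevant articles toward the first pages.
#' @return object of class `output_model`.
#' @export
output_model <- function(strategy_id, query_retention, filter_retention = 1,
                         size_log_mean, size_log_sd = 1,
                         rank_concentration = 0) {
  for (p in c(query_retention, filter_retention)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      abort("retention probabilities must lie in [0, 1]", "invalid_config")
    }
  }
  if (rank_concentration < 0) {
    abort("rank_concentration must be >= 0", "invalid_config")
  }
  structure(
    list(strategy_id = as.character(strategy_id),
         query_retention = query_retention,
         filter_retention = filter_retention,
         size_log_mean = size_log_mean, size_log_sd = size_log_sd,
         rank_concentration = rank_concentration),
    class = "output_model"
  )
}

#' Assemble a simulation configuration
#'
#' @param n_questions number of clinical questions to simulate.
#' @param gold_size_log_mean,gold_size_log_sd log-normal parameters for
#'   the number of studies included in a review (rounded, floored at 4 —
#'   reviews with fewer than 4 studies are not usable gold standards).
#' @param indexing_prob probability that an included study is
#'   PubMed-indexed (at least one indexed study is guaranteed per
#'   question, since an all-unindexed gold standard is not evaluable).
#' @param output_models list of [output_model()] objects, one per
#'   simulated strategy.
#' @param seed root random seed; per-question streams are spawned from it
#'   so that adding questions does not perturb earlier ones.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_questions = 30,
                              gold_size_log_mean = log(14),
                              gold_size_log_sd = 0.7,
                              indexing_prob = 0.85,
                              output_models = default_output_models(),
                              seed = 20120612) {
  if (n_questions < 1) abort("n_questions must be >= 1", "invalid_config")
  if (!is.numeric(indexing_prob) || indexing_prob <= 0 || indexing_prob > 1) {
    abort("indexing_prob must lie in (0, 1]", "invalid_config")
  }
  if (length(output_models) < 1 ||
      !all(vapply(output_models, inherits, logical(1), "output_model"))) {
    abort("output_models must be a non-empty list of output_model objects",
          "invalid_config")
  }
  names(output_models) <- vapply(output_models, `[[`, character(1),
                                 "strategy_id")
  structure(
    list(n_questions = as.integer(n_questions),
         gold_size_log_mean = gold_size_log_mean,
         gold_size_log_sd = gold_size_log_sd,
         indexing_prob = indexing_prob,
         output_models = output_models,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default per-strategy output models
#'
#' One model per strategy of [strategy_grid()], calibrated once to the
#' benchmark study conditions: full-output retention about 0.85 for PIC
#' queries and 0.69 for PICO queries; the broad therapy filter keeps 99%
#' and the narrow filter 93% of query-matched trials; the Abridged Index
#' Medicus journal limit keeps roughly a fifth; output-size medians match
#' the observed per-strategy hit medians (173 unfiltered PIC down to 5
#' for narrow + AIM; hundreds for related-articles outputs); rank
#' concentration 0 for unfiltered searches, 1 broad, 4 narrow, 2 for
#' AIM-limited and related-articles outputs.
#'
#' @return named list of 15 [output_model()] objects, S1..S15.
#' @export
default_output_models <- function() {
  # strategy_id, query retention, filter retention, size median, lambda
  params <- list(
    list("S1",  0.85, 1.00, 173, 0),
    list("S2",  0.85, 0.99, 126, 1),
    list("S3",  0.85, 0.99,  97, 1),
    list("S4",  0.85, 0.93,  33, 4),
    list("S5",  0.85, 0.93,  31, 4),
    list("S6",  0.69, 1.00,  91, 0),
    list("S7",  0.69, 0.99,  75, 1),
    list("S8",  0.69, 0.99,  62, 1),
    list("S9",  0.69, 0.22,  11, 2),
    list("S10", 0.69, 0.93,  22, 4),
    list("S11", 0.69, 0.93,  20, 4),
    list("S12", 0.69, 0.21,   5, 2),
    list("S13", 0.60, 1.00, 350, 2),
    list("S14", 0.60, 1.00, 340, 2),
    list("S15", 0.60, 1.00, 305, 2)
  )
  models <- lapply(params, function(s) {
    output_model(s[[1]], query_retention = s[[2]], filter_retention = s[[3]],
                 size_log_mean = log(s[[4]]), size_log_sd = 1,
                 rank_concentration = s[[5]])
  })
  names(models) <- vapply(models, `[[`, character(1), "strategy_id")
  models
}

#' The default simulation configuration
#'
#' The packaged calibration: 30 questions; included-study counts
#' LogNormal(log 14, 0.7) floored at 4, which after 85% indexing yields a
#' median gold-standard size near 12 with IQR roughly 7-18; the
#' per-strategy output models of [default_output_models()]; a fixed
#' default seed.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
default_config <- function(...) {
  simulation_config(...)
}

# Sample the (1-based) positions of n_rel relevant items in an output of
# total length len, with weight exp(-lambda * u), u = position / len.
sample_relevant_positions <- function(len, n_rel, lambda) {
  if (n_rel == 0L) return(integer())
  if (lambda == 0) {
    return(sort(sample.int(len, n_rel)))
  }
  u <- seq_len(len) / len
  sort(sample.int(len, n_rel, prob = exp(-lambda * u)))
}

#' Simulate one question's gold standard and outputs
#'
#' Draws the number of included studies, marks each as PubMed-indexed
#' with probability `indexing_prob` (redrawing until at least one study
#' is indexed), then for each output model: each indexed gold article
#' enters the output with probability `query_retention *
#' filter_retention`; a log-normal count of freshly minted nonrelevant
#' articles is added; relevant articles are placed by the exponential
#' position-weight model.
#'
#' @param config a [simulation_config()].
#' @param question_index integer, used in identifiers.
#' @param seed seed for this question's private random stream.
#' @return list with `gold` (a [gold_standard()]), `outputs` (named list
#'   of [ranked_output()], one per model) and `truth` (realized draws:
#'   `n_included`, `n_indexed`, and per strategy `n_relevant_in_output`
#'   and `output_size`).
#' @export
simulate_question <- function(config, question_index, seed) {
  with_seed(seed, {
    qid <- sprintf("q%03d", question_index)
    n_included <- max(4L, as.integer(round(stats::rlnorm(
      1, config$gold_size_log_mean, config$gold_size_log_sd))))
    included <- sprintf("%s_a%04d", qid, seq_len(n_included))
    repeat {
      indexed_flag <- stats::runif(n_included) < config$indexing_prob
      if (any(indexed_flag)) break
    }
    indexed <- included[indexed_flag]
    gold <- gold_standard(qid, included, indexed)

    outputs <- list()
    truth_models <- list()
    for (model in config$output_models) {
      keep_p <- model$query_retention * model$filter_retention
      kept <- indexed[stats::runif(length(indexed)) < keep_p]
      n_rel <- length(kept)
      n_nonrel <- max(0L, as.integer(round(stats::rlnorm(
        1, model$size_log_mean, model$size_log_sd))))
      len <- n_rel + n_nonrel
      ids <- character(len)
      if (len > 0) {
        pos <- sample_relevant_positions(len, n_rel, model$rank_concentration)
        ids[pos] <- kept
        ids[-pos] <- sprintf("%s_%s_n%05d", qid, tolower(model$strategy_id),
                             seq_len(n_nonrel))
        if (n_rel == 0L) {
          ids <- sprintf("%s_%s_n%05d", qid, tolower(model$strategy_id),
                         seq_len(n_nonrel))
        }
      }
      outputs[[model$strategy_id]] <- ranked_output(qid, model$strategy_id,
                                                    ids)
      truth_models[[model$strategy_id]] <- list(
        n_relevant_in_output = n_rel, output_size = len)
    }
    list(
      gold = gold,
      outputs = outputs,
      truth = list(question_id = qid, n_included = n_included,
                   n_indexed = length(indexed), models = truth_models)
    )
  })
}

#' Simulate a complete evaluation study
#'
#' `n_questions` independent questions, each drawn from its own random
#' stream spawned from the root seed: extending the study with more
#' questions leaves the earlier questions byte-identical.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_study`: `config`, `questions` (list
#'   of [simulate_question()] results) and `truth` (the per-question truth
#'   records, for parameter-recovery checks).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("'config' must be a simulation_config", "invalid_config")
  }
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, config$n_questions))
  questions <- lapply(seq_len(config$n_questions), function(i) {
    simulate_question(config, i, seeds[i])
  })
  structure(
    list(config = config, questions = questions,
         truth = lapply(questions, `[[`, "truth")),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d questions x %d strategies (seed %d)\n",
    length(x$questions), length(x$config$output_models), x$config$seed
  ))
  invisible(x)
}
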