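# Shared generators and independent oracles for the test suite.

word_pool <- c("asthma", "chronic bronchitis", "COPD", "mucolytics",
               "placebo", "exacerbations", "beta blockers", "hypertension",
               "caffeine", "FEV1", "influenza", "vaccination",
               "proton pump inhibitors", "malaria", "artesunate")

random_terms <- function(n_max = 3, allow_empty = FALSE) {
  n <- sample.int(n_max, 1) - as.integer(allow_empty && stats::runif(1) < 0.4)
  if (n <= 0) return(character())
  sample(word_pool, n)
}

random_question <- function(id = "q") {
  pico_question(id,
    population = random_terms(),
    interventions = random_terms(),
    comparison = random_terms(allow_empty = TRUE),
    outcomes = random_terms()
  )
}

# Independent parenthesis-balance oracle: running bracket count.
count_parens_balanced <- function(text) {
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  depth_ok <- TRUE
  d <- 0L
  for (ch in strsplit(text, "")[[1]]) {
    d <- d + (ch == "(") - (ch == ")")
    if (d < 0) depth_ok <- FALSE
  }
  opens == closes && depth_ok
}

# Brute-force two-sided signed-rank p-value by enumerating every sign
# assignment (doubled ranks keep everything in integers under ties).
enum_signed_rank_p <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  r2 <- as.integer(round(2 * rank(abs(d))))
  m <- length(r2)
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
  w2 <- as.vector(signs %*% r2)
  obs <- sum(r2[d > 0])
  min(1, 2 * min(mean(w2 <= obs), mean(w2 >= obs)))
}

# Independent sort-and-interpolate quantile at position 1 + p(n-1).
interp_quantile <- function(values, p) {
  s <- sort(values)
  pos <- 1 + p * (length(s) - 1)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Random small evaluation instance: gold + ranked output with known overlap.
random_instance <- function(max_gold = 10, max_out = 60) {
  universe <- sprintf("id%03d", 1:120)
  gold_ids <- sample(universe, sample.int(max_gold, 1))
  out_ids <- sample(universe, sample.int(max_out, 1))
  list(
    gold = gold_standard("q", gold_ids),
    output = ranked_output("q", "S", out_ids)
  )
}

# Metric lists for the benchmark fixture's two strategies at a cutoff.
fixture_metrics <- function(dataset, fixture, strategy, cutoff) {
  lapply(seq_len(nrow(fixture)), function(i) {
    qid <- sprintf("q%02d", fixture$review_id[i])
    evaluate(dataset$outputs[[paste(qid, strategy, sep = ":")]],
             dataset$golds[[qid]], cutoff)
  })
}
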