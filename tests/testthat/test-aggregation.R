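test_that("median_iqr uses linear interpolation between order statistics", {
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  set.seed(21)
  for (i in 1:30) {
    v <- stats::rnorm(sample(2:40, 1))
    got <- median_iqr(v)
    expect_equal(got[["median"]], interp_quantile(v, 0.5))
    expect_equal(got[["q1"]], interp_quantile(v, 0.25))
    expect_equal(got[["q3"]], interp_quantile(v, 0.75))
    expect_lte(got[["q1"]], got[["median"]])
    expect_lte(got[["median"]], got[["q3"]])
  }
  expect_error(median_iqr(numeric()), class = "invalid_input")
})

test_that("benchmark medians reproduce the published strategy summaries", {
  fx <- load_benchmark_table()
  expect_equal(round_half_up(median_iqr(fx$s1_p2_sens)[["median"]]), 9.8)
  expect_equal(round_half_up(median_iqr(fx$s1_p2_ppv)[["median"]]), 2.5)
  expect_equal(round_half_up(median_iqr(fx$s4_p2_ppv)[["median"]]), 21.3)
})

test_that("signed-rank test: rank sums partition, exact branch matches enumeration", {
  set.seed(22)
  for (i in 1:40) {
    m <- sample(2:8, 1)
    # draw from a small integer grid so ties and zero differences occur
    x <- sample(0:5, m, replace = TRUE)
    y <- sample(0:5, m, replace = TRUE)
    if (all(y == x)) y[1] <- y[1] + 1
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$w_pos + w$w_neg,
                 w$n_effective * (w$n_effective + 1) / 2)
    expect_identical(w$method, "exact")
    expect_equal(w$p_two_sided, enum_signed_rank_p(x, y))
    # two-sided symmetry under swapping the pair
    expect_equal(wilcoxon_signed_rank(y, x)$p_two_sided, w$p_two_sided)
  }
})

test_that("signed-rank exact branch agrees with stats::wilcox.test on tie-free data", {
  set.seed(23)
  for (i in 1:20) {
    m <- sample(4:12, 1)
    x <- stats::rnorm(m)
    y <- stats::rnorm(m)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                               exact = TRUE))
    expect_equal(mine$p_two_sided, ref$p.value)
    expect_equal(mine$w_pos, unname(ref$statistic))
  }
})

test_that("signed-rank large-sample branch uses the tie-corrected normal approximation", {
  set.seed(24)
  x <- stats::rnorm(30)
  y <- x + stats::rnorm(30, mean = 0.5)
  w <- wilcoxon_signed_rank(x, y)
  expect_identical(w$method, "normal")
  # independent recomputation of the approximation
  d <- (y - x)[(y - x) != 0]
  r <- rank(abs(d))
  stat <- min(sum(r[d > 0]), sum(r[d < 0]))
  m <- length(d)
  ties <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  p_ref <- min(1, 2 * stats::pnorm((stat - m * (m + 1) / 4 + 0.5) /
                                     sqrt(sigma2)))
  expect_equal(w$p_two_sided, p_ref)
  # degenerate: identical pairs
  wd <- wilcoxon_signed_rank(x, x)
  expect_true(wd$degenerate)
  expect_equal(wd$p_two_sided, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), class = "invalid_input")
})

test_that("strategy comparison reproduces the published 21/6/3 split and zero-yield drop", {
  fx <- load_benchmark_table()
  ds <- fixture_to_dataset(fx)
  ms1 <- fixture_metrics(ds, fx, "S1", 40)
  ms4 <- fixture_metrics(ds, fx, "S4", 40)
  cr <- compare_strategies(ms1, ms4, "sensitivity")
  expect_equal(cr$n_increased, 21)
  expect_equal(cr$n_stable, 6)
  expect_equal(cr$n_decreased, 3)
  expect_equal(cr$zero_yield_a, 11)
  expect_equal(cr$zero_yield_b, 4)
  expect_lt(cr$wilcoxon$p_two_sided, 0.001)
  # self-comparison: everything stable
  self <- compare_strategies(ms1, ms1, "sensitivity")
  expect_equal(c(self$n_increased, self$n_stable, self$n_decreased),
               c(0, 30, 0))
  # counts are invariant to question order
  perm <- sample(seq_along(ms1))
  cr2 <- compare_strategies(ms1[perm], ms4[rev(perm)], "sensitivity")
  expect_equal(cr2$n_increased, cr$n_increased)
  expect_equal(cr2$n_stable, cr$n_stable)
  expect_equal(cr2$n_decreased, cr$n_decreased)
  expect_error(compare_strategies(ms1[-1], ms4, "sensitivity"),
               class = "mismatched_questions")
})

test_that("strategy summaries assemble medians, IQRs and the derived NNR", {
  fx <- load_benchmark_table()
  ds <- fixture_to_dataset(fx)
  sm <- summarize_strategy(fixture_metrics(ds, fx, "S1", 40))
  expect_equal(round_half_up(sm$ppv_median), 2.5)
  expect_equal(sm$nnr_median, 40L)
  expect_equal(round_half_up(sm$sens_median), 9.8)
  sm4 <- summarize_strategy(fixture_metrics(ds, fx, "S4", 40))
  expect_equal(round_half_up(sm4$ppv_median), 21.3)
  # single question: the summary is that question's values
  one <- fixture_metrics(ds, fx, "S1", 40)[17]
  sm1 <- summarize_strategy(one)
  expect_equal(sm1$sens_median, one[[1]]$sensitivity_pct)
  expect_equal(sm1$sens_q1, sm1$sens_q3)
})

test_that("median cumulative curves are medians of per-question curves", {
  g <- gold_standard("q1", c("a", "b"))
  o <- ranked_output("q1", "S", c("x", "a", "y", "b"))
  # all questions identical: the median curve is the single-question curve
  golds <- list(g, gold_standard("q2", c("a", "b")))
  outs <- list(o, ranked_output("q2", "S", c("x", "a", "y", "b")))
  expect_equal(median_cumulative_curve(outs, golds, 4),
               cumulative_curve(o, g, 4))
  set.seed(25)
  insts <- replicate(7, random_instance(), simplify = FALSE)
  golds <- lapply(seq_along(insts), function(i) {
    g <- insts[[i]]$gold; g$question_id <- paste0("q", i); g
  })
  outs <- lapply(seq_along(insts), function(i) {
    o <- insts[[i]]$output; o$question_id <- paste0("q", i); o
  })
  curve <- median_cumulative_curve(outs, golds, 45)
  expect_true(all(diff(curve) >= 0))
  # element at k = 40 equals the median of per-question sensitivity@40
  sens40 <- vapply(seq_along(outs), function(i)
    evaluate(outs[[i]], golds[[i]], 40)$sensitivity_pct, numeric(1))
  expect_equal(curve[40], stats::median(sens40))
})
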