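test_that("category clauses OR terms, parenthesize multiword terms only", {
  expect_identical(build_category_clause(c("chronic bronchitis", "COPD")),
                   "((chronic bronchitis) OR COPD)")
  expect_identical(build_category_clause("mucolytics"), "mucolytics")
  expect_identical(build_category_clause("chronic bronchitis"),
                   "(chronic bronchitis)")
  expect_identical(build_category_clause("beta-blocker"), "beta-blocker")
  expect_identical(build_category_clause(character()), "")
  expect_identical(build_category_clause("  spaced   out  term "),
                   "(spaced out term)")
  expect_error(build_category_clause(c("ok", "   ")), class = "invalid_term")
})

test_that("queries AND categories in PICO order; PIC drops outcomes; empty comparison omitted", {
  q <- pico_question("copd",
    population = c("chronic bronchitis", "COPD"),
    interventions = "mucolytics", comparison = "placebo",
    outcomes = "exacerbations")
  expect_identical(
    compose_query(q, "PICO")$text,
    "((chronic bronchitis) OR COPD) AND mucolytics AND placebo AND exacerbations")
  expect_identical(
    compose_query(q, "PIC")$text,
    "((chronic bronchitis) OR COPD) AND mucolytics AND placebo")
  q2 <- pico_question("asthma", population = "asthma",
                      interventions = "caffeine", outcomes = "FEV1")
  expect_identical(compose_query(q2, "PICO")$text,
                   "asthma AND caffeine AND FEV1")
  expect_error(pico_question("bad", population = character(),
                             interventions = "x"),
               class = "invalid_question")
  expect_error(pico_question("bad", population = "x",
                             interventions = " "),
               class = "invalid_term")
})

test_that("the strategy grid matches the 15-strategy design", {
  grid <- strategy_grid()
  expect_equal(nrow(grid), 15)
  expect_identical(grid$strategy_id, paste0("S", 1:15))
  expect_identical(grid$query_form,
                   c(rep("PIC", 5), rep("PICO", 7), rep("RELATED", 3)))
  s9 <- grid[grid$strategy_id == "S9", ]
  expect_identical(s9$cq_filter, "therapy_broad")
  expect_identical(s9$limits[[1]], c("english", "human", "aim"))
  s10 <- grid[grid$strategy_id == "S10", ]
  expect_identical(s10$cq_filter, "therapy_narrow")
  expect_length(s10$limits[[1]], 0)
  # seed rank present iff RELATED; RELATED rows unfiltered and unlimited
  expect_identical(!is.na(grid$related_seed_rank),
                   grid$query_form == "RELATED")
  rel <- grid[grid$query_form == "RELATED", ]
  expect_identical(rel$related_seed_rank, 1:3)
  expect_true(all(rel$cq_filter == "none"))
  expect_true(all(lengths(rel$limits) == 0))
  # AIM only ever appears on top of the english + human limits
  has_aim <- vapply(grid$limits, function(l) "aim" %in% l, logical(1))
  expect_true(all(vapply(grid$limits[has_aim], function(l)
    all(c("english", "human") %in% l), logical(1))))
})

test_that("strategy rendering appends filter, limit and date clauses", {
  q <- pico_question("copd",
    population = c("chronic bronchitis", "COPD"),
    interventions = "mucolytics", comparison = "placebo",
    outcomes = "exacerbations")
  grid <- strategy_grid()
  row <- function(id) grid[grid$strategy_id == id, ]
  base_pic <- compose_query(q, "PIC")
  base_pico <- compose_query(q, "PICO")

  expect_identical(render_strategy_query(base_pic, row("S1"))$text,
                   base_pic$text)
  expect_identical(
    render_strategy_query(base_pic, row("S4"))$text,
    paste0(base_pic$text,
           " AND (randomized controlled trial[Publication Type] OR",
           " (randomized[Title/Abstract] AND controlled[Title/Abstract]",
           " AND trial[Title/Abstract]))"))
  # narrow filter + 3 limits = 4 appended AND-conjuncts
  r12 <- render_strategy_query(base_pico, row("S12"))
  expect_length(searcheval:::split_top_level_and(r12$text),
                length(searcheval:::split_top_level_and(base_pico$text)) + 4)
  # date cap rendered as a publication-date range
  capped <- compose_query(q, "PIC", date_cap = "2010-02-28")
  rc <- render_strategy_query(capped, row("S1"))
  expect_match(rc$text,
               "AND \\(1900/01/01\\[Date - Publication\\] : 2010/02/28\\[Date - Publication\\]\\)$")
  expect_error(render_strategy_query(base_pic, row("S13")),
               class = "unsupported_strategy")
  expect_error(render_strategy_query(base_pic, row("S10")),
               class = "form_mismatch")
})

test_that("rendered queries are balanced, round-trip, and nest by added limits", {
  grid <- strategy_grid()
  renderable <- grid[grid$query_form != "RELATED", ]
  set.seed(42)
  for (rep in 1:25) {
    q <- random_question(sprintf("q%02d", rep))
    for (i in seq_len(nrow(renderable))) {
      strat <- renderable[i, ]
      base <- compose_query(q, strat$query_form)
      rendered <- render_strategy_query(base, strat)
      expect_true(count_parens_balanced(rendered$text))
      # round-trip: top-level AND split recovers category + appended clauses
      clauses <- searcheval:::split_top_level_and(rendered$text)
      n_appended <- (strat$cq_filter != "none") + length(strat$limits[[1]])
      base_clauses <- searcheval:::split_top_level_and(base$text)
      expect_identical(clauses[seq_along(base_clauses)], base_clauses)
      expect_length(clauses, length(base_clauses) + n_appended)
    }
    # strategies differing only by added limits: lesser text is a prefix
    for (pair in list(c("S2", "S3"), c("S4", "S5"), c("S7", "S8"),
                      c("S8", "S9"), c("S10", "S11"), c("S11", "S12"))) {
      a <- grid[grid$strategy_id == pair[1], ]
      b <- grid[grid$strategy_id == pair[2], ]
      base <- compose_query(q, a$query_form)
      ta <- render_strategy_query(base, a)$text
      tb <- render_strategy_query(base, b)$text
      expect_identical(substr(tb, 1, nchar(ta)), ta)
    }
  }
})

test_that("PICO question files round-trip through JSON and YAML", {
  recs <- list(
    list(question_id = "q1", population = list("asthma"),
         interventions = list("caffeine"), comparison = list(),
         outcomes = list("FEV1")),
    list(question_id = "q2",
         population = list("chronic bronchitis", "COPD"),
         interventions = list("mucolytics"))
  )
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(recs, jf, auto_unbox = TRUE)
  qs <- read_pico_questions(jf)
  expect_length(qs, 2)
  expect_identical(qs[[1]]$outcomes, "FEV1")
  expect_length(qs[[2]]$comparison, 0)
  yf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(recs, yf)
  qs2 <- read_pico_questions(yf)
  expect_identical(qs2[[2]]$population, c("chronic bronchitis", "COPD"))
})
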