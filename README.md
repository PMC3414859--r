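# searcheval

Clinicians who search PubMed at the point of care rarely screen more than
the first two results pages — about 40 items.  `searcheval` measures how
well different search strategies surface the clinical trials a systematic
review would have included, within that realistic screening budget.

The package covers the whole evaluation pipeline:

* **Query construction.** Structured PICO questions (population,
  interventions, comparison, outcomes) are turned into PubMed-dialect
  Boolean queries: terms are OR-ed within a category, categories AND-ed
  together, multiword terms wrapped in parentheses (never quotes).  A
  grid of 15 point-of-care strategies crosses the query form (PIC or
  full PICO) with the Clinical Queries therapy filters (broad or
  narrow), search limits (English, humans, the Abridged Index Medicus
  journal subset), and related-articles seeds.
* **Retrieval metrics.** For a ranked output *O* screened to depth
  *k* = min(cutoff, |O|) against a gold standard *G* (the review's
  included trials that are indexed in PubMed):

  sensitivity = |O₁..ₖ ∩ G| / |G|,  PPV = |O₁..ₖ ∩ G| / k,  NNR = round(1 / PPV).

  The PPV denominator is the number of items actually screened, not the
  nominal cutoff.  Cumulative sensitivity curves trace recall as a
  function of screening depth.
* **Aggregation.** Per-strategy median/IQR summaries over questions,
  increased/stable/decreased counts, zero-yield risk, and paired
  Wilcoxon signed-rank tests (exact by full sign-assignment enumeration
  up to 12 nonzero differences, tie-corrected normal approximation with
  continuity correction beyond).
* **Synthetic data.** A seeded simulator draws gold standards and
  per-strategy ranked outputs with configurable retention, output-size
  and rank-concentration parameters, so the whole pipeline runs and is
  testable without any network access.
* **Benchmark fixture.** A packaged transcription of a published
  30-question benchmark (Cochrane reviews vs. an unfiltered and a
  narrow-filtered PIC strategy) used for worked examples and validation.

## Worked example

```r
library(searcheval)

q <- pico_question("copd-mucolytics",
  population    = c("chronic bronchitis", "COPD"),
  interventions = "mucolytics",
  comparison    = "placebo",
  outcomes      = "exacerbations")
compose_query(q, "PICO")$text
#> [1] "((chronic bronchitis) OR COPD) AND mucolytics AND placebo AND exacerbations"

grid <- strategy_grid()
render_strategy_query(compose_query(q, "PIC"),
                      grid[grid$strategy_id == "S4", ])$text
#> [1] "((chronic bronchitis) OR COPD) AND mucolytics AND placebo AND
#>  (randomized controlled trial[Publication Type] OR (randomized[Title/Abstract]
#>  AND controlled[Title/Abstract] AND trial[Title/Abstract]))"

# score the packaged 30-question benchmark
ds <- fixture_to_dataset(load_benchmark_table())
bundle <- run_pipeline(ds, cutoffs = list(40, "full"),
                       comparisons = list(c("S1", "S4")))
bundle$comparisons$S1_vs_S4
#> <comparison_report> S4 vs S1 (sensitivity): 21 increased / 6 stable / 3 decreased of 30 questions
#>   zero-yield: 11 (S1) -> 4 (S4)
#>   Wilcoxon signed-rank: V = 22, p = 0.0002692 (normal, n_eff = 24)
```

Adding the Clinical Queries narrow filter to an unfiltered PIC query
raised 2-page sensitivity for 21 of the 30 questions, left 6 unchanged
and lowered 3, and cut the number of questions yielding *nothing*
relevant in the first two pages from 11 to 4 — the filter concentrates
the relevant trials onto the first pages, trading a little full-output
recall for much better recall within a realistic screening budget.

A fully synthetic run works the same way:

```r
study <- simulate_study(default_config(n_questions = 30))
bundle <- run_pipeline(as_study_dataset(study),
                       comparisons = list(c("S1", "S4")))
```

## Scope

The package evaluates ranked outputs it is given (or simulates); it does
not execute live PubMed searches.  The pluggable adapter contract
(`offline_search_adapter()`) documents where a live E-utilities client
would slot in, but none is shipped and none is needed for any test.
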