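---
title: "Evaluating point-of-care PubMed search strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating point-of-care PubMed search strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searcheval)
```

## The evaluation model

A systematic review of a focused clinical question is, for evaluation
purposes, a complete enumeration of the relevant trials: its inclusion
process is far more thorough than any single database query.
`searcheval` therefore scores a PubMed search strategy for a question by
how many of the review's included trials it surfaces — restricted to the
trials actually indexed in PubMed, because no query can retrieve a study
the database does not hold.

For a gold standard $G$ (the indexed included trials) and a ranked,
deduplicated output $O$ screened to depth $k = \min(c, |O|)$ at cutoff
$c$:

$$\mathrm{sensitivity}@c = \frac{|O_{1..k} \cap G|}{|G|}, \qquad
  \mathrm{PPV}@c = \frac{|O_{1..k} \cap G|}{k}, \qquad
  \mathrm{NNR} = \mathrm{round}\!\left(\frac{1}{\mathrm{PPV}}\right).$$

Two conventions matter and are easy to get wrong:

* **The PPV denominator is what was screened**, $\min(c, |O|)$, never
  the nominal cutoff.  A 12-item output screened at cutoff 40 has
  denominator 12.  This is regression-tested against a brute-force
  intersection oracle.
* **Percentages are reported to one decimal, rounding half away from
  zero**; internal arithmetic keeps full precision.  Cross-question
  comparisons (increased / stable / decreased) are made on the reported
  one-decimal scale, so differences below reporting precision count as
  stable — this is required to reproduce the benchmark's published
  21/6/3 split, and matches how a reader of the printed table would
  count.

The default cutoff of 40 items is the "two pages of PubMed output" most
clinicians will actually screen; full-output metrics and cumulative
sensitivity curves (`cumulative_curve()`) describe what deeper screening
would buy.

## Query construction

Queries follow the PICO discipline: within a category, terms are joined
with OR (sensitivity); categories are joined with AND (precision).
Multiword terms are wrapped in parentheses rather than quotes so that
PubMed's automatic term mapping still expands each word group; the
package performs no term mapping or MeSH expansion of its own, since
PubMed does that server-side.  The truncated PIC form drops the outcomes
clause — outcomes are the element least reliably present in abstracts —
and an empty comparison category is silently omitted (for about half of
review questions the comparison shares its terms with the intervention
and no separate term is retained).

The Clinical Queries therapy filter texts are **configuration, not
constants** (`filter_config()`): PubMed has revised them over time.  The
packaged default carries the 2005-revision wording (narrow:
`randomized controlled trial[Publication Type] OR (randomized[Title/Abstract]
AND controlled[Title/Abstract] AND trial[Title/Abstract])`; broad: the
six-clause sensitivity-maximising disjunction) plus the usual limit
expansions (`English[lang]`, `humans[MeSH Terms]`, `jsubsetaim`).  A
date cap is rendered as a publication-date range from 1900/01/01 to the
cap date, matching how a searcher would restrict a query to the period a
review covers.  Related-articles strategies (S13–S15 in
`strategy_grid()`) have no query text at all: their ranked outputs come
from PubMed's similarity engine (or the simulator) and are supplied to
the evaluator directly.

## The Wilcoxon signed-rank test

Strategy pairs are compared per question with a paired Wilcoxon
signed-rank test.  Zero differences are dropped (the classical
treatment; the Pratt variant, which ranks zeros before discarding them,
is not implemented — the choice is documented here because the two can
disagree near significance thresholds).  Absolute differences are ranked
with average ranks for ties, and the statistic is the smaller of the
positive- and negative-rank sums.

With at most 12 nonzero differences the two-sided p-value is exact: the
null distribution of the positive-rank sum over all $2^n$ sign
assignments is built by a dynamic-programming convolution over doubled
ranks (doubling keeps average-rank ties in integer arithmetic), and the
tests verify it against a literal enumeration of every sign assignment.
Beyond 12 pairs the normal approximation is used, with tie-corrected
variance $n(n+1)(2n+1)/24 - \sum(t^3 - t)/48$ and a 0.5 continuity
correction.  The threshold of 12 keeps the exact branch instantaneous
while the approximation error at $n > 12$ is already far below any
decision boundary used here.  No multiple-testing adjustment is applied:
comparisons are reported as raw paired p-values, mirroring how such
benchmark comparisons are conventionally presented.

Quantile summaries use linear interpolation at position $1 + p(n-1)$
(`quantile(type = 7)`); this convention reproduces the benchmark's
printed interquartile ranges exactly.

## What the simulator emulates

`simulate_study()` generates the data structure the pipeline consumes —
per-question gold standards plus per-strategy ranked outputs — with the
statistical features that drive the real evaluation:

* **Gold-standard sizes.** Included-study counts are
  LogNormal(log 14, 0.7), rounded and floored at 4 (reviews with fewer
  than 4 studies are not useful gold standards); each study is
  PubMed-indexed with probability 0.85.  This calibration gives a median
  gold size of about 12 with IQR roughly 7–18, matching the benchmark's
  observed distribution.  Log-normals are used throughout because the
  observed count distributions are strongly right-skewed.
* **Retention.** An indexed gold article enters a strategy's output with
  probability `query_retention * filter_retention`.  Defaults: 0.85 for
  PIC queries, 0.69 for PICO (outcome terms miss some trials), filter
  retention 0.99 for the broad and 0.93 for the narrow therapy filter,
  about 0.2 for the core-journal (AIM) limit.  Retention is a fixed
  probability, not question-varying — the benchmark reports no
  dispersion for it.
* **Output sizes.** Nonrelevant counts are log-normal with medians set
  to the observed per-strategy hit medians (173 for unfiltered PIC down
  to 5 for narrow + AIM; 300–350 for related-articles outputs) and
  sdlog 1.
* **Rank concentration.** Relevant items are placed at positions drawn
  without replacement with weight $\propto e^{-\lambda u}$, $u$ the
  fractional position.  $\lambda = 0$ is uniform placement; larger
  $\lambda$ pulls relevant articles toward the first pages.  Defaults:
  0 for unfiltered searches, 1 broad, 4 narrow, 2 for AIM-limited and
  related-articles outputs.  One parameter is the simplest mechanism
  that reproduces the qualitative signature of specificity-maximising
  filters: *higher* 2-page sensitivity despite *lower* full-output
  sensitivity.

Randomness is organised as a root seed spawning one private stream per
question, so extending a study with more questions leaves the earlier
questions byte-identical.

The simulator does **not** model query text, MeSH indexing, content
similarity, per-article covariates, or cross-question article overlap
(each question's nonrelevant universe is disjoint).  Passing simulation
tests therefore validate the pipeline's arithmetic and the direction of
filter effects under the stated generative assumptions — they say
nothing about how any particular live query would perform against
today's PubMed.

## The packaged benchmark

`load_benchmark_table()` ships a transcription of a published
30-question benchmark: per question, the number of included and
PubMed-retrievable studies and the full-output and 2-page sensitivity
and PPV of an unfiltered (S1) and a narrow-filtered (S4) PIC strategy,
as 1-decimal percentages.  Integer retrieval counts are derived at load
time as `round(pct × denominator / 100)` and checked to round back to
the printed value; the file itself is integrity-checked against an
embedded digest.

`fixture_to_dataset()` expands the table into *synthetic* gold standards
and ranked outputs whose scores reproduce every printed percentage:
output length comes from the full-output PPV, the 2-page relevant
articles occupy the earliest ranks, the remaining relevant articles sit
just beyond rank 40.  Identifiers are synthetic; only membership and
rank structure are meaningful.  This reconstruction is what lets worked
examples and the comparison statistics (21 improved / 6 stable / 3
decreased; zero-yield 11 → 4; p < .001) be recomputed through the same
code path as any user dataset.

One transcription caveat, kept deliberately: the source's per-strategy
summary prints a 2-page sensitivity median of 48.5 for the
narrow-filtered strategy, while the median of its own 30 printed
per-question values is 52.8.  The fixture-based tests target only the
internally consistent cells (the unfiltered strategy's sensitivity and
PPV medians and the narrow strategy's PPV median); the per-question
table is not "corrected" to force the summary value.

## Degenerate inputs and numerical choices

* An empty output is scored sensitivity 0 / PPV 0 with a `degenerate`
  flag rather than an error — real searches can return nothing.
* A gold standard with no indexed article is not evaluable and raises.
* NNR is undefined at PPV 0 and raises a classed error.
* Duplicate identifiers in an incoming ranked list are deduplicated
  keeping the best rank; identifiers are opaque strings compared after
  trimming (leading zeros preserved).
* All randomised tests in the suite run at sizes chosen for desk-scale
  runtimes (500 simulated questions for the Monte-Carlo recovery checks,
  2000 replicates for the placement check); the Monte-Carlo tolerances
  are three standard errors of the corresponding estimate.

## Known limitations

Binary relevance only (every included trial counts equally); no
deduplication across strategies; no modelling of the searcher's
iterative query refinement; the live-search adapter is a documented
contract (`offline_search_adapter()` shows the shape) with no shipped
E-utilities implementation, so conclusions about live PubMed require
supplying real outputs in the documented CSV schemas.
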