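# polsa

Phrase-ontology latent semantic analysis (POLSA) for literature-based
knowledge discovery in R.

`polsa` is for researchers who want to mine a large annotated abstract
corpus for *indirect* associations between biomedical concepts — the
kind a keyword search misses because no single abstract mentions both
concepts.  It builds a latent semantic space whose rows are multi-gram
dictionary terms compiled from a MeSH-style ontology and a gene-symbol
list, and whose columns are ontology headings (each pooling all
abstracts annotated with it), then ranks headings against free-text
queries and reads the result back onto the ontology hierarchy.

## The model

Given a term-by-heading count matrix *C* (obtained by greedy
longest-match multi-gram tokenization of abstracts), the semantic model
is built in three steps:

* **TF-IDF weighting** — `W[t,h] = C[t,h] · ln(H / df_t)`, with `df_t`
  the number of heading columns containing term *t*;
* **truncated SVD** — `W ≈ U_k S_k V_kᵀ`, with *k* the smallest rank
  whose cumulative squared singular values (spectral energy) reach 95%
  of the total;
* **cosine ranking** — a query pseudo-document *q* (idf weights at its
  resolved term rows) is folded in as `q̂ = qᵀU_k` and compared by
  cosine against the heading coordinates `V_k S_k`.

The resulting cosine distribution is partitioned by one-dimensional
fuzzy c-means (3 clusters, fuzzifier 2, deterministic percentile
initialization) into **highly associated / possibly associated /
unknown** groups with data-driven cutoffs (midpoints between cluster
centers, re-estimated per query).  Relevant headings are re-attached to
their ontology ancestor chains and exported as a collapsible D3
flare-style JSON hierarchy.

The package also ships a synthetic-data generator that emits a toy
ontology, gene-symbol list and JSONL corpus with *planted*
term-heading associations, so the whole pipeline is testable with no
external data; see the methods vignette
(`vignettes/polsa-methods.Rmd`) for the generative model and every
design decision.

## Worked example

Generate a small synthetic corpus with planted associations, fit the
model, and query one of the planted surfaces:

```r
library(polsa)

spec <- synthetic_spec(n_headings = 20, n_terms = 70, n_multigrams = 10,
                       n_records = 200, tokens_per_abstract = 60, seed = 42)
pipe <- run_synthetic_pipeline(spec)
pipe$model
#> <polsa_model> 70 terms x 20 headings, rank k = 13 (95.7% energy retained)

head(pipe$planted, 3)
#> # A tibble: 3 × 3
#>   query_surface target_heading_id strength
#>   <chr>         <chr>                <dbl>
#> 1 gs0044        SH0019                  25
#> 2 gs0040        SH0005                  25
#> 3 gs0004        SH0001                  25

grouped <- pipe$model |>
  query_model("gs0044", pipe$dictionary) |>
  assign_groups()
head(tidy(grouped), 5)
#> # A tibble: 5 × 7
#>   heading_id cosine  rank membership_unknown membership_possibly
#>   <chr>       <dbl> <int>              <dbl>               <dbl>
#> 1 SH0019      0.991     1           0.000458            0.000694
#> 2 SH0017      0.481     2           0.217               0.576
#> 3 SH0010      0.174     3           0.00678             0.993
#> 4 SH0016      0.132     4           0.156               0.840
#> 5 SH0002      0.128     5           0.189               0.807

build_network("gs0044", grouped, pipe$ontology)
#> <polsa_network> query 'gs0044', 5 relevant heading(s)
#> gs0044
#>   Technology
#>     device0001 [highly 0.9908]
#>   Chemicals and Drugs
#>     compound0007 [possibly 0.4813]
#>     compound0006 [possibly 0.1323]
#>   Diseases
#>     disorder0009
#>       disorder0010 [possibly 0.1739]
#>     disorder0002 [possibly 0.1277]
```

The planted target `SH0019` (the heading named `device0001`) is ranked
first with cosine 0.99 and lands in the *highly associated* group; the
remaining headings fall into *possibly* and *unknown* bands whose
boundaries were estimated from this query's own score distribution.
`network_to_json()` serializes the printed hierarchy for a collapsible
D3 view, and `autoplot()` methods draw the scree curve of the model,
the grouped ranking, and the network tree.

A command-line interface wrapping the same functions is installed at
`exec/polsa` with subcommands `synth`, `build` (config-driven:
ontology + gene symbols + corpus → model archive), `query`
(grouped ranking TSV, network JSON, top-N to stdout) and `precompute`
(cache every dictionary query; cache hits are byte-identical to fresh
computation).

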