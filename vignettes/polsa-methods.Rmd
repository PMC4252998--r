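---
title: "Phrase-ontology LSA for literature-based association discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phrase-ontology LSA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsa)
```

## The problem

Biomedical knowledge relevant to a question — is this drug associated
with pulmonary fibrosis? which disease concepts co-travel with this gene
symbol? — is scattered across millions of abstracts, and a keyword
search only surfaces *direct* co-mentions.  `polsa` implements a
pipeline that learns a latent semantic space over a controlled
vocabulary and uses it to rank ontology concepts against free-text
queries, surfacing indirect (higher-order) associations: concept A and
concept C can score highly even when no single abstract mentions both,
provided both co-occur with a shared set of intermediate terms.

The design is phrase-ontology latent semantic analysis (POLSA).
Ordinary LSA factorizes a term-by-document matrix; POLSA replaces both
axes with ontology-derived structure.  Rows are *multi-gram dictionary
terms* — headings, their entry-term synonyms (including comma-inverted
display forms such as "Scleroderma, Systemic" for *systemic
scleroderma*), and gene symbols — treated as single semantic units, so
"yellow virus fever" is one row, not three.  Columns are *ontology
headings*: all abstracts annotated with a heading are pooled into one
pseudo-document.  This keeps the column space small, interpretable, and
directly mappable back onto the ontology hierarchy.

## Pipeline and model

1. **Heading selection.** From a MeSH-style ontology, headings with an
   abstract count in the inclusive window \[1000, 50000\] are eligible
   (below: too specific; above: too general), restricted to categories
   C, D, F, G, I, J, M, N.  At least half of the selection must carry
   the Disease category (C); the constraint is a floor, enforced by
   dropping the lowest-count non-C headings.  Both bounds and the
   fraction are `select_headings()` arguments.

2. **Dictionary.** One term per selected heading (surfaces: all comma
   rotations of the preferred name and entry terms) plus one term per
   gene symbol.  Surface collisions resolve by source priority
   heading > entry term > gene symbol — ontology concepts anchor the
   space; symbols are a genetic-information layer on top.  Surfaces
   longer than `max_ngram = 6` tokens are left out of the matcher
   index.

3. **Counting.** Each abstract (title + abstract text) is normalized
   (lowercase, punctuation stripped, intra-token hyphens kept) and
   scanned with a greedy leftmost-longest matcher: at each position the
   longest indexed window is consumed, so a phrase absorbs its
   constituent words.  A record's term counts are added to the column
   of every selected heading it is annotated with, with no 1/k
   down-weighting — the simplest pooling consistent with
   heading-columns.  Annotation strings themselves are never injected
   as text; that would make the model circular.

4. **Weighting and decomposition.** `w[t,h] = c[t,h] * ln(H / df_t)` —
   raw term frequency times natural-log inverse document frequency, no
   sublinear damping, no column normalization.  The weighted matrix is
   factorized by SVD and truncated at the smallest rank `k` whose
   cumulative squared singular values reach `energy_threshold`
   (default 0.95).  "Energy" is Frobenius (spectral) energy
   `sigma_i^2`; this is the standard spectral-energy reading and makes
   a 95% cutoff well defined.  Heading coordinates are `V_k S_k`
   (document-coordinate convention), queries are folded in as
   `q' = q^T U_k` — so the singular-value weighting sits once, on the
   heading side.

5. **Query and ranking.** A query resolves through the surface index to
   term rows; the pseudo-document carries the idf weight at each
   resolved row (idf weighting keeps queries on the same scale as
   matrix columns; `query_idf_weighting = FALSE` gives raw
   indicators).  Cosine similarity against every heading vector,
   descending, ties broken by heading id.

6. **Relevance grouping.** One-dimensional fuzzy c-means (standard
   Bezdek iteration) with exactly three clusters partitions the cosine
   distribution into *highly associated*, *possibly associated* and
   *unknown*.  The cutoffs are data-driven: midpoints between adjacent
   converged centers, re-estimated for every query rather than fixed
   globally.  Final groups are assigned by cutoff interval, not raw
   argmax, so groups are contiguous in score.

7. **Reverse ontology mapping.** Relevant headings are re-attached
   under their full ancestor chains (one leaf per tree position in the
   polyhierarchy; `n_relevant` counts distinct headings), shared
   ancestors merge, children sort by best descendant cosine, and the
   hierarchy serializes deterministically as D3 flare-style JSON for
   collapsible rendering.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_abstracts`, `max_abstracts` | 1000, 50000 | inclusive abstract-count eligibility window (abstracts per heading) |
| `disease_fraction` | 0.5 | floor on the Disease-category share of the selection |
| `max_ngram` | 6 tokens | longest indexed surface; bounds the matcher window |
| `energy_threshold` | 0.95 | retained fraction of squared-singular-value energy |
| `query_idf_weighting` | TRUE | idf-weighted vs indicator query pseudo-documents |
| fuzzifier `m` | 2 | FCM softness; 2 is the standard choice |
| FCM `tolerance` | 1e-6 | convergence threshold on center movement |

FCM initialization is deterministic — centers start at the 10th, 50th
and 90th percentiles of the scores — so the whole pipeline is seedless
at query time and repeated runs are byte-identical.

## Numerical choices

* The energy cutoff compares cumulative fractions with a `1e-12`
  slack so that a threshold of exactly 1.0 retains precisely the
  numerical rank.
* A heading column that is all zero in the weighted matrix has a
  latent row that is zero only up to SVD round-off; its cosine is
  forced to 0, and any cosine below `1e-12` in magnitude is snapped to
  0 so that analytic zeros tie deterministically (broken by heading
  id).  Cosines are clipped to \[-1, 1\].
* In FCM, a score coinciding exactly with a center takes membership 1
  there (split equally across coinciding centers), the textbook
  singularity rule.  If the percentile init produces duplicate centers
  (heavily skewed score distributions), they are nudged apart
  deterministically by a `1e-6` fraction of the score range.
* Fewer than three distinct scores is a degenerate distribution:
  clustering refuses; `assign_groups(lenient = TRUE)` instead labels
  everything *unknown* with a warning.
* Model archives store factors as full-precision (`%.17g`) text, so a
  reloaded model reproduces rankings bit-for-bit.

## The synthetic-data generator

Because the corpus the method is designed for (decades of annotated
abstracts) cannot ship with a package, the `synthetic` module generates
all three inputs with known structure, in the same file dialects the
real readers consume; the generator's output *is* the test fixture.

The corpus model is occupancy-gated Poisson.  Each synthetic heading
belongs to one of `n_topics` topics; each surface inherits its linked
heading's topic (gene symbols draw one at random).  A surface is
*active* under every same-topic heading and under each other heading
independently with probability `background_occupancy = 0.3`; in records
of active headings it occurs `Poisson(background_rate)` times
(`topic_boost = 3` times that for same-topic headings), emitted as an
intact token unit and shuffled among unit boundaries so multi-gram
surfaces stay contiguous.  A planted pair overrides one surface's rate
in one target heading's records to `planted_rate`.  Records are padded
with out-of-dictionary filler tokens to `tokens_per_abstract`.

The occupancy gate matters: if every surface occurred everywhere, every
term's document frequency would equal the number of headings and every
idf — hence every query vector — would be zero.  Real terms appear
under topically related headings, which is exactly what the gate
emulates; the topic structure also gives the corpus a low-rank
co-occurrence backbone for the SVD to find.

The reference study conditions used by the tests and the acceptance
script are 100 headings (half Disease-category), 500 dictionary terms
including 50 multi-gram entry surfaces, 2000 records of 200 tokens,
10 planted pairs, `planted_rate = 5` against `background_rate = 0.2`
(strength 25).  Under these conditions the pipeline places the planted
target in the *highly associated* group for essentially every pair
across seeds.  What this shows — and does not show — about real data:
recovery demonstrates that the TF-IDF/SVD/cosine/FCM chain concentrates
and separates genuine co-occurrence signal at realistic sparsity; it
does not exercise ambiguous English phrasing, synonymy beyond the entry
terms, annotation noise, or temporal drift, none of which the generator
models.

## Design choices where the design was open

* **Comma rotations, not permutations**: entry-form inversion in
  MeSH-style vocabularies moves comma segments to the front;
  generating all rotations covers those forms with linearly many
  variants, where full permutations would explode.
* **Entry terms of non-selected headings contribute no surfaces**; the
  dictionary is strictly anchored on the modelled column space.
* **Ambiguous symbols** (a gene symbol identical to a concept surface)
  resolve by the source-priority rule alone; no context
  disambiguation is attempted.
* **Pooling into all annotated headings** (rather than one heading per
  record) is the simplest reading of heading-columns; the synthetic
  generator uses single annotations so planted attribution stays
  unambiguous, and multi-annotation pooling is pinned by hand-built
  fixtures in the tests.
* **Greedy leftmost-longest matching** rather than maximal-coverage
  tiling: linear time, standard gazetteer behaviour; an exhaustive
  tiling oracle in the test suite pins the semantics.
* **Precomputed query caches** are keyed by normalized surface plus a
  digest of the model manifest, so case variants hit the same entry
  and a rebuilt model invalidates every entry.

## Problem sizes in the test suite

Unit fixtures are hand-built (a six-heading ontology, two-column count
matrices); property checks run on 20-term x 10-heading random matrices
over ten seeds, 500 random matcher cases, and 20 random score vectors
for FCM.  End-to-end checks run the generator at the reference
conditions above across ten seeds, and smaller 20-heading corpora for
byte-level determinism checks of the build/query/precompute commands —
sizes chosen so each property is exercised at the scale where its
failure modes appear.

## Known limitations

* Heading abstract counts must be supplied (TSV column or annotation
  tallies); the XML reader alone cannot select headings.
* The SVD is computed densely; the intended column space (a few
  thousand headings) keeps this cheap, but the implementation is not
  suited to document-level columns in the millions.
* Relevance grouping assumes the cosine distribution supports three
  clusters; queries with essentially flat score distributions are
  reported as all-unknown rather than forced into groups.
* Association networks contain only hierarchy edges; no cross-links
  between headings beyond the ontology structure are inferred.
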