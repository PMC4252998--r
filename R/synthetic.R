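#' Specification for synthetic pipeline inputs
#'
#' Describes a synthetic ontology, dictionary and corpus with known
#' planted term-heading associations, so the whole pipeline can be
#' exercised and validated without any external download.  Token
#' occurrences follow an occupancy-gated Poisson model: each surface is
#' active only under a random subset of headings (probability
#' `background_occupancy` per heading, always under same-topic
#' headings), occurs in records of active headings at Poisson mean
#' `background_rate` (`topic_boost * background_rate` for same-topic
#' headings), and a planted surface occurs in records of its target
#' heading at `planted_rate`.  The occupancy gate mirrors real
#' literature, where a term appears under topically related headings
#' rather than uniformly: it keeps document frequencies below the
#' number of headings so inverse document frequency stays informative.
#' Poisson occurrence is the minimal generative structure under which
#' TF-IDF/LSA concentrates the planted signal; all rates are explicit
#' parameters.
#'
#' @param n_headings Number of selectable headings (>= 4).
#' @param n_terms Total dictionary terms: heading terms plus gene
#'   symbols (`n_terms - n_headings` symbols are generated).
#' @param n_multigrams Number of multi-token (2-3 gram) entry-term
#'   surfaces attached to headings.
#' @param n_records Number of abstract records.
#' @param n_topics Number of latent topics; each heading belongs to one,
#'   giving the corpus low-rank co-occurrence structure for the SVD to
#'   find.
#' @param n_planted Number of planted associations (used when
#'   `planted_pairs` is `NULL`).
#' @param planted_pairs Optional tibble (`query_surface`,
#'   `target_heading_id`) fixing the plants explicitly.
#' @param background_rate Poisson mean for baseline surface occurrences
#'   in records of headings the surface is active under.
#' @param planted_rate Poisson mean for a planted surface in its target
#'   heading's records; must exceed `background_rate`.
#' @param topic_boost Multiplier on `background_rate` for same-topic
#'   surfaces (default 3).
#' @param background_occupancy Probability that a surface is active
#'   under any given off-topic heading (default 0.3).
#' @param tokens_per_abstract Records are padded with out-of-dictionary
#'   filler tokens up to this length.
#' @param disease_fraction_target Fraction of headings placed in the
#'   Disease category C.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `polsa_synth_spec` list.
#' @export
synthetic_spec <- function(n_headings = 100L,
                           n_terms = 500L,
                           n_multigrams = 50L,
                           n_records = 2000L,
                           n_topics = 10L,
                           n_planted = 10L,
                           planted_pairs = NULL,
                           background_rate = 0.2,
                           planted_rate = 5,
                           topic_boost = 3,
                           background_occupancy = 0.3,
                           tokens_per_abstract = 200L,
                           disease_fraction_target = 0.5,
                           seed = 1L) {
  if (n_headings < 4L) {
    stop("synthetic_spec: n_headings must be at least 4", call. = FALSE)
  }
  if (n_terms <= n_headings) {
    stop("synthetic_spec: n_terms must exceed n_headings", call. = FALSE)
  }
  if (planted_rate <= background_rate) {
    stop("synthetic_spec: planted_rate must exceed background_rate",
      call. = FALSE
    )
  }
  stopifnot(
    disease_fraction_target > 0, disease_fraction_target <= 1,
    n_topics >= 1L, tokens_per_abstract >= 1L, seed == floor(seed),
    background_occupancy > 0, background_occupancy <= 1
  )
  structure(
    list(
      n_headings = as.integer(n_headings),
      n_terms = as.integer(n_terms),
      n_multigrams = as.integer(n_multigrams),
      n_records = as.integer(n_records),
      n_topics = as.integer(n_topics),
      n_planted = as.integer(n_planted),
      planted_pairs = planted_pairs,
      background_rate = background_rate,
      planted_rate = planted_rate,
      topic_boost = topic_boost,
      background_occupancy = background_occupancy,
      tokens_per_abstract = as.integer(tokens_per_abstract),
      disease_fraction_target = disease_fraction_target,
      seed = as.integer(seed)
    ),
    class = "polsa_synth_spec"
  )
}

#' Generate a synthetic ontology
#'
#' Builds a two-level heading tree under named category roots C
#' ("Diseases"), D ("Chemicals and Drugs") and J ("Technology"): at
#' least `disease_fraction_target` of the headings sit under C, every
#' fifth heading is nested one level deeper to give ancestor chains of
#' length three, and abstract counts are drawn uniformly inside the
#' default selection window so all generated headings are selectable.
#' The category roots themselves carry count 0, keeping them out of any
#' selection.  Multi-gram entry terms are attached round-robin to the
#' headings.
#'
#' @param spec A `polsa_synth_spec`.
#' @return List with `ontology` (a `polsa_ontology`), `selected`
#'   (heading ids from [select_headings()] under default configuration)
#'   and `gene_symbols` (character vector).
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "polsa_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_headings
  n_c <- max(1L, ceiling(spec$disease_fraction_target * n))
  n_j <- max(1L, floor((n - n_c) / 4))
  n_d <- n - n_c - n_j
  cats <- c(rep("C", n_c), rep("D", n_d), rep("J", n_j))
  stems <- c(C = "disorder", D = "compound", J = "device")
  roots <- c(C = "C01", D = "D01", J = "J01")
  root_names <- c(
    C = "Diseases", D = "Chemicals and Drugs", J = "Technology"
  )
  per_cat <- stats::setNames(integer(3), names(roots))
  tree_numbers <- character(n)
  names_ <- character(n)
  prev_tn <- stats::setNames(character(3), names(roots))
  for (i in seq_len(n)) {
    cat <- cats[i]
    per_cat[cat] <- per_cat[cat] + 1L
    names_[i] <- sprintf("%s%04d", stems[cat], per_cat[cat])
    base <- sprintf("%s.%03d", roots[cat], per_cat[cat])
    # every fifth heading in a category nests under the previous one
    if (per_cat[cat] %% 5L == 0L && nzchar(prev_tn[cat])) {
      tree_numbers[i] <- paste0(prev_tn[cat], ".001")
    } else {
      tree_numbers[i] <- base
      prev_tn[cat] <- base
    }
  }
  entry_terms <- rep(list(character(0)), n)
  glue_a <- c("chronic", "acute", "familial", "juvenile", "recurrent")
  glue_b <- c("syndrome", "deficiency", "complex", "response")
  for (j in seq_len(spec$n_multigrams)) {
    i <- ((j - 1L) %% n) + 1L
    mg <- if (j %% 2L == 0L) {
      paste(glue_a[(j %% 5L) + 1L], sprintf("cond%03d", j))
    } else {
      paste(
        glue_a[(j %% 5L) + 1L], sprintf("cond%03d", j),
        glue_b[(j %% 4L) + 1L]
      )
    }
    entry_terms[[i]] <- c(entry_terms[[i]], mg)
  }
  headings <- tibble::tibble(
    heading_id = c(
      sprintf("SH%04d", seq_len(n)),
      paste0("ROOT", names(roots))
    ),
    preferred_name = c(names_, unname(root_names)),
    entry_terms = c(entry_terms, rep(list(character(0)), 3)),
    tree_numbers = c(
      as.list(tree_numbers),
      as.list(unname(roots))
    ),
    abstract_count = c(
      sample(1000:50000, n, replace = TRUE),
      rep(0L, 3)
    )
  )
  ontology <- new_ontology(headings)
  selected <- select_headings(ontology,
    disease_fraction = spec$disease_fraction_target
  )
  gene_symbols <- sprintf("GS%04d", seq_len(spec$n_terms - n))
  list(ontology = ontology, selected = selected, gene_symbols = gene_symbols)
}

#' Generate a synthetic corpus with planted associations
#'
#' Draws one annotated heading per record (round-robin over the
#' selection, then shuffled), emits dictionary surfaces as intact token
#' units with Poisson counts under the rate model of [synthetic_spec()],
#' pads with unique filler tokens, and returns both the records and the
#' planted-association truth table.  Planted query surfaces are drawn
#' half from gene symbols and half from multi-gram heading variants
#' (never targeting the heading the surface itself links to).
#'
#' @param spec A `polsa_synth_spec`.
#' @param ontology The synthetic `polsa_ontology` (unused beyond
#'   validation; the dictionary fixes the surface set).
#' @param dictionary A `polsa_dictionary` built from the synthetic
#'   ontology and gene symbols.
#' @return List with `records` (tibble as from [read_corpus()]) and
#'   `planted` (tibble: `query_surface`, `target_heading_id`,
#'   `strength`).
#' @export
generate_corpus <- function(spec, ontology, dictionary) {
  stopifnot(
    inherits(spec, "polsa_synth_spec"),
    inherits(ontology, "polsa_ontology"),
    inherits(dictionary, "polsa_dictionary")
  )
  set.seed(spec$seed + 1L)
  terms <- dictionary$terms
  selected <- terms$linked_heading[terms$source == "heading"]
  n_h <- length(selected)
  surfaces <- dictionary$surfaces
  surf_term <- dictionary$surface_terms
  surf_head <- terms$linked_heading[surf_term]
  n_s <- length(surfaces)

  planted <- spec$planted_pairs
  if (is.null(planted)) {
    gs_surf <- surfaces[terms$source[surf_term] == "gene_symbol"]
    mg_surf <- surfaces[
      terms$source[surf_term] == "heading" &
        vapply(strsplit(surfaces, " ", fixed = TRUE), length,
          integer(1)
        ) > 1L
    ]
    n_gs <- min(length(gs_surf), ceiling(spec$n_planted / 2))
    n_mg <- min(length(mg_surf), spec$n_planted - n_gs)
    qs <- c(
      sample(gs_surf, n_gs),
      if (n_mg > 0L) sample(mg_surf, n_mg) else character(0)
    )
    targets <- vapply(qs, function(s) {
      own <- surf_head[match(s, surfaces)]
      pool <- setdiff(selected, own)
      sample(pool, 1L)
    }, character(1), USE.NAMES = FALSE)
    planted <- tibble::tibble(
      query_surface = qs,
      target_heading_id = targets,
      strength = spec$planted_rate / max(spec$background_rate, 1e-12)
    )
  }

  # topic of each heading (by selection position) and of each surface
  topic_of_heading <- stats::setNames(
    ((seq_len(n_h) - 1L) %% spec$n_topics) + 1L, selected
  )
  topic_of_surface <- ifelse(
    is.na(surf_head),
    sample.int(spec$n_topics, n_s, replace = TRUE),
    unname(topic_of_heading[surf_head])
  )

  ann <- selected[((seq_len(spec$n_records) - 1L) %% n_h) + 1L]
  ann <- ann[sample.int(spec$n_records)]

  planted_surf_idx <- match(planted$query_surface, surfaces)
  surf_ntok <- vapply(
    strsplit(surfaces, " ", fixed = TRUE), length, integer(1)
  )
  # occupancy gate: surface s is active under heading h only for a random
  # subset of headings (always under same-topic headings), so document
  # frequencies stay below n_h and idf carries signal
  active <- matrix(
    stats::runif(n_s * n_h) < spec$background_occupancy, n_s, n_h
  )
  for (j in seq_len(n_h)) {
    active[topic_of_surface == topic_of_heading[selected[j]], j] <- TRUE
  }
  col_of <- stats::setNames(seq_len(n_h), selected)
  abstracts <- character(spec$n_records)
  for (r in seq_len(spec$n_records)) {
    h <- ann[r]
    rates <- spec$background_rate * active[, col_of[h]]
    boost <- topic_of_surface == topic_of_heading[h]
    rates[boost] <- spec$background_rate * spec$topic_boost
    hit <- planted$target_heading_id == h
    if (any(hit)) rates[planted_surf_idx[hit]] <- spec$planted_rate
    counts <- stats::rpois(n_s, rates)
    units <- rep.int(surfaces, counts)
    n_fill <- max(0L, spec$tokens_per_abstract - sum(counts * surf_ntok))
    if (n_fill > 0L) {
      units <- c(units, sprintf("filler%02d%04d", r %% 97L, seq_len(n_fill)))
    }
    units <- units[sample.int(length(units))]
    abstracts[r] <- paste(units, collapse = " ")
  }
  records <- tibble::tibble(
    record_id = sprintf("R%06d", seq_len(spec$n_records)),
    year = 1960L + (seq_len(spec$n_records) %% 53L),
    title = sprintf("synthetic study %d", seq_len(spec$n_records)),
    abstract = abstracts,
    annotations = as.list(ann)
  )
  list(records = records, planted = planted)
}

#' Write synthetic inputs in the reader dialects
#'
#' Emits the exact file formats the real readers consume: ontology TSV,
#' gene-symbol list, JSONL corpus, and a planted-truth TSV.
#'
#' @param spec A `polsa_synth_spec`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_ontology(spec)
  dictionary <- build_dictionary(
    gen$ontology, gen$selected, gen$gene_symbols,
    quiet = TRUE
  )
  corp <- generate_corpus(spec, gen$ontology, dictionary)
  paths <- c(
    ontology = file.path(dir, "ontology.tsv"),
    gene_symbols = file.path(dir, "gene_symbols.txt"),
    corpus = file.path(dir, "corpus.jsonl"),
    planted = file.path(dir, "planted.tsv")
  )
  h <- gen$ontology$headings
  writeLines(
    vapply(seq_len(nrow(h)), function(i) {
      paste(c(
        h$heading_id[i], h$preferred_name[i],
        paste(h$entry_terms[[i]], collapse = "|"),
        paste(h$tree_numbers[[i]], collapse = "|"),
        h$abstract_count[i]
      ), collapse = "\t")
    }, character(1)),
    paths[["ontology"]],
    useBytes = TRUE
  )
  writeLines(
    c("# synthetic gene symbols", gen$gene_symbols),
    paths[["gene_symbols"]],
    useBytes = TRUE
  )
  rec <- corp$records
  writeLines(
    vapply(seq_len(nrow(rec)), function(i) {
      jsonlite::toJSON(
        list(
          id = rec$record_id[i], year = rec$year[i],
          title = rec$title[i], abstract = rec$abstract[i],
          headings = as.list(rec$annotations[[i]])
        ),
        auto_unbox = TRUE
      )
    }, character(1)),
    paths[["corpus"]],
    useBytes = TRUE
  )
  p <- corp$planted
  writeLines(
    c(
      "query_surface\ttarget_heading_id\tstrength",
      sprintf(
        "%s\t%s\t%s", p$query_surface, p$target_heading_id,
        fmt_num(p$strength)
      )
    ),
    paths[["planted"]],
    useBytes = TRUE
  )
  invisible(paths)
}

#' Run the full pipeline on synthetic inputs
#'
#' Generates the ontology, dictionary and corpus for `spec`, accumulates
#' counts, TF-IDF weights them and fits the semantic model — the
#' in-memory equivalent of `cmd_synth` followed by `cmd_build`.
#'
#' @param spec A `polsa_synth_spec`.
#' @param energy_threshold Passed to [fit_semantic_model()].
#' @return List with `ontology`, `selected`, `dictionary`, `records`,
#'   `planted`, `counts`, `model`.
#' @export
run_synthetic_pipeline <- function(spec, energy_threshold = 0.95) {
  gen <- generate_ontology(spec)
  dictionary <- build_dictionary(
    gen$ontology, gen$selected, gen$gene_symbols,
    quiet = TRUE
  )
  corp <- generate_corpus(spec, gen$ontology, dictionary)
  counts <- accumulate_counts(corp$records, dictionary, gen$selected)
  model <- fit_semantic_model(
    tfidf_weight(counts),
    energy_threshold = energy_threshold
  )
  list(
    ontology = gen$ontology, selected = gen$selected,
    dictionary = dictionary, records = corp$records,
    planted = corp$planted, counts = counts, model = model
  )
}
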