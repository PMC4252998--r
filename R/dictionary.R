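#' Normalize text to a token vector
#'
#' Lowercases, strips punctuation (Unicode classes) except hyphens inside
#' tokens, and splits on whitespace.  No stop-word removal: stop words can
#' be meaningful inside multi-gram phrases.
#'
#' @param text A character scalar (empty or `NA` gives an empty vector).
#' @return Character vector of tokens.
#' @examples
#' normalize_text("Scleroderma, Systemic") # "scleroderma" "systemic"
#' normalize_text("beta-endorphin")        # hyphen kept
#' @export
normalize_text <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) {
    return(character(0))
  }
  x <- stringr::str_to_lower(text)
  # any punctuation or symbol except "-" becomes a separator
  x <- stringr::str_replace_all(x, "[\\p{P}\\p{S}&&[^-]]+", " ")
  tokens <- stringr::str_split_1(x, "\\s+")
  # hyphens survive only between word characters
  tokens <- stringr::str_remove_all(tokens, "^-+|-+$")
  tokens <- stringr::str_replace_all(tokens, "-{2,}", "-")
  tokens[nzchar(tokens)]
}

# canonical surface string: normalized tokens joined by single spaces
normalize_surface <- function(text) {
  paste(normalize_text(text), collapse = " ")
}

#' Comma-inversion variants of a heading name
#'
#' MeSH displays many headings in comma-inverted form
#' (`"Scleroderma, Systemic"` for *systemic scleroderma*).  This generates
#' all rotations of the comma-separated segments, normalized, so both the
#' display form and the natural reading become dictionary surfaces.
#'
#' @param name Raw heading or entry-term string.
#' @return Character vector of distinct normalized surface forms.
#' @examples
#' permute_comma_inverted("Scleroderma, Systemic")
#' @export
permute_comma_inverted <- function(name) {
  segs <- trimws(strsplit(name, ",", fixed = TRUE)[[1]])
  segs <- segs[nzchar(segs)]
  if (length(segs) <= 1L) {
    out <- normalize_surface(name)
    return(out[nzchar(out)])
  }
  k <- length(segs)
  forms <- vapply(seq_len(k), function(r) {
    rot <- segs[c(seq(r, k), if (r > 1L) seq_len(r - 1L))]
    normalize_surface(paste(rot, collapse = " "))
  }, character(1))
  unique(forms[nzchar(forms)])
}

#' Build the multi-gram dictionary
#'
#' Compiles the context-specific multi-gram dictionary: one term per
#' selected heading, whose surface variants are the comma-rotation forms
#' of its preferred name and entry terms, plus one term per gene symbol
#' whose normalized form does not collide with an existing surface.
#' Surface collisions are resolved by source priority
#' heading > entry term > gene symbol (ontology concepts anchor the
#' semantic space; gene symbols are a layer of genetic information added
#' on top), then by earlier term id.  Variants longer than `max_ngram`
#' tokens are excluded from the surface index so the matcher window stays
#' bounded.
#'
#' @param ontology A `polsa_ontology`.
#' @param selected Ordered heading ids from [select_headings()].
#' @param gene_symbols Character vector of gene symbols (may be empty).
#' @param max_ngram Longest surface length, in tokens (default 6).
#' @param quiet Suppress collision/truncation messages.
#' @return An object of class `polsa_dictionary`: list with `terms`
#'   (tibble: `term_id`, `canonical`, `n_tokens`, `source`,
#'   `linked_heading`, `variants` list-column of indexed surfaces),
#'   `surface_index` (environment mapping surface -> term_id) and
#'   `max_ngram`.
#' @export
build_dictionary <- function(ontology, selected, gene_symbols = character(0),
                             max_ngram = 6L, quiet = FALSE) {
  stopifnot(inherits(ontology, "polsa_ontology"))
  if (length(selected) == 0L) {
    stop("empty selection: cannot build a dictionary", call. = FALSE)
  }
  h <- ontology$headings
  rows <- match(selected, h$heading_id)
  if (anyNA(rows)) {
    stop("selected heading(s) not in ontology: ",
      paste(selected[is.na(rows)], collapse = ", "),
      call. = FALSE
    )
  }
  note <- function(...) if (!quiet) rlang::inform(paste0(...))

  gene_symbols <- gene_symbols[nzchar(trimws(gene_symbols))]
  gs_norm <- vapply(gene_symbols, normalize_surface, character(1),
    USE.NAMES = FALSE
  )
  if (anyDuplicated(gs_norm)) {
    note(
      "build_dictionary: dropping duplicate gene symbols: ",
      paste(unique(gs_norm[duplicated(gs_norm)]), collapse = ", ")
    )
    gs_norm <- gs_norm[!duplicated(gs_norm)]
  }
  gs_norm <- sort(gs_norm[nzchar(gs_norm)], method = "radix")

  n_head <- length(rows)
  terms <- tibble::tibble(
    term_id = seq_len(n_head + length(gs_norm)),
    canonical = c(
      vapply(h$preferred_name[rows], normalize_surface, character(1),
        USE.NAMES = FALSE
      ),
      gs_norm
    ),
    source = c(rep("heading", n_head), rep("gene_symbol", length(gs_norm))),
    linked_heading = c(selected, rep(NA_character_, length(gs_norm)))
  )

  # priority heading > entry_term > gene_symbol is enforced by pass order:
  # the first claimant of a surface keeps it
  surface_index <- new.env(parent = emptyenv(), hash = TRUE)
  claim <- function(surface, term_id, label) {
    ntok <- length(strsplit(surface, " ", fixed = TRUE)[[1]])
    if (ntok > max_ngram) {
      note(
        "build_dictionary: surface '", surface, "' exceeds max_ngram (",
        max_ngram, " tokens), not indexed"
      )
      return(FALSE)
    }
    prev <- surface_index[[surface]]
    if (is.null(prev)) {
      assign(surface, term_id, envir = surface_index)
      return(TRUE)
    }
    if (prev != term_id) {
      note(
        "build_dictionary: surface '", surface, "' from ", label,
        " collides with term ", prev, "; keeping existing mapping"
      )
    }
    FALSE
  }

  variants <- vector("list", nrow(terms))
  # pass 1: heading preferred names; pass 2: entry terms; pass 3: symbols
  for (i in seq_len(n_head)) {
    v <- character(0)
    for (s in permute_comma_inverted(h$preferred_name[[rows[i]]])) {
      if (claim(s, i, paste0("heading ", selected[i]))) v <- c(v, s)
    }
    variants[[i]] <- v
  }
  for (i in seq_len(n_head)) {
    v <- variants[[i]]
    for (et in h$entry_terms[[rows[i]]]) {
      for (s in permute_comma_inverted(et)) {
        if (claim(s, i, paste0("entry term of ", selected[i]))) {
          v <- c(v, s)
        }
      }
    }
    variants[[i]] <- unique(v)
  }
  keep_gs <- logical(length(gs_norm))
  for (j in seq_along(gs_norm)) {
    tid <- n_head + j
    ok <- claim(gs_norm[j], tid, paste0("gene symbol '", gs_norm[j], "'"))
    keep_gs[j] <- ok
    variants[[tid]] <- if (ok) gs_norm[j] else character(0)
  }
  if (any(!keep_gs)) {
    drop_ids <- n_head + which(!keep_gs)
    terms <- terms[-drop_ids, ]
    variants <- variants[-drop_ids]
    # re-densify term ids and remap the index
    old_ids <- terms$term_id
    terms$term_id <- seq_len(nrow(terms))
    remap <- match(seq_len(n_head + length(gs_norm)), old_ids)
    for (s in ls(surface_index)) {
      assign(s, remap[surface_index[[s]]], envir = surface_index)
    }
  }
  terms$variants <- variants
  terms$n_tokens <- vapply(
    strsplit(terms$canonical, " ", fixed = TRUE), length, integer(1)
  )
  terms <- terms[, c(
    "term_id", "canonical", "n_tokens", "source",
    "linked_heading", "variants"
  )]
  new_dictionary(terms, surface_index)
}

# assemble the dictionary object, caching flat surface vectors the
# matcher uses (ls() on the env per call would dominate corpus scans)
new_dictionary <- function(terms, surface_index) {
  surfaces <- ls(surface_index)
  surface_terms <- vapply(
    surfaces, function(s) as.integer(surface_index[[s]]), integer(1),
    USE.NAMES = FALSE
  )
  ntok <- if (length(surfaces)) {
    vapply(strsplit(surfaces, " ", fixed = TRUE), length, integer(1))
  } else {
    1L
  }
  structure(
    list(
      terms = terms,
      surface_index = surface_index,
      surfaces = surfaces,
      surface_terms = surface_terms,
      max_ngram = max(ntok)
    ),
    class = "polsa_dictionary"
  )
}

#' @export
print.polsa_dictionary <- function(x, ...) {
  cat("<polsa_dictionary> ", nrow(x$terms), " terms (",
    sum(x$terms$source == "heading"), " heading, ",
    sum(x$terms$source == "gene_symbol"), " gene symbol), max n-gram ",
    x$max_ngram, "\n",
    sep = ""
  )
  print(x$terms, ...)
  invisible(x)
}

#' Look up a normalized surface form
#'
#' @param dictionary A `polsa_dictionary`.
#' @param surface A normalized surface string (see [normalize_text()]).
#' @return The term id, or `NA` if the surface is not indexed.
#' @export
lookup_surface <- function(dictionary, surface) {
  v <- dictionary$surface_index[[surface]]
  if (is.null(v)) NA_integer_ else as.integer(v)
}

#' Read a gene-symbol list
#'
#' Plain text, one symbol per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_symbols <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a dictionary to TSV for inspection and reload
#'
#' Columns: `term_id`, `canonical`, `source`, `linked_heading`, then the
#' indexed variants, all tab-separated.
#'
#' @param dictionary A `polsa_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  t <- dictionary$terms
  lines <- vapply(seq_len(nrow(t)), function(i) {
    paste(c(
      t$term_id[i], t$canonical[i], t$source[i],
      ifelse(is.na(t$linked_heading[i]), "", t$linked_heading[i]),
      t$variants[[i]]
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Reload a dictionary written by [write_dictionary()]
#'
#' @param path TSV path.
#' @param max_ngram Matcher window bound (default 6).
#' @return A `polsa_dictionary`.
#' @export
read_dictionary <- function(path, max_ngram = 6L) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- purrr::map_dfr(fields, function(f) {
    tibble::tibble(
      term_id = as.integer(f[1L]),
      canonical = f[2L],
      source = f[3L],
      linked_heading = if (nzchar(f[4L])) f[4L] else NA_character_,
      variants = list(if (length(f) > 4L) f[-(1:4)] else character(0))
    )
  })
  terms$n_tokens <- vapply(
    strsplit(terms$canonical, " ", fixed = TRUE), length, integer(1)
  )
  surface_index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(terms))) {
    for (s in terms$variants[[i]]) {
      assign(s, terms$term_id[i], envir = surface_index)
    }
  }
  terms <- terms[, c(
    "term_id", "canonical", "n_tokens", "source",
    "linked_heading", "variants"
  )]
  new_dictionary(terms, surface_index)
}
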