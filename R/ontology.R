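#' Read a heading ontology
#'
#' Parses a MeSH-style descriptor ontology into a heading table.  Two
#' dialects are supported: MeSH descriptor XML (`DescriptorRecordSet`
#' records with descriptor UI, preferred name, entry terms and tree
#' numbers) and a simplified five-column TSV
#' (`heading_id`, `preferred_name`, pipe-joined `entry_terms`,
#' pipe-joined `tree_numbers`, `abstract_count`).
#'
#' Each heading carries one or more dotted tree numbers (e.g.
#' `"C04.557.450"`) encoding its positions in the polyhierarchy; the set of
#' category letters is derived from the first character of each tree
#' number.  Abstract counts are taken from the TSV column when present and
#' are zero for XML input (they are attached later from corpus annotation
#' tallies).
#'
#' @param path Path to the ontology file.
#' @param format `"tsv"` or `"mesh-xml"`.
#' @return An object of class `polsa_ontology`: a list with element
#'   `headings`, a tibble with columns `heading_id`, `preferred_name`,
#'   `entry_terms` (list), `tree_numbers` (list), `categories` (list) and
#'   `abstract_count`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("D1\tPneumonia\t\tC08.381\t2000",
#'              "D2\tFibroma\tFibromas\tC04.557\t1500"), tsv)
#' ont <- read_ontology(tsv)
#' ont$headings
#' @export
read_ontology <- function(path, format = c("tsv", "mesh-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("ontology file does not exist: ", path, call. = FALSE)
  }
  headings <- switch(format,
    "tsv" = parse_ontology_tsv(path),
    "mesh-xml" = parse_ontology_xml(path)
  )
  if (nrow(headings) == 0L) {
    stop("ontology parse error: no descriptor records in ", path,
      call. = FALSE
    )
  }
  dup <- headings$heading_id[duplicated(headings$heading_id)]
  if (length(dup) > 0L) {
    stop("duplicate heading_id in ontology: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  new_ontology(headings)
}

new_ontology <- function(headings) {
  stopifnot(all(nzchar(headings$preferred_name)))
  headings$categories <- purrr::map(
    headings$tree_numbers,
    ~ sort(unique(substr(.x, 1L, 1L)))
  )
  structure(list(headings = tibble::as_tibble(headings)),
    class = "polsa_ontology"
  )
}

#' @export
print.polsa_ontology <- function(x, ...) {
  cat("<polsa_ontology> ", nrow(x$headings), " headings, categories: ",
    paste(sort(unique(unlist(x$headings$categories))), collapse = " "),
    "\n",
    sep = ""
  )
  print(x$headings, ...)
  invisible(x)
}

parse_ontology_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("ontology parse error: empty TSV file ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L) {
    stop("ontology parse error at TSV record ", bad[1L],
      ": expected 5 tab-separated columns",
      call. = FALSE
    )
  }
  split_pipe <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)[[1]]
    out[nzchar(trimws(out))]
  }
  purrr::map_dfr(seq_along(fields), function(i) {
    f <- fields[[i]]
    cnt <- if (length(f) >= 5L && nzchar(trimws(f[5L]))) {
      suppressWarnings(as.integer(f[5L]))
    } else {
      0L
    }
    if (is.na(cnt) || cnt < 0L) {
      stop("ontology parse error at TSV record ", i,
        ": bad abstract_count '", f[5L], "'",
        call. = FALSE
      )
    }
    if (!nzchar(trimws(f[2L]))) {
      stop("ontology parse error at TSV record ", i,
        ": empty preferred_name",
        call. = FALSE
      )
    }
    tibble::tibble(
      heading_id = trimws(f[1L]),
      preferred_name = trimws(f[2L]),
      entry_terms = list(split_pipe(f[3L])),
      tree_numbers = list(split_pipe(f[4L])),
      abstract_count = cnt
    )
  })
}

parse_ontology_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("ontology parse error: malformed XML in ", path, ": ",
      conditionMessage(e),
      call. = FALSE
    )
  })
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  if (length(recs) == 0L) {
    stop("ontology parse error: no DescriptorRecord elements in ", path,
      call. = FALSE
    )
  }
  purrr::map_dfr(recs, function(rec) {
    ui <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorUI"))
    name <- xml2::xml_text(
      xml2::xml_find_first(rec, "./DescriptorName/String")
    )
    terms <- xml2::xml_text(
      xml2::xml_find_all(rec, ".//ConceptList//TermList/Term/String")
    )
    trees <- xml2::xml_text(
      xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber")
    )
    if (is.na(ui) || !nzchar(ui) || is.na(name) || !nzchar(name)) {
      stop("ontology parse error: DescriptorRecord missing UI or name",
        call. = FALSE
      )
    }
    tibble::tibble(
      heading_id = ui,
      preferred_name = name,
      entry_terms = list(setdiff(unique(terms), name)),
      tree_numbers = list(unique(trees)),
      abstract_count = 0L
    )
  })
}

#' Attach abstract counts to an ontology
#'
#' Replaces per-heading abstract counts, typically with tallies of corpus
#' annotations (see [read_corpus()]).
#'
#' @param ontology A `polsa_ontology`.
#' @param counts Named integer vector, names are heading ids.  Headings
#'   absent from `counts` keep their current count.
#' @return The updated `polsa_ontology`.
#' @export
set_abstract_counts <- function(ontology, counts) {
  stopifnot(inherits(ontology, "polsa_ontology"))
  idx <- match(ontology$headings$heading_id, names(counts))
  hit <- !is.na(idx)
  ontology$headings$abstract_count[hit] <-
    as.integer(counts[idx[hit]])
  ontology
}

#' Select the modelled heading set
#'
#' Filters headings to those with an abstract count inside the inclusive
#' `[min_abstracts, max_abstracts]` window (very specific and very general
#' topics are excluded) and with at least one category among
#' `allowed_categories`, then enforces a Disease-category balance: at
#' least `disease_fraction` of the selected headings must carry category
#' C.  The balance is a floor, enforced by dropping the lowest-count
#' non-C headings until it holds; selection is maximal subject to that
#' constraint.
#'
#' @param ontology A `polsa_ontology` with abstract counts populated.
#' @param min_abstracts,max_abstracts Inclusive abstract-count window
#'   (defaults 1000 and 50000).
#' @param disease_fraction Minimum fraction of selected headings carrying
#'   category C (default 0.5).
#' @param allowed_categories Category letters eligible for selection.
#' @return Character vector of heading ids, ordered by descending
#'   abstract count with heading-id tie-break.
#' @export
select_headings <- function(ontology,
                            min_abstracts = 1000L,
                            max_abstracts = 50000L,
                            disease_fraction = 0.5,
                            allowed_categories = c(
                              "C", "D", "F", "G",
                              "I", "J", "M", "N"
                            )) {
  stopifnot(inherits(ontology, "polsa_ontology"))
  stopifnot(disease_fraction > 0, disease_fraction <= 1)
  stopifnot(min_abstracts < max_abstracts)
  h <- ontology$headings
  in_bounds <- h$abstract_count >= min_abstracts &
    h$abstract_count <= max_abstracts
  allowed <- purrr::map_lgl(
    h$categories,
    ~ length(intersect(.x, allowed_categories)) > 0L
  )
  cand <- h[in_bounds & allowed, ]
  if (nrow(cand) == 0L) {
    stop("empty selection: no heading satisfies the abstract-count bounds",
      call. = FALSE
    )
  }
  cand <- cand[order(-cand$abstract_count, cand$heading_id), ]
  is_c <- purrr::map_lgl(cand$categories, ~ "C" %in% .x)
  if (!any(is_c)) {
    stop("disease_fraction unachievable: no Disease-category heading ",
      "within the abstract-count bounds",
      call. = FALSE
    )
  }
  # drop lowest-count non-C headings until the C fraction holds
  keep <- rep(TRUE, nrow(cand))
  repeat {
    n_sel <- sum(keep)
    n_c <- sum(is_c & keep)
    if (n_c / n_sel >= disease_fraction) break
    drop_pool <- which(keep & !is_c)
    keep[drop_pool[length(drop_pool)]] <- FALSE
  }
  cand$heading_id[keep]
}

#' Ancestor chain of a heading's tree position
#'
#' Walks the dotted tree number from its category root down to the
#' heading, resolving each prefix to the heading occupying that tree
#' position.  A prefix with no heading in the ontology is kept as a
#' structural entry named after the tree number itself.
#'
#' @param ontology A `polsa_ontology`.
#' @param heading_id A heading id in the ontology.
#' @param tree_number One of that heading's tree numbers.
#' @return A tibble with columns `name` and `tree_number`, one row per
#'   dotted component, root first, the heading itself last.
#' @export
ancestor_chain <- function(ontology, heading_id, tree_number) {
  stopifnot(inherits(ontology, "polsa_ontology"))
  h <- ontology$headings
  row <- which(h$heading_id == heading_id)
  if (length(row) != 1L) {
    stop("unknown heading_id: ", heading_id, call. = FALSE)
  }
  if (!tree_number %in% h$tree_numbers[[row]]) {
    stop("tree number ", tree_number, " does not belong to heading ",
      heading_id,
      call. = FALSE
    )
  }
  parts <- strsplit(tree_number, ".", fixed = TRUE)[[1]]
  prefixes <- vapply(
    seq_along(parts),
    function(i) paste(parts[seq_len(i)], collapse = "."),
    character(1)
  )
  tn_index <- tree_number_index(ontology)
  name <- purrr::map_chr(prefixes, function(p) {
    j <- tn_index[[p]]
    if (is.null(j)) p else h$preferred_name[[j]]
  })
  tibble::tibble(name = name, tree_number = prefixes)
}

# tree number -> heading row lookup, memoised on the ontology object
tree_number_index <- function(ontology) {
  env <- attr(ontology, "tn_index")
  if (!is.null(env)) {
    return(env)
  }
  env <- new.env(parent = emptyenv(), hash = TRUE)
  h <- ontology$headings
  for (i in seq_len(nrow(h))) {
    for (tn in h$tree_numbers[[i]]) assign(tn, i, envir = env)
  }
  env
}

#' Render an ancestor chain as a path string
#'
#' @param chain A tibble from [ancestor_chain()].
#' @param sep Separator (default `" > "`).
#' @return A single string, e.g. `"Proteostasis Deficiencies > Amyloidosis"`.
#' @export
render_chain <- function(chain, sep = " > ") {
  paste(chain$name, collapse = sep)
}
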