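#' Read a corpus of abstracts
#'
#' Reads abstract records from either JSON-lines (keys `id`, `year`,
#' `title`, `abstract`, `headings`) or MEDLINE plain text (`PMID-`, `TI-`,
#' `AB-`, `MH-`, `DP-` tagged fields with continuation-line unfolding).
#' MEDLINE `MH` values have their qualifier stripped at `/` and the major
#' topic asterisk removed, then are resolved to heading ids via ontology
#' preferred names and entry terms; unmatched values are skipped with a
#' message.  Records without an id are skipped with a warning.
#'
#' @param path Corpus file path.
#' @param ontology A `polsa_ontology`, required for MEDLINE input (to map
#'   `MH` names to heading ids); ignored for JSONL, whose `headings` field
#'   already carries ids.
#' @param format `"jsonl"` or `"medline"`.
#' @param quiet Suppress unmatched-annotation messages.
#' @return A tibble with columns `record_id`, `year`, `title`, `abstract`
#'   and `annotations` (list of heading ids), in file order.
#' @export
read_corpus <- function(path, ontology = NULL,
                        format = c("jsonl", "medline"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("corpus file does not exist: ", path, call. = FALSE)
  }
  switch(format,
    "jsonl" = read_corpus_jsonl(path),
    "medline" = read_corpus_medline(path, ontology, quiet = quiet)
  )
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop("corpus parse error at JSONL line ", i, ": ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
    id <- rec$id
    if (is.null(id) || !nzchar(as.character(id))) {
      warning("corpus record at line ", i, " has no id; skipped",
        call. = FALSE
      )
      return(NULL)
    }
    tibble::tibble(
      record_id = as.character(id),
      year = as.integer(rec$year %||% NA_integer_),
      title = as.character(rec$title %||% ""),
      abstract = as.character(rec$abstract %||% ""),
      annotations = list(as.character(unlist(rec$headings)))
    )
  })
  dplyr::bind_rows(recs)
}

read_corpus_medline <- function(path, ontology, quiet = FALSE) {
  if (is.null(ontology)) {
    stop("MEDLINE input needs an ontology to resolve MH annotations",
      call. = FALSE
    )
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # unfold continuation lines (six leading spaces)
  tags <- character(0)
  vals <- character(0)
  for (ln in lines) {
    if (grepl("^ {6}", ln) && length(vals) > 0L) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(ln))
    } else if (grepl("^[A-Z0-9]{1,4} *- ", ln)) {
      tags <- c(tags, trimws(sub("^([A-Z0-9]{1,4}) *- .*$", "\\1", ln)))
      vals <- c(vals, sub("^[A-Z0-9]{1,4} *- ", "", ln))
    }
  }
  if (length(tags) == 0L) {
    stop("corpus parse error: no MEDLINE fields in ", path, call. = FALSE)
  }
  rec_break <- which(tags == "PMID")
  if (length(rec_break) == 0L) {
    stop("corpus parse error: no PMID fields in ", path, call. = FALSE)
  }
  name_idx <- heading_name_index(ontology)
  starts <- rec_break
  ends <- c(rec_break[-1] - 1L, length(tags))
  recs <- purrr::map(seq_along(starts), function(r) {
    sel <- seq(starts[r], ends[r])
    t <- tags[sel]
    v <- vals[sel]
    id <- trimws(v[t == "PMID"][1])
    if (!nzchar(id)) {
      warning("MEDLINE record ", r, " has empty PMID; skipped",
        call. = FALSE
      )
      return(NULL)
    }
    mh <- v[t == "MH"]
    mh <- sub("/.*$", "", mh) # strip qualifiers
    mh <- gsub("*", "", mh, fixed = TRUE) # major-topic marker
    ann <- purrr::map_chr(mh, function(m) {
      hid <- name_idx[[normalize_surface(m)]]
      if (is.null(hid)) {
        if (!quiet) {
          rlang::inform(paste0(
            "read_corpus: unmatched MH annotation '", trimws(m),
            "' in record ", id, "; skipped"
          ))
        }
        NA_character_
      } else {
        hid
      }
    })
    dp <- v[t == "DP"]
    year <- if (length(dp) > 0L) {
      suppressWarnings(as.integer(sub("^.*?(\\d{4}).*$", "\\1", dp[1])))
    } else {
      NA_integer_
    }
    tibble::tibble(
      record_id = id,
      year = year,
      title = paste(v[t == "TI"], collapse = " "),
      abstract = paste(v[t == "AB"], collapse = " "),
      annotations = list(ann[!is.na(ann)])
    )
  })
  dplyr::bind_rows(recs)
}

# normalized heading name / entry term -> heading_id
heading_name_index <- function(ontology) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  h <- ontology$headings
  for (i in seq_len(nrow(h))) {
    for (nm in c(h$preferred_name[[i]], h$entry_terms[[i]])) {
      s <- normalize_surface(nm)
      if (nzchar(s) && is.null(env[[s]])) {
        assign(s, h$heading_id[[i]], envir = env)
      }
    }
  }
  env
}

#' Match multi-gram dictionary terms in a token stream
#'
#' Greedy left-to-right longest-match: at each position the longest
#' window of at most `max_ngram` tokens whose space-joined form is an
#' indexed surface is consumed; matched spans never overlap, and
#' unmatched tokens are skipped.  Phrase terms therefore absorb their
#' constituent words ("yellow virus fever" is one match even when
#' "fever" is also a dictionary surface), which is what lets the model
#' see phrases as single semantic units.
#'
#' @param tokens Character vector of tokens, already normalized by
#'   [normalize_text()].
#' @param dictionary A `polsa_dictionary`.
#' @return Tibble with columns `term_id`, `start`, `length`, sorted by
#'   `start`, spans pairwise disjoint.
#' @export
match_multigrams <- function(tokens, dictionary) {
  m <- match_multigrams_core(tokens, dictionary)
  tibble::tibble(term_id = m$term, start = m$start, length = m$len)
}

# plain-vector matcher core, used directly on hot paths
match_multigrams_core <- function(tokens, dictionary) {
  n <- length(tokens)
  if (n == 0L) {
    return(list(
      term = integer(0), start = integer(0), len = integer(0)
    ))
  }
  greedy_consume(ngram_hits(tokens, dictionary), n)
}

# term-id hits for every window size: hits[[g]][p] is the term matched by
# the g-gram starting at position p (NA if none)
ngram_hits <- function(tokens, dictionary) {
  n <- length(tokens)
  gmax <- min(dictionary$max_ngram, n)
  surfaces <- dictionary$surfaces
  term_of <- dictionary$surface_terms
  hits <- vector("list", gmax)
  joined <- tokens
  for (g in seq_len(gmax)) {
    if (g > 1L) {
      m <- n - g + 1L
      joined <- paste(joined[seq_len(m)], tokens[seq(g, n)])
    }
    idx <- match(joined, surfaces)
    hits[[g]] <- ifelse(is.na(idx), NA_integer_, term_of[idx])
  }
  hits
}

greedy_consume <- function(hits, n) {
  gmax <- length(hits)
  term <- integer(n)
  start <- integer(n)
  len <- integer(n)
  k <- 0L
  pos <- 1L
  while (pos <= n) {
    g <- min(gmax, n - pos + 1L)
    consumed <- FALSE
    while (g >= 1L) {
      t <- hits[[g]][pos]
      if (!is.na(t)) {
        k <- k + 1L
        term[k] <- t
        start[k] <- pos
        len[k] <- g
        pos <- pos + g
        consumed <- TRUE
        break
      }
      g <- g - 1L
    }
    if (!consumed) pos <- pos + 1L
  }
  idx <- seq_len(k)
  list(term = term[idx], start = start[idx], len = len[idx])
}

#' Accumulate the term-by-heading count matrix
#'
#' Tokenizes each record (title and abstract concatenated), matches
#' multi-gram terms, and adds the record's term counts to the column of
#' every selected heading the record is annotated with.  Records whose
#' annotations include none of the selected headings contribute nothing.
#'
#' @param records Tibble from [read_corpus()] (or the synthetic
#'   generator).
#' @param dictionary A `polsa_dictionary`.
#' @param selected Ordered heading ids defining the column space.
#' @return A sparse `Matrix::dgCMatrix`, terms x headings, with dimnames
#'   `(term_id, heading_id)`.
#' @export
accumulate_counts <- function(records, dictionary, selected) {
  n_terms <- nrow(dictionary$terms)
  n_head <- length(selected)
  col_of <- stats::setNames(seq_len(n_head), selected)
  acc_t <- vector("list", nrow(records))
  acc_h <- vector("list", nrow(records))
  acc_c <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    ann <- records$annotations[[r]]
    cols <- unname(col_of[ann[ann %in% selected]])
    if (length(cols) == 0L) next
    tokens <- normalize_text(
      paste(records$title[[r]], records$abstract[[r]])
    )
    m <- match_multigrams_core(tokens, dictionary)
    if (length(m$term) == 0L) next
    tab <- tabulate(m$term, nbins = n_terms)
    tids <- which(tab > 0L)
    cnts <- as.numeric(tab[tids])
    acc_t[[r]] <- rep(tids, times = length(cols))
    acc_h[[r]] <- rep(cols, each = length(tids))
    acc_c[[r]] <- rep(cnts, times = length(cols))
  }
  ti <- unlist(acc_t)
  hi <- unlist(acc_h)
  cv <- unlist(acc_c)
  if (length(ti) == 0L) {
    warning("accumulate_counts: no record matched any dictionary term; ",
      "count matrix is all zero",
      call. = FALSE
    )
  }
  Matrix::sparseMatrix(
    i = as.integer(ti), j = as.integer(hi), x = as.numeric(cv),
    dims = c(n_terms, n_head),
    dimnames = list(
      as.character(dictionary$terms$term_id),
      selected
    )
  )
}

#' Write a sparse count matrix as MatrixMarket + label sidecars
#'
#' @param counts Sparse matrix from [accumulate_counts()].
#' @param path Base path; writes `<path>.mtx`, `<path>.rows`,
#'   `<path>.cols`.
#' @return Base path, invisibly.
#' @export
write_counts <- function(counts, path) {
  Matrix::writeMM(counts, paste0(path, ".mtx"))
  writeLines(rownames(counts), paste0(path, ".rows"))
  writeLines(colnames(counts), paste0(path, ".cols"))
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path Base path used when writing.
#' @return Sparse matrix with row/column labels restored.
#' @export
read_counts <- function(path) {
  m <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(
    readLines(paste0(path, ".rows")),
    readLines(paste0(path, ".cols"))
  )
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
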