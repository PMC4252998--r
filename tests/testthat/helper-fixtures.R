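# in-code fixtures and independent oracles shared across the suite

# write an ontology TSV from parallel lists and read it back
make_ontology <- function(heading_id, preferred_name, entry_terms,
                          tree_numbers, abstract_count) {
  path <- withr::local_tempfile(
    fileext = ".tsv",
    .local_envir = parent.frame()
  )
  lines <- vapply(seq_along(heading_id), function(i) {
    paste(c(
      heading_id[i], preferred_name[i],
      paste(entry_terms[[i]], collapse = "|"),
      paste(tree_numbers[[i]], collapse = "|"),
      abstract_count[i]
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  read_ontology(path, format = "tsv")
}

# small mixed-category ontology used by several suites
fixture_ontology <- function() {
  make_ontology(
    heading_id = c("D1", "D2", "D3", "D4", "D5", "D6"),
    preferred_name = c(
      "Pneumonia", "Fibroma", "Steel", "Amyloidosis",
      "Proteostasis Deficiencies", "Scleroderma, Systemic"
    ),
    entry_terms = list(
      c("Lung Inflammation"), character(0), character(0),
      character(0), character(0), c("Systemic Sclerosis")
    ),
    tree_numbers = list(
      "C08.381", "C04.557", "J01.637", "C18.452.284.281",
      "C18.452.284", c("C17.300.799", "C17.800.784")
    ),
    abstract_count = c(2000L, 1500L, 1200L, 3000L, 2500L, 4000L)
  )
}

# dictionary over explicit surfaces (id/name pairs as single headings)
make_surface_dictionary <- function(surfaces) {
  ont <- make_ontology(
    heading_id = sprintf("H%03d", seq_along(surfaces)),
    preferred_name = surfaces,
    entry_terms = rep(list(character(0)), length(surfaces)),
    tree_numbers = as.list(sprintf("C01.%03d", seq_along(surfaces))),
    abstract_count = rep(2000L, length(surfaces))
  )
  build_dictionary(
    ont, sprintf("H%03d", seq_along(surfaces)),
    quiet = TRUE
  )
}

# --- exhaustive leftmost-longest tiling oracle ------------------------------
# Enumerates match options position by position and picks the preferred
# tiling by lexicographic comparison of (start, -length) sequences, with a
# longer sequence preferred over its own prefix.  Dynamic programming over
# positions, structurally independent of the scan-and-consume matcher.
oracle_match <- function(tokens, dictionary) {
  n <- length(tokens)
  gmax <- dictionary$max_ngram
  lookup <- function(p, g) {
    if (p + g - 1L > n) {
      return(NA_integer_)
    }
    s <- paste(tokens[p:(p + g - 1L)], collapse = " ")
    v <- dictionary$surface_index[[s]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }
  better <- function(a, b) {
    # is tiling a preferred over b?  elements are rows (start, -len, term)
    la <- length(a)
    lb <- length(b)
    for (i in seq_len(min(la, lb))) {
      if (a[[i]][1] != b[[i]][1]) {
        return(a[[i]][1] < b[[i]][1])
      }
      if (a[[i]][2] != b[[i]][2]) {
        return(a[[i]][2] < b[[i]][2])
      }
    }
    la > lb
  }
  memo <- vector("list", n + 1L)
  done <- logical(n + 1L)
  solve <- function(p) {
    if (p > n) {
      return(list())
    }
    if (done[p]) {
      return(memo[[p]])
    }
    best <- NULL
    for (g in seq_len(min(gmax, n - p + 1L))) {
      t <- lookup(p, g)
      if (!is.na(t)) {
        cand <- c(list(c(p, -g, t)), solve(p + g))
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
    skip <- solve(p + 1L)
    if (is.null(best) || better(skip, best)) best <- skip
    memo[[p]] <<- best
    done[p] <<- TRUE
    best
  }
  res <- solve(1L)
  if (length(res) == 0L) {
    return(tibble::tibble(
      term_id = integer(0), start = integer(0), length = integer(0)
    ))
  }
  tibble::tibble(
    term_id = vapply(res, function(r) as.integer(r[3]), integer(1)),
    start = vapply(res, function(r) as.integer(r[1]), integer(1)),
    length = vapply(res, function(r) as.integer(-r[2]), integer(1))
  )
}

# random matcher test case: small alphabet so surfaces collide and overlap
random_match_case <- function() {
  alphabet <- letters[1:5]
  n_surf <- sample(1:8, 1)
  surfaces <- unique(vapply(seq_len(n_surf), function(i) {
    paste(sample(alphabet, sample(1:3, 1), replace = TRUE),
      collapse = " "
    )
  }, character(1)))
  tokens <- sample(alphabet, sample(0:12, 1), replace = TRUE)
  list(dict = make_surface_dictionary(surfaces), tokens = tokens)
}

# --- brute-force heading-selection oracle -----------------------------------
# maximal subset of in-bounds candidates with C-fraction >= f, by
# exhaustive enumeration (use only on small fixtures)
oracle_max_selection_size <- function(is_c, f) {
  n <- length(is_c)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (sum(sel) == 0L) next
    if (sum(is_c & sel) / sum(sel) >= f) best <- max(best, sum(sel))
  }
  best
}

# --- independent FCM oracle --------------------------------------------------
# e1071's cmeans run from the same percentile start to a tight tolerance
oracle_fcm_centers <- function(x, m = 2) {
  init <- stats::quantile(x, probs = c(0.1, 0.5, 0.9), names = FALSE)
  if (anyDuplicated(init)) {
    init <- init + seq(0, diff(range(x)) * 1e-6, length.out = 3)
  }
  fit <- e1071::cmeans(
    matrix(x, ncol = 1),
    centers = matrix(init, ncol = 1),
    iter.max = 2000, m = m, method = "cmeans"
  )
  sort(unname(drop(fit$centers)))
}

# small synthetic spec for fast end-to-end tests
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(
    n_headings = 20L, n_terms = 70L, n_multigrams = 10L,
    n_records = 200L, n_topics = 5L, n_planted = 4L,
    tokens_per_abstract = 60L, seed = seed, ...
  )
}

# matrix with prescribed singular values via fixed random rotations
matrix_with_singular_values <- function(d, n = 6, m = 4, seed = 99) {
  set.seed(seed)
  qu <- qr.Q(qr(matrix(rnorm(n * n), n)))
  qv <- qr.Q(qr(matrix(rnorm(m * m), m)))
  s <- matrix(0, n, m)
  diag(s)[seq_along(d)] <- d
  out <- qu %*% s %*% t(qv)
  dimnames(out) <- list(
    as.character(seq_len(n)), sprintf("H%02d", seq_len(m))
  )
  out
}

# small sparse count matrix fixture for semantic-model checks
small_counts <- function(seed = 1, t = 20, h = 10, density = 0.25) {
  set.seed(seed)
  m <- matrix(stats::rpois(t * h, 0.6) *
    (stats::runif(t * h) < density), t, h)
  m[1, 1] <- m[1, 1] + 1
  Matrix::Matrix(m,
    sparse = TRUE,
    dimnames = list(as.character(1:t), sprintf("H%02d", 1:h))
  )
}
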