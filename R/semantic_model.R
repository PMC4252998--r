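#' TF-IDF weight a term-by-heading count matrix
#'
#' The weighted entry is `w[t, h] = c[t, h] * ln(H / df_t)`, where `df_t`
#' is the number of heading columns in which term `t` occurs.  Raw term
#' frequency, natural-log inverse document frequency, no sublinear
#' damping and no column normalization: the textbook form.  A term
#' present in every column gets weight zero everywhere (`ln 1 = 0`) —
#' ubiquitous terms carry no discriminative signal.
#'
#' @param counts Sparse terms x headings matrix from
#'   [accumulate_counts()].
#' @return List with `weights` (sparse matrix, same shape and dimnames)
#'   and `idf` (numeric vector, one entry per term; 0 for terms that
#'   never occur).
#' @export
tfidf_weight <- function(counts) {
  if (length(counts@x) == 0L || all(counts@x == 0)) {
    stop("tfidf_weight: count matrix is all zero", call. = FALSE)
  }
  n_head <- ncol(counts)
  df <- Matrix::rowSums(counts > 0)
  idf <- ifelse(df > 0, log(n_head / df), 0)
  weights <- Matrix::Diagonal(x = idf) %*% counts
  dimnames(weights) <- dimnames(counts)
  list(weights = methods::as(weights, "CsparseMatrix"), idf = idf)
}

#' Fit the latent semantic model
#'
#' Computes the SVD of the TF-IDF matrix and truncates it at the smallest
#' rank `k` whose components carry at least `energy_threshold` of the
#' total spectral energy, where the energy of component `i` is its
#' squared singular value.  Heading coordinates are `V_k %*% diag(s_k)`
#' (document-coordinate convention), so cosine comparisons against
#' folded-in queries happen with the singular-value weighting on the
#' heading side.
#'
#' @param weighted Output of [tfidf_weight()], or a plain (sparse or
#'   dense) matrix (then `idf` defaults to ones).
#' @param energy_threshold Proportion of total squared-singular-value
#'   energy to retain, in (0, 1]; default 0.95.
#' @param query_idf_weighting Should [embed_query()] weight query entries
#'   by idf (default `TRUE`) rather than raw indicators?
#' @return An object of class `polsa_model` with elements `k`,
#'   `singular_values`, `term_factors` (T x k), `heading_vectors`
#'   (H x k), `idf`, `energy_fraction`, `energy_threshold`,
#'   `heading_ids`, `term_ids`, `query_idf_weighting`.
#' @export
fit_semantic_model <- function(weighted, energy_threshold = 0.95,
                               query_idf_weighting = TRUE) {
  stopifnot(energy_threshold > 0, energy_threshold <= 1)
  if (is.list(weighted) && !is.null(weighted$weights)) {
    w <- weighted$weights
    idf <- weighted$idf
  } else {
    w <- weighted
    idf <- rep(1, nrow(weighted))
  }
  dense <- as.matrix(w)
  if (all(dense == 0)) {
    stop("fit_semantic_model: weighted matrix is all zero", call. = FALSE)
  }
  sv <- tryCatch(svd(dense), error = function(e) {
    stop("fit_semantic_model: SVD failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
  # numerically-zero components carry no energy and are never retained
  tol <- max(dim(dense)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  energy <- sv$d^2
  total <- sum(energy)
  cum_frac <- cumsum(energy) / total
  k <- which(cum_frac >= energy_threshold - 1e-12)[1]
  if (is.na(k)) k <- sum(pos)
  k <- min(k, sum(pos))
  k <- max(k, 1L)
  structure(
    list(
      k = as.integer(k),
      singular_values = sv$d[seq_len(k)],
      term_factors = sv$u[, seq_len(k), drop = FALSE],
      heading_vectors = sv$v[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], nrow = k),
      idf = idf,
      energy_fraction = cum_frac[k],
      energy_threshold = energy_threshold,
      heading_ids = colnames(w),
      term_ids = rownames(w),
      query_idf_weighting = query_idf_weighting
    ),
    class = "polsa_model"
  )
}

#' @export
print.polsa_model <- function(x, ...) {
  cat("<polsa_model> ", length(x$term_ids), " terms x ",
    length(x$heading_ids), " headings, rank k = ", x$k,
    sprintf(" (%.1f%% energy retained)", 100 * x$energy_fraction), "\n",
    sep = ""
  )
  invisible(x)
}

#' Fold a query into the latent space
#'
#' Builds a term-space pseudo-document with (by default) the idf weight
#' at each resolved query term's row, and projects it with the standard
#' LSA folding-in map `q_hat = t(q) %*% U_k`.  The construction is
#' linear: a multi-term query embeds to the sum of its single-term
#' embeddings.
#'
#' @param model A `polsa_model`.
#' @param query_terms Character vector of query strings; each is
#'   normalized and looked up as a dictionary surface.
#' @param dictionary The `polsa_dictionary` the model was built with.
#' @return Numeric latent vector of length `model$k`, with attribute
#'   `resolved` (tibble: `query`, `term_id`).
#' @export
embed_query <- function(model, query_terms, dictionary) {
  stopifnot(inherits(model, "polsa_model"))
  surfaces <- vapply(query_terms, normalize_surface, character(1),
    USE.NAMES = FALSE
  )
  tids <- vapply(surfaces, function(s) lookup_surface(dictionary, s),
    integer(1),
    USE.NAMES = FALSE
  )
  if (all(is.na(tids))) {
    near <- unique(unlist(lapply(
      surfaces,
      function(s) {
        utils::head(
          agrep(s, dictionary$surfaces, max.distance = 2, value = TRUE), 3
        )
      }
    )))
    stop(
      "query out of dictionary: ",
      paste(sQuote(surfaces), collapse = ", "),
      if (length(near) > 0L) {
        paste0("; near misses: ", paste(sQuote(near), collapse = ", "))
      } else {
        ""
      },
      call. = FALSE
    )
  }
  q <- numeric(length(model$term_ids))
  for (tid in tids[!is.na(tids)]) {
    wgt <- if (isTRUE(model$query_idf_weighting)) model$idf[tid] else 1
    q[tid] <- q[tid] + wgt
  }
  vec <- drop(crossprod(q, model$term_factors))
  attr(vec, "resolved") <- tibble::tibble(
    query = surfaces[!is.na(tids)],
    term_id = tids[!is.na(tids)]
  )
  vec
}

#' Rank ontology headings against a query vector
#'
#' Cosine similarity between the folded-in query and every heading's
#' latent vector, sorted descending with heading-id tie-break.  Headings
#' with an all-zero latent vector get cosine 0.  Cosines are clipped to
#' `[-1, 1]` against round-off.
#'
#' @param model A `polsa_model`.
#' @param query_vec Latent vector from [embed_query()].
#' @return Tibble with columns `heading_id`, `cosine`, `rank` (1-based).
#' @export
rank_headings <- function(model, query_vec) {
  stopifnot(inherits(model, "polsa_model"))
  qn <- sqrt(sum(query_vec^2))
  if (qn == 0) {
    stop("rank_headings: query vector is zero", call. = FALSE)
  }
  hv <- model$heading_vectors
  hn <- sqrt(rowSums(hv^2))
  num <- drop(hv %*% query_vec)
  # a heading absent from the weighted matrix has a latent row that is
  # zero only up to SVD round-off; treat it as zero, cosine 0
  tol <- max(model$singular_values) * 1e-12
  cosine <- ifelse(hn > tol, num / (hn * qn), 0)
  # similarities that are zero analytically come back as +/-1e-16 noise;
  # snap them so ties resolve deterministically by heading id
  cosine[abs(cosine) < 1e-12] <- 0
  cosine <- pmin(pmax(cosine, -1), 1)
  ord <- order(-cosine, model$heading_ids, method = "radix")
  tibble::tibble(
    heading_id = model$heading_ids[ord],
    cosine = cosine[ord],
    rank = seq_along(ord)
  )
}

#' Query a model end to end
#'
#' Convenience wrapper: [embed_query()] then [rank_headings()].
#'
#' @inheritParams embed_query
#' @return Ranking tibble as from [rank_headings()].
#' @export
query_model <- function(model, query_terms, dictionary) {
  rank_headings(model, embed_query(model, query_terms, dictionary))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the spectrum of a fitted semantic model
#'
#' One row per retained component: singular value, its energy share and
#' the cumulative energy fraction.
#'
#' @param x A `polsa_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `singular_value`, `energy`,
#'   `energy_share`, `cumulative_energy`.
#' @method tidy polsa_model
#' @export
tidy.polsa_model <- function(x, ...) {
  e <- x$singular_values^2
  total <- sum(e) / x$energy_fraction # back out full-spectrum energy
  tibble::tibble(
    component = seq_len(x$k),
    singular_value = x$singular_values,
    energy = e,
    energy_share = e / total,
    cumulative_energy = cumsum(e) / total
  )
}

#' One-row summary of a fitted semantic model
#'
#' @param x A `polsa_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_terms`, `n_headings`, `k`,
#'   `energy_fraction`, `energy_threshold`.
#' @method glance polsa_model
#' @export
glance.polsa_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$term_ids),
    n_headings = length(x$heading_ids),
    k = x$k,
    energy_fraction = x$energy_fraction,
    energy_threshold = x$energy_threshold
  )
}

#' Scree plot of retained spectral energy
#'
#' @param object A `polsa_model`.
#' @param ... Unused.
#' @return A ggplot: cumulative energy fraction against component, with
#'   the energy threshold drawn as a horizontal line.
#' @method autoplot polsa_model
#' @export
autoplot.polsa_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$component, y = .data$cumulative_energy)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      yintercept = object$energy_threshold,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "component",
      y = "cumulative energy fraction",
      title = sprintf(
        "retained rank k = %d (%.1f%% of spectral energy)",
        object$k, 100 * object$energy_fraction
      )
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
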