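#' One-dimensional fuzzy c-means
#'
#' Standard Bezdek fuzzy c-means on a vector of scores, specialised to
#' one dimension and three clusters as used for relevance grouping.
#' Memberships follow `u_ij = 1 / sum_l (|x_i - c_j| / |x_i - c_l|)^(2/(m-1))`
#' and centers `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`; the objective
#' `sum_ij u_ij^m (x_i - c_j)^2` is non-increasing across iterations.  A
#' point coinciding exactly with a center takes membership 1 there (split
#' equally when several centers coincide with it).  Initialization is
#' deterministic: centers start at the 10th, 50th and 90th percentiles of
#' the scores, so no random seed is involved.
#'
#' @param scores Numeric vector with at least `n_clusters` distinct
#'   values.
#' @param n_clusters Number of clusters (default 3).
#' @param m Fuzzifier, > 1 (default 2).
#' @param tolerance Convergence tolerance on maximum center movement
#'   (default 1e-6).
#' @param max_iterations Iteration cap (default 300); non-convergence
#'   returns the best iterate with a warning.
#' @return List with `centers` (ascending), `memberships` (n x c matrix,
#'   columns ordered as `centers`), `objective` (trace, one value per
#'   iteration) and `iterations`.
#' @export
fuzzy_cmeans_1d <- function(scores, n_clusters = 3L, m = 2,
                            tolerance = 1e-6, max_iterations = 300L) {
  stopifnot(m > 1, n_clusters >= 2L)
  x <- as.numeric(scores)
  if (length(unique(x)) < n_clusters) {
    stop("degenerate score distribution: need at least ", n_clusters,
      " distinct score values",
      call. = FALSE
    )
  }
  centers <- stats::quantile(
    x,
    probs = seq(0.1, 0.9, length.out = n_clusters),
    names = FALSE, type = 7
  )
  # percentile init can collide on skewed data; nudge apart deterministically
  if (anyDuplicated(centers)) {
    centers <- centers +
      seq(0, diff(range(x)) * 1e-6, length.out = n_clusters)
  }
  expo <- 2 / (m - 1)
  objective <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iterations)) {
    d <- abs(outer(x, centers, "-"))
    u <- fcm_memberships(d, expo)
    objective <- c(objective, sum(u^m * d^2))
    new_centers <- colSums(u^m * x) / colSums(u^m)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tolerance) break
  }
  if (it == max_iterations) {
    warning("fuzzy_cmeans_1d: not converged after ", max_iterations,
      " iterations; returning best iterate",
      call. = FALSE
    )
  }
  # final memberships at the converged centers, columns sorted ascending
  d <- abs(outer(x, centers, "-"))
  u <- fcm_memberships(d, expo)
  ord <- order(centers)
  list(
    centers = centers[ord],
    memberships = u[, ord, drop = FALSE],
    objective = objective,
    iterations = it
  )
}

# membership update with the exact-coincidence singularity rule
fcm_memberships <- function(d, expo) {
  n <- nrow(d)
  c <- ncol(d)
  u <- matrix(0, n, c)
  zero <- d == 0
  any_zero <- rowSums(zero) > 0
  if (any(!any_zero)) {
    dd <- d[!any_zero, , drop = FALSE]^(-expo)
    u[!any_zero, ] <- dd / rowSums(dd)
  }
  if (any(any_zero)) {
    z <- zero[any_zero, , drop = FALSE]
    u[any_zero, ] <- z / rowSums(z)
  }
  u
}

#' Partition a ranking into relevance groups
#'
#' Runs [fuzzy_cmeans_1d()] on the cosine scores of a ranking and labels
#' the three clusters by center order: highest center `"highly"`
#' (highly associated), middle `"possibly"` (possibly associated),
#' lowest `"unknown"`.  The final hard grouping is by cutoff intervals —
#' the cutoffs are the midpoints between adjacent sorted centers — so
#' groups are contiguous in score, matching the data-driven cut-off
#' reading: the boundaries are re-estimated from each query's score
#' distribution rather than fixed globally.
#'
#' @param ranked Tibble from [rank_headings()].
#' @param m,tolerance,max_iterations Passed to [fuzzy_cmeans_1d()].
#' @param lenient If `TRUE`, a degenerate score distribution (fewer than
#'   3 distinct values) groups every heading `"unknown"` with a warning
#'   instead of failing.
#' @return The ranking tibble with added columns `membership_unknown`,
#'   `membership_possibly`, `membership_highly` and `group` (factor with
#'   levels unknown < possibly < highly), plus attributes `centers`
#'   (ascending), `cutoffs` (`c(low, high)`) and class
#'   `polsa_relevance`.
#' @export
assign_groups <- function(ranked, m = 2, tolerance = 1e-6,
                          max_iterations = 300L, lenient = FALSE) {
  stopifnot(nrow(ranked) > 0L, "cosine" %in% names(ranked))
  fcm <- tryCatch(
    fuzzy_cmeans_1d(ranked$cosine,
      n_clusters = 3L, m = m,
      tolerance = tolerance, max_iterations = max_iterations
    ),
    error = function(e) {
      if (lenient && grepl("degenerate score distribution",
        conditionMessage(e),
        fixed = TRUE
      )) {
        NULL
      } else {
        stop(e)
      }
    }
  )
  lev <- c("unknown", "possibly", "highly")
  if (is.null(fcm)) {
    warning("assign_groups: degenerate score distribution; ",
      "all headings grouped 'unknown'",
      call. = FALSE
    )
    out <- ranked
    out$membership_unknown <- 1
    out$membership_possibly <- 0
    out$membership_highly <- 0
    out$group <- factor("unknown", levels = lev, ordered = TRUE)
    return(new_relevance(out, centers = NULL, cutoffs = NULL))
  }
  centers <- fcm$centers
  cutoffs <- c(
    low = (centers[1] + centers[2]) / 2,
    high = (centers[2] + centers[3]) / 2
  )
  out <- ranked
  out$membership_unknown <- fcm$memberships[, 1]
  out$membership_possibly <- fcm$memberships[, 2]
  out$membership_highly <- fcm$memberships[, 3]
  out$group <- factor(
    ifelse(ranked$cosine >= cutoffs["high"], "highly",
      ifelse(ranked$cosine >= cutoffs["low"], "possibly", "unknown")
    ),
    levels = lev, ordered = TRUE
  )
  new_relevance(out, centers = centers, cutoffs = cutoffs)
}

new_relevance <- function(tbl, centers, cutoffs) {
  structure(tbl,
    centers = centers, cutoffs = cutoffs,
    class = c("polsa_relevance", class(tbl))
  )
}

#' Data-driven relevance cutoffs of a grouped ranking
#'
#' @param assignments A `polsa_relevance` from [assign_groups()].
#' @return Named numeric vector `c(low, high)`, or `NULL` for a
#'   degenerate grouping.
#' @export
relevance_cutoffs <- function(assignments) {
  attr(assignments, "cutoffs")
}

#' Tidy a relevance assignment
#'
#' @param x A `polsa_relevance`.
#' @param ... Unused.
#' @return A plain tibble of the per-heading rows (rank, heading id,
#'   cosine, memberships, group).
#' @method tidy polsa_relevance
#' @export
tidy.polsa_relevance <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a relevance assignment
#'
#' @param x A `polsa_relevance`.
#' @param ... Unused.
#' @return A one-row tibble: group sizes, centers and cutoffs.
#' @method glance polsa_relevance
#' @export
glance.polsa_relevance <- function(x, ...) {
  ctr <- attr(x, "centers")
  cut <- attr(x, "cutoffs")
  tibble::tibble(
    n_headings = nrow(x),
    n_highly = sum(x$group == "highly"),
    n_possibly = sum(x$group == "possibly"),
    n_unknown = sum(x$group == "unknown"),
    center_unknown = if (is.null(ctr)) NA_real_ else ctr[1],
    center_possibly = if (is.null(ctr)) NA_real_ else ctr[2],
    center_highly = if (is.null(ctr)) NA_real_ else ctr[3],
    cutoff_low = if (is.null(cut)) NA_real_ else unname(cut["low"]),
    cutoff_high = if (is.null(cut)) NA_real_ else unname(cut["high"])
  )
}

#' Plot a grouped ranking
#'
#' Cosine score against rank, colored by relevance group, with the
#' data-driven cutoffs drawn as horizontal lines.
#'
#' @param object A `polsa_relevance`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polsa_relevance
#' @export
autoplot.polsa_relevance <- function(object, ...) {
  d <- tidy(object)
  cut <- attr(object, "cutoffs")
  p <- ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$rank, y = .data$cosine, color = .data$group)
  ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(
      x = "rank", y = "cosine similarity", color = "relevance"
    )
  if (!is.null(cut)) {
    p <- p + ggplot2::geom_hline(yintercept = cut, linetype = "dashed")
  }
  p
}

#' Export a grouped ranking as TSV
#'
#' Columns: rank, heading_id, name, cosine, group, the three
#' memberships.
#'
#' @param assignments A `polsa_relevance`.
#' @param ontology A `polsa_ontology` supplying heading names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grouped_ranking <- function(assignments, ontology, path) {
  h <- ontology$headings
  nm <- h$preferred_name[match(assignments$heading_id, h$heading_id)]
  lines <- c(
    paste(c(
      "rank", "heading_id", "name", "cosine", "group",
      "membership_unknown", "membership_possibly", "membership_highly"
    ), collapse = "\t"),
    vapply(seq_len(nrow(assignments)), function(i) {
      paste(c(
        assignments$rank[i], assignments$heading_id[i], nm[i],
        fmt_num(assignments$cosine[i]),
        as.character(assignments$group[i]),
        fmt_num(assignments$membership_unknown[i]),
        fmt_num(assignments$membership_possibly[i]),
        fmt_num(assignments$membership_highly[i])
      ), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting for file output
fmt_num <- function(x) {
  sprintf("%.17g", x)
}
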