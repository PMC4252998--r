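#' Build a hierarchical association network
#'
#' Reverse ontology mapping: headings whose relevance group is in
#' `include_groups` are re-attached to the ontology under their full
#' ancestor chains, giving a collapsible hierarchy rooted at the query.
#' Shared ancestors are merged into single nodes; a heading occupying
#' several tree positions (the MeSH polyhierarchy) appears once per
#' position, while `n_relevant` counts distinct headings.  Ancestors that
#' are not themselves relevant are included as structural nodes without
#' scores.  Children are ordered by the best cosine among their
#' descendants, descending, so the strongest associations read top-down.
#'
#' @param query Query text used to name the root.
#' @param assignments A `polsa_relevance` from [assign_groups()].
#' @param ontology The `polsa_ontology`.
#' @param include_groups Relevance labels to keep (default `"highly"`
#'   and `"possibly"`).
#' @return An object of class `polsa_network`: list with `query`, `root`
#'   (nested node: `name`, optional `tree_number`, `heading_id`,
#'   `cosine`, `group`, and `children`) and `n_relevant`.
#' @export
build_network <- function(query, assignments, ontology,
                          include_groups = c("highly", "possibly")) {
  stopifnot(inherits(ontology, "polsa_ontology"))
  rel <- assignments[as.character(assignments$group) %in% include_groups, ]
  if (nrow(rel) == 0L) {
    warning("build_network: no relevant headings for query '", query, "'",
      call. = FALSE
    )
    return(structure(
      list(
        query = query,
        root = list(name = query, children = list()),
        n_relevant = 0L
      ),
      class = "polsa_network"
    ))
  }
  h <- ontology$headings
  root <- list(name = query, children = list())
  for (i in seq_len(nrow(rel))) {
    hid <- rel$heading_id[[i]]
    row <- match(hid, h$heading_id)
    if (is.na(row)) {
      stop("build_network: heading ", hid, " not in ontology",
        call. = FALSE
      )
    }
    for (tn in h$tree_numbers[[row]]) {
      chain <- ancestor_chain(ontology, hid, tn)
      leaf_info <- list(
        heading_id = hid,
        cosine = rel$cosine[[i]],
        group = as.character(rel$group[[i]])
      )
      root <- insert_chain(root, chain, leaf_info)
    }
  }
  root <- sort_children(root)
  structure(
    list(
      query = query,
      root = root,
      n_relevant = length(unique(rel$heading_id))
    ),
    class = "polsa_network"
  )
}

# merge one root-to-heading chain into the hierarchy; the terminal node
# receives the score payload
insert_chain <- function(node, chain, leaf_info, depth = 1L) {
  nm <- chain$name[[depth]]
  tn <- chain$tree_number[[depth]]
  idx <- NULL
  for (j in seq_along(node$children)) {
    if (node$children[[j]]$name == nm &&
      identical(node$children[[j]]$tree_number, tn)) {
      idx <- j
      break
    }
  }
  if (is.null(idx)) {
    node$children <- c(node$children,
      list(list(name = nm, tree_number = tn, children = list()))
    )
    idx <- length(node$children)
  }
  if (depth == nrow(chain)) {
    node$children[[idx]]$heading_id <- leaf_info$heading_id
    node$children[[idx]]$cosine <- leaf_info$cosine
    node$children[[idx]]$group <- leaf_info$group
  } else {
    node$children[[idx]] <- insert_chain(
      node$children[[idx]], chain, leaf_info, depth + 1L
    )
  }
  node
}

# order children by best descendant cosine (desc), name tie-break
sort_children <- function(node) {
  if (length(node$children) == 0L) {
    return(node)
  }
  node$children <- lapply(node$children, sort_children)
  best <- vapply(node$children, best_cosine, numeric(1))
  nms <- vapply(node$children, function(ch) ch$name, character(1))
  node$children <- node$children[order(-best, nms, method = "radix")]
  node
}

best_cosine <- function(node) {
  own <- if (is.null(node$cosine)) -Inf else node$cosine
  if (length(node$children) == 0L) {
    return(own)
  }
  max(own, vapply(node$children, best_cosine, numeric(1)))
}

#' @export
print.polsa_network <- function(x, ...) {
  cat("<polsa_network> query '", x$query, "', ", x$n_relevant,
    " relevant heading(s)\n",
    sep = ""
  )
  print_node <- function(node, indent) {
    score <- if (!is.null(node$cosine)) {
      sprintf(" [%s %.4f]", node$group, node$cosine)
    } else {
      ""
    }
    cat(strrep("  ", indent), node$name, score, "\n", sep = "")
    for (ch in node$children) print_node(ch, indent + 1L)
  }
  print_node(x$root, 0L)
  invisible(x)
}

#' Serialize an association network as D3 flare-style JSON
#'
#' Nodes are objects with `"name"`, then optional `"cosine"`, `"group"`,
#' `"heading_id"`, `"tree_number"`, then `"children"`, in that key
#' order.  Serialization is deterministic: the same network yields
#' byte-identical output.
#'
#' @param network A `polsa_network`.
#' @return A single JSON string (UTF-8, no trailing newline).
#' @export
network_to_json <- function(network) {
  stopifnot(inherits(network, "polsa_network"))
  as_flare <- function(node) {
    out <- list(name = node$name)
    if (!is.null(node$cosine)) out$cosine <- node$cosine
    if (!is.null(node$group)) out$group <- node$group
    if (!is.null(node$heading_id)) out$heading_id <- node$heading_id
    if (!is.null(node$tree_number)) out$tree_number <- node$tree_number
    out$children <- lapply(node$children, as_flare)
    out
  }
  jsonlite::toJSON(as_flare(network$root),
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
}

#' Parse flare JSON back into a network
#'
#' Inverse of [network_to_json()] up to node ordering metadata; useful
#' for round-trip checks and for consuming cached query results.
#'
#' @param json JSON string.
#' @param query Root/query name override (default: the root's `name`).
#' @return A `polsa_network`.
#' @export
network_from_json <- function(json, query = NULL) {
  from_flare <- function(obj) {
    node <- list(name = obj$name)
    if (!is.null(obj$tree_number)) node$tree_number <- obj$tree_number
    node$children <- lapply(obj$children, from_flare)
    if (!is.null(obj$heading_id)) node$heading_id <- obj$heading_id
    if (!is.null(obj$cosine)) node$cosine <- obj$cosine
    if (!is.null(obj$group)) node$group <- obj$group
    node
  }
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  root <- from_flare(obj)
  leaves <- function(node) {
    own <- if (!is.null(node$heading_id)) node$heading_id else character(0)
    c(own, unlist(lapply(node$children, leaves)))
  }
  structure(
    list(
      query = query %||% root$name,
      root = root,
      n_relevant = length(unique(leaves(root)))
    ),
    class = "polsa_network"
  )
}

#' Flatten a network to an edge list
#'
#' @param network A `polsa_network`.
#' @return Tibble with columns `parent_name`, `child_name`, `heading_id`,
#'   `cosine`, `group` (NA for structural nodes), one row per edge in
#'   display order.
#' @export
network_edges <- function(network) {
  rows <- list()
  walk <- function(node) {
    for (ch in node$children) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        parent_name = node$name,
        child_name = ch$name,
        heading_id = ch$heading_id %||% NA_character_,
        cosine = ch$cosine %||% NA_real_,
        group = ch$group %||% NA_character_
      )
      walk(ch)
    }
  }
  walk(network$root)
  if (length(rows) == 0L) {
    return(tibble::tibble(
      parent_name = character(0), child_name = character(0),
      heading_id = character(0), cosine = numeric(0), group = character(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Write a network edge list as TSV
#'
#' @param network A `polsa_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  e <- network_edges(network)
  lines <- c(
    paste(names(e), collapse = "\t"),
    vapply(seq_len(nrow(e)), function(i) {
      paste(c(
        e$parent_name[i], e$child_name[i],
        ifelse(is.na(e$heading_id[i]), "", e$heading_id[i]),
        ifelse(is.na(e$cosine[i]), "", fmt_num(e$cosine[i])),
        ifelse(is.na(e$group[i]), "", e$group[i])
      ), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Plot an association network as a dendrogram-style tree
#'
#' A simple left-to-right layout: leaves evenly spaced vertically,
#' internal nodes at the mean of their children, segments drawn between
#' parent and child, score-bearing nodes colored by relevance group.
#'
#' @param object A `polsa_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polsa_network
#' @export
autoplot.polsa_network <- function(object, ...) {
  nodes <- list()
  edges <- list()
  counter <- new.env(parent = emptyenv())
  counter$leaf_y <- 0
  layout <- function(node, depth) {
    if (length(node$children) == 0L) {
      counter$leaf_y <- counter$leaf_y + 1
      y <- counter$leaf_y
    } else {
      ys <- vapply(node$children, function(ch) layout(ch, depth + 1L),
        numeric(1)
      )
      y <- mean(ys)
      for (ch_y in ys) {
        edges[[length(edges) + 1L]] <<- tibble::tibble(
          x = depth, y = y, xend = depth + 1L, yend = ch_y
        )
      }
    }
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(
      x = depth, y = y, name = node$name,
      group = node$group %||% NA_character_
    )
    y
  }
  layout(object$root, 0L)
  nd <- dplyr::bind_rows(nodes)
  eg <- if (length(edges)) dplyr::bind_rows(edges) else NULL
  p <- ggplot2::ggplot()
  if (!is.null(eg)) {
    p <- p + ggplot2::geom_segment(
      data = eg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend
      ),
      color = "grey60"
    )
  }
  p +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$group),
      size = 2
    ) +
    ggplot2::geom_text(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      hjust = -0.08, size = 2.8
    ) +
    ggplot2::scale_x_continuous(
      expand = ggplot2::expansion(mult = c(0.05, 0.3))
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "relevance", title = object$query)
}
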