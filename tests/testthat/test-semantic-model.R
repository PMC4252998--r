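test_that("TF-IDF weighting follows count times log inverse frequency", {
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 1, 2),
    j = c(1, 2, 3, 4, 1),
    x = c(1, 2, 1, 3, 2),
    dims = c(3, 4),
    dimnames = list(c("t1", "t2", "t3"), sprintf("H%d", 1:4))
  )
  w <- tfidf_weight(counts)
  # term in every column: weight zero everywhere
  expect_equal(unname(as.matrix(w$weights)[1, ]), rep(0, 4))
  # df 1 in 4 columns: w = 2 * ln 4
  expect_equal(w$weights[2, 1], 2 * log(4), tolerance = 1e-12)
  expect_equal(w$weights[2, 1], 2.7726, tolerance = 1e-4)
  # zero counts stay zero, unseen term row is all zero with idf 0
  expect_equal(w$weights[3, 2], 0)
  expect_equal(unname(w$idf), c(0, log(4), 0))

  zero <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(2, 2)
  )
  expect_error(tfidf_weight(zero), "all zero")
})

test_that("energy cutoff retains the minimal rank k", {
  # singular values (3, 2, 1): energy fractions 9/14, 13/14, 14/14
  w <- matrix_with_singular_values(c(3, 2, 1))
  fit <- fit_semantic_model(w, energy_threshold = 0.95)
  expect_equal(fit$k, 3L)
  expect_equal(fit$singular_values, c(3, 2, 1), tolerance = 1e-9)
  expect_equal(fit$energy_fraction, 1, tolerance = 1e-12)
  # at 0.9 the first two components suffice (13/14 = 0.9286)
  expect_equal(fit_semantic_model(w, energy_threshold = 0.9)$k, 2L)
  # threshold below the first component's share
  expect_equal(fit_semantic_model(w, energy_threshold = 0.6)$k, 1L)

  # threshold 1.0 on a rank-r matrix retains exactly r components
  expect_equal(fit_semantic_model(w, energy_threshold = 1.0)$k, 3L)
  r1 <- matrix_with_singular_values(c(2))
  expect_equal(fit_semantic_model(r1, energy_threshold = 0.5)$k, 1L)
  expect_equal(fit_semantic_model(r1, energy_threshold = 1.0)$k, 1L)
})

test_that("retained rank is minimal for random fits", {
  for (seed in 1:6) {
    w <- tfidf_weight(small_counts(seed))
    fit <- fit_semantic_model(w, energy_threshold = 0.9)
    e <- svd(as.matrix(w$weights))$d^2
    frac <- cumsum(e) / sum(e)
    expect_gte(frac[fit$k], 0.9 - 1e-12)
    if (fit$k > 1L) expect_lt(frac[fit$k - 1L], 0.9)
    expect_equal(fit$energy_fraction, frac[fit$k], tolerance = 1e-12)
  }
})

test_that("query folding is linear and fails informatively out of dictionary", {
  d <- make_surface_dictionary(c("alpha", "beta", "gamma delta"))
  rec <- tibble::tibble(
    record_id = c("r1", "r2"),
    year = 2000L,
    title = c("alpha alpha beta", "gamma delta beta"),
    abstract = "",
    annotations = list("HA", "HB")
  )
  counts <- accumulate_counts(rec, d, c("HA", "HB"))
  model <- fit_semantic_model(tfidf_weight(counts), energy_threshold = 1.0)

  va <- embed_query(model, "alpha", d)
  vb <- embed_query(model, "beta", d)
  vab <- embed_query(model, c("alpha", "beta"), d)
  expect_equal(as.numeric(vab), as.numeric(va) + as.numeric(vb),
    tolerance = 1e-12
  )
  # multi-gram surfaces resolve as one term
  expect_equal(nrow(attr(embed_query(model, "gamma delta", d), "resolved")), 1L)
  err <- tryCatch(embed_query(model, "alhpa", d), error = identity)
  expect_match(conditionMessage(err), "query out of dictionary")
  expect_match(conditionMessage(err), "alpha") # near miss suggested
})

test_that("a term unique to one heading ranks that heading first", {
  d <- make_surface_dictionary(c("alpha", "beta"))
  rec <- tibble::tibble(
    record_id = c("r1", "r2"),
    year = 2000L,
    title = c("alpha alpha beta", "beta beta"),
    abstract = "",
    annotations = list("HA", "HB")
  )
  counts <- accumulate_counts(rec, d, c("HA", "HB"))
  wt <- tfidf_weight(counts)
  model <- fit_semantic_model(wt, energy_threshold = 1.0)
  ranked <- query_model(model, "alpha", d)
  expect_equal(ranked$heading_id[1], "HA")
  # brute-force cosine in the raw TF-IDF space agrees
  w <- as.matrix(wt$weights)
  q <- c(wt$idf[1], 0)
  brute <- drop(crossprod(w, q)) /
    (sqrt(colSums(w^2)) * sqrt(sum(q^2)))
  expect_equal(names(which.max(brute)), "HA")
  expect_equal(ranked$cosine[ranked$heading_id == "HA"],
    unname(brute["HA"]),
    tolerance = 1e-8
  )
})

test_that("full-rank latent cosines reproduce original-space cosines", {
  for (seed in 1:10) {
    wt <- tfidf_weight(small_counts(seed))
    model <- fit_semantic_model(wt, energy_threshold = 1.0)
    w <- as.matrix(wt$weights)
    set.seed(seed + 1000)
    # pseudo-document in the span of the heading columns
    q <- drop(w %*% stats::runif(ncol(w)))
    latent <- rank_headings(model, drop(crossprod(q, model$term_factors)))
    cn <- sqrt(colSums(w^2))
    brute <- ifelse(cn > 0, drop(crossprod(w, q)) / (cn * sqrt(sum(q^2))), 0)
    ord <- order(-brute, colnames(w), method = "radix")
    expect_equal(latent$heading_id, colnames(w)[ord])
    expect_equal(latent$cosine, unname(brute[ord]), tolerance = 1e-8)
  }
})

test_that("cosine identities, clipping and scale invariance hold", {
  wt <- tfidf_weight(small_counts(3))
  model <- fit_semantic_model(wt, energy_threshold = 1.0)
  # query equal to one heading's latent vector: cosine 1, rank 1
  j <- 2L
  ranked <- rank_headings(model, model$heading_vectors[j, ])
  expect_equal(ranked$heading_id[1], model$heading_ids[j])
  expect_equal(ranked$cosine[1], 1, tolerance = 1e-12)
  expect_true(all(ranked$cosine >= -1 & ranked$cosine <= 1))
  expect_error(rank_headings(model, rep(0, model$k)), "zero")

  # scaling the weighted matrix leaves cosines and ranks unchanged
  scaled <- fit_semantic_model(
    list(weights = wt$weights * 7.3, idf = wt$idf),
    energy_threshold = 1.0
  )
  qv1 <- drop(crossprod(
    replace(numeric(nrow(wt$weights)), 1, 1), model$term_factors
  ))
  qv2 <- drop(crossprod(
    replace(numeric(nrow(wt$weights)), 1, 1), scaled$term_factors
  ))
  r1 <- rank_headings(model, qv1)
  r2 <- rank_headings(scaled, qv2)
  expect_equal(r1$heading_id, r2$heading_id)
  expect_equal(r1$cosine, r2$cosine, tolerance = 1e-9)
})

test_that("tidy and glance expose the retained spectrum", {
  w <- matrix_with_singular_values(c(3, 2, 1))
  fit <- fit_semantic_model(w, energy_threshold = 0.9)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$k)
  expect_equal(td$cumulative_energy[fit$k], fit$energy_fraction,
    tolerance = 1e-12
  )
  expect_equal(td$singular_value, c(3, 2), tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$k, 2L)
  expect_equal(g$n_headings, 4L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
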