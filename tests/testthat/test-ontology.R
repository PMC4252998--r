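test_that("TSV parsing transcribes descriptors, categories and counts", {
  ont <- fixture_ontology()
  expect_s3_class(ont, "polsa_ontology")
  expect_equal(nrow(ont$headings), 6L)
  h <- ont$headings
  expect_equal(h$preferred_name[h$heading_id == "D1"], "Pneumonia")
  expect_equal(h$categories[[which(h$heading_id == "D1")]], "C")
  expect_equal(h$categories[[which(h$heading_id == "D3")]], "J")
  # two tree numbers under the same category collapse to one letter
  expect_equal(h$categories[[which(h$heading_id == "D6")]], "C")
  expect_equal(h$abstract_count[h$heading_id == "D4"], 3000L)
  expect_equal(h$entry_terms[[which(h$heading_id == "D1")]],
    "Lung Inflammation")
})

test_that("malformed, empty and duplicate ontology input raises parse errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_ontology(empty, "tsv"), "empty|no descriptor")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("only_one_column", bad)
  expect_error(read_ontology(bad, "tsv"), "record 1")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("D1\tA\t\tC01\t10", "D1\tB\t\tC02\t10"), dup)
  expect_error(read_ontology(dup, "tsv"), "duplicate heading_id")

  expect_error(read_ontology(tempfile(), "tsv"), "does not exist")
})

test_that("MeSH descriptor XML parsing captures names, terms and trees", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<DescriptorRecordSet>
 <DescriptorRecord>
  <DescriptorUI>D011014</DescriptorUI>
  <DescriptorName><String>Pneumonia</String></DescriptorName>
  <TreeNumberList><TreeNumber>C08.381</TreeNumber></TreeNumberList>
  <ConceptList><Concept><TermList>
    <Term><String>Pneumonia</String></Term>
    <Term><String>Lung Inflammation</String></Term>
  </TermList></Concept></ConceptList>
 </DescriptorRecord>
 <DescriptorRecord>
  <DescriptorUI>D005350</DescriptorUI>
  <DescriptorName><String>Fibroma</String></DescriptorName>
  <TreeNumberList>
    <TreeNumber>C04.557</TreeNumber>
    <TreeNumber>C18.452</TreeNumber>
  </TreeNumberList>
 </DescriptorRecord>
</DescriptorRecordSet>', xml)
  ont <- read_ontology(xml, format = "mesh-xml")
  h <- ont$headings
  expect_equal(nrow(h), 2L)
  expect_equal(h$heading_id, c("D011014", "D005350"))
  # preferred name is excluded from entry terms
  expect_equal(h$entry_terms[[1]], "Lung Inflammation")
  expect_equal(h$tree_numbers[[2]], c("C04.557", "C18.452"))
  expect_equal(h$categories[[2]], "C")
  # abstract counts attach later for XML input
  expect_equal(h$abstract_count, c(0L, 0L))

  broken <- withr::local_tempfile(fileext = ".xml")
  writeLines("<DescriptorRecordSet><oops>", broken)
  expect_error(read_ontology(broken, "mesh-xml"), "malformed XML")
})

test_that("abstract-count window is inclusive and enforced exhaustively", {
  ont <- make_ontology(
    heading_id = sprintf("H%d", 1:6),
    preferred_name = sprintf("name%d", 1:6),
    entry_terms = rep(list(character(0)), 6),
    tree_numbers = list("C01.1", "C01.2", "C01.3", "C01.4", "C01.5", "C01.6"),
    abstract_count = c(900L, 1000L, 25000L, 50000L, 60000L, 999L)
  )
  sel <- select_headings(ont)
  # 900, 999 (too specific) and 60000 (too general) are excluded;
  # the bounds themselves pass
  expect_setequal(sel, c("H2", "H3", "H4"))
  # ordered by descending count
  expect_equal(sel, c("H4", "H3", "H2"))
})

test_that("disease balance is a floor enforced by dropping small non-C headings", {
  ont <- make_ontology(
    heading_id = c("C1", "DD1", "DD2", "DD3"),
    preferred_name = c("c one", "d one", "d two", "d three"),
    entry_terms = rep(list(character(0)), 4),
    tree_numbers = list("C01.1", "D01.1", "D01.2", "D01.3"),
    abstract_count = c(5000L, 9000L, 7000L, 3000L)
  )
  # brute force: max subset size with C fraction >= 0.5 is 2
  expect_equal(oracle_max_selection_size(c(TRUE, FALSE, FALSE, FALSE), 0.5), 2L)
  sel <- select_headings(ont)
  expect_equal(sort(sel), c("C1", "DD1"))

  # already balanced: nothing dropped
  ont2 <- make_ontology(
    heading_id = c("C1", "C2", "DD1", "DD2"),
    preferred_name = c("c one", "c two", "d one", "d two"),
    entry_terms = rep(list(character(0)), 4),
    tree_numbers = list("C01.1", "C01.2", "D01.1", "D01.2"),
    abstract_count = c(5000L, 6000L, 9000L, 7000L)
  )
  expect_equal(length(select_headings(ont2)), 4L)
})

test_that("selection errors on empty candidates or no disease headings", {
  ont <- make_ontology(
    heading_id = c("H1", "H2"),
    preferred_name = c("a", "b"),
    entry_terms = rep(list(character(0)), 2),
    tree_numbers = list("C01.1", "D01.1"),
    abstract_count = c(10L, 99999L)
  )
  expect_error(select_headings(ont), "empty selection")

  ont2 <- make_ontology(
    heading_id = c("H1", "H2"),
    preferred_name = c("a", "b"),
    entry_terms = rep(list(character(0)), 2),
    tree_numbers = list("D01.1", "D01.2"),
    abstract_count = c(5000L, 6000L)
  )
  expect_error(select_headings(ont2), "unachievable")
})

test_that("selection predicate and balance hold on randomized trees", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 30L
    cats <- sample(c("C", "D", "F", "J"), n,
      replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)
    )
    counts <- sample(c(100L, 500:60000), n, replace = TRUE)
    ont <- make_ontology(
      heading_id = sprintf("H%02d", 1:n),
      preferred_name = sprintf("name%02d", 1:n),
      entry_terms = rep(list(character(0)), n),
      tree_numbers = as.list(sprintf("%s01.%03d", cats, 1:n)),
      abstract_count = counts
    )
    sel <- tryCatch(select_headings(ont), error = function(e) NULL)
    if (is.null(sel)) next
    h <- ont$headings
    idx <- match(sel, h$heading_id)
    expect_true(all(h$abstract_count[idx] >= 1000L))
    expect_true(all(h$abstract_count[idx] <= 50000L))
    is_c <- vapply(h$categories[idx], function(cc) "C" %in% cc, logical(1))
    expect_gte(mean(is_c), 0.5)
    # idempotence: selecting from the already-selected subtree is stable
    ont_sub <- make_ontology(
      heading_id = h$heading_id[idx],
      preferred_name = h$preferred_name[idx],
      entry_terms = h$entry_terms[idx],
      tree_numbers = h$tree_numbers[idx],
      abstract_count = h$abstract_count[idx]
    )
    expect_equal(select_headings(ont_sub), sel)
  }
})

test_that("ancestor chains walk from category root to the heading", {
  ont <- fixture_ontology()
  # depth-3 tree number gives one entry per dotted component
  chain <- ancestor_chain(ont, "D4", "C18.452.284.281")
  expect_equal(nrow(chain), 4L)
  expect_equal(chain$tree_number[1], "C18")
  expect_equal(chain$name[3], "Proteostasis Deficiencies")
  expect_equal(chain$name[4], "Amyloidosis")
  expect_match(render_chain(chain), "Proteostasis Deficiencies > Amyloidosis")

  # depth-1 tree number: the heading is its own root
  ont2 <- make_ontology("R1", "Diseases", list(character(0)),
    list("C01"), 0L)
  chain1 <- ancestor_chain(ont2, "R1", "C01")
  expect_equal(nrow(chain1), 1L)
  expect_equal(chain1$name, "Diseases")

  # unresolvable prefixes fall back to the tree-number string
  chain2 <- ancestor_chain(ont, "D1", "C08.381")
  expect_equal(chain2$name, c("C08", "Pneumonia"))

  expect_error(ancestor_chain(ont, "D1", "C99.999"), "does not belong")
  expect_error(ancestor_chain(ont, "nope", "C08.381"), "unknown heading_id")
})
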