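test_that("codes roll up to first-level labels with the population-health merge", {
  tree <- example_tree()
  expect_equal(rollup_code("N06.850.520", tree), "Population Health")
  expect_equal(rollup_code("N01.400.550", tree), "Population Health")
  expect_equal(rollup_code("H02.403.720.500", tree), "Population Health")
  # depth-2 rollup under Information Science
  expect_equal(rollup_code("L01.224.050.375", tree),
               "Computing Methodologies")
  expect_equal(rollup_code("L01.453.245.945", tree), "Informatics")
  # depth-1 rollup for diseases and techniques
  expect_equal(rollup_code("C14.907.489", tree), "Cardiovascular Diseases")
  expect_equal(rollup_code("E07.305.250.300", tree),
               "Equipment and Supplies")
  # shorter than the requested depth: maximal available depth
  expect_equal(rollup_code("L01", tree), "Information Science")
  # uncategorised codes roll to NA
  expect_true(is.na(rollup_code("B01.050", tree)))
})

test_that("co-occurrence cells count each article once per label pair", {
  tree <- example_tree()
  corpus <- dplyr::bind_rows(
    # two C14 codes (Hypertension + Myocardial Ischemia's two codes)
    # meeting one I topic: the (Cardiovascular, Computing) pair still +1
    one_article(c("Hypertension", "Myocardial Ischemia",
                  "Machine Learning"), pmid = "1"),
    one_article(c("Public Health", "Machine Learning"), pmid = "2"),
    one_article(c("Public Health", "Telemedicine"), pmid = "3"))
  m <- cooccurrence_matrix(corpus, tree, axis = "HxI")
  cell <- function(r, c) m$n[m$row_label == r & m$col_label == c]
  expect_equal(cell("Cardiovascular Diseases", "Computing Methodologies"),
               1L)
  expect_equal(cell("Population Health", "Computing Methodologies"), 2L)
  # Telemedicine owns codes in both Informatics and Computing Methodologies
  expect_equal(cell("Population Health", "Informatics"), 1L)

  # per-code counting is the flagged alternative
  m_code <- cooccurrence_matrix(corpus, tree, axis = "HxI",
                                count_by = "code")
  code_cell <- m_code$n[m_code$row_label == "Cardiovascular Diseases" &
                          m_code$col_label == "Computing Methodologies"]
  expect_equal(code_cell, 3L) # 3 C14 codes x 1 ML code

  # brute-force reconstruction: per-article label sets, pair union
  brute <- list()
  for (k in seq_len(nrow(corpus))) {
    codes <- suppressMessages(
      hitmapper:::major_topic_codes(corpus[k, ], tree))
    cats <- classify_code(codes$tree_number)
    labs <- rollup_code(codes$tree_number, tree)
    hs <- unique(labs[!is.na(cats) & cats == "H"])
    ivals <- unique(labs[!is.na(cats) & cats == "I"])
    for (a in hs) for (b in ivals) {
      key <- paste(a, b, sep = "||")
      prev <- if (is.null(brute[[key]])) 0L else brute[[key]]
      brute[[key]] <- prev + 1L
    }
  }
  for (key in names(brute)) {
    parts <- strsplit(key, "||", fixed = TRUE)[[1]]
    expect_equal(cell(parts[1], parts[2]), brute[[key]], info = key)
  }
  expect_equal(sum(m$n), sum(unlist(brute)))
})

test_that("empty corpora yield empty matrices; single-pair corpora sum to size", {
  tree <- example_tree()
  empty <- cooccurrence_matrix(one_article("x")[0, ], tree, axis = "HxI")
  expect_equal(nrow(empty), 0)

  # every article has exactly one H and one I label -> total = corpus size
  corpus <- dplyr::bind_rows(
    one_article(c("Hypertension", "Machine Learning"), pmid = "1"),
    one_article(c("Neoplasms", "Electronic Health Records"), pmid = "2"),
    one_article(c("Infections", "Communications Media"), pmid = "3"))
  m <- cooccurrence_matrix(corpus, tree, axis = "HxI")
  expect_equal(sum(m$n), nrow(corpus))
  # widened form matches the long form
  wide <- interaction_matrix(m)
  expect_equal(sum(wide), nrow(corpus))
  expect_equal(dim(wide), c(length(unique(m$row_label)),
                            length(unique(m$col_label))))
})

test_that("subtree subsets select exactly the touching articles", {
  tree <- example_tree()
  corpus <- dplyr::bind_rows(
    one_article(c("Natural Language Processing", "Heart Diseases"),
                pmid = "1"),
    one_article(c("Artificial Intelligence", "Neoplasms"), pmid = "2"),
    one_article(c("Telemedicine", "Heart Diseases"), pmid = "3"),
    one_article(c("Electronic Health Records", "Infections"), pmid = "4"))
  ai <- subset_by_subtree(corpus, tree, "Artificial Intelligence")
  expect_setequal(ai$pmid, c("1", "2"))
  ehr <- subset_by_subtree(corpus, tree, "Electronic Health Records")
  expect_setequal(ehr$pmid, "4")
  expect_lte(nrow(ai), nrow(corpus))
  # subset and complement partition the corpus
  expect_setequal(c(ai$pmid, setdiff(corpus$pmid, ai$pmid)), corpus$pmid)
  expect_error(subset_by_subtree(corpus, tree, "No Such Node"),
               "cannot resolve")
})

test_that("sankey edges conserve retained cell weights", {
  tree <- example_tree()
  corpus <- dplyr::bind_rows(
    one_article(c("Hypertension", "Machine Learning"), pmid = "1"),
    one_article(c("Hypertension", "Telemedicine"), pmid = "2"),
    one_article(c("Public Health", "Machine Learning"), pmid = "3"))
  m <- cooccurrence_matrix(corpus, tree, axis = "HxI")
  edges <- sankey_edges(m, min_count = 1)
  expect_equal(sum(edges$weight), sum(m$n[m$n >= 1]))
  expect_named(edges, c("source", "target", "weight"))
  # threshold above the maximum -> no edges
  expect_equal(nrow(sankey_edges(m, min_count = max(m$n) + 1)), 0)
  # single-cell matrix: one edge carrying the full count
  single <- cooccurrence_matrix(corpus[3, ], tree, axis = "HxI")
  e1 <- sankey_edges(single, 1)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$weight, 1L)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
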