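test_that("exclusion filter flags secondary-research records, first reason wins", {
  corpus <- dplyr::bind_rows(
    one_article(c("Meta-Analysis as Topic", "Telemedicine"), pmid = "1"),
    one_article(c("Heart Diseases", "Telemedicine"), pmid = "2",
                publication_types = c("Journal Article", "Review")),
    one_article("Telemedicine", pmid = "3",
                title = "A Bibliometric overview of informatics"),
    one_article(c("Heart Diseases", "Telemedicine"), pmid = "4"),
    # major-topic reason outranks publication type
    one_article("Systematic Reviews as Topic", pmid = "5",
                publication_types = "Review"))
  expect_equal(exclusion_reason(corpus),
               c("major_topic", "publication_type", "bibliometric_title",
                 NA, "major_topic"))
})

test_that("inclusion needs at least one H and one I major-topic code", {
  tree <- example_tree()
  corpus <- dplyr::bind_rows(
    one_article(c("Heart Diseases", "Telemedicine"), pmid = "1"),
    one_article("Heart Diseases", pmid = "2"),
    one_article(c("Telemedicine", "Diagnosis"), pmid = "3"),
    one_article(c("Equipment and Supplies", "Diagnosis"), pmid = "4"))
  expect_equal(includes_h_and_i(corpus, tree),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("codes are counted per category, per code, across all major topics", {
  tree <- example_tree()
  # one descriptor carrying both a disease and a technique code
  tr <- mesh_tree(tibble::tibble(
    ui = c("D1", "D1"), name = "Dual Branch Term",
    tree_number = c("C01.100", "E01.100")))
  cnt <- hit_counts(one_article("Dual Branch Term"), tr)
  expect_equal(cnt[, c("n_h", "n_i", "n_t")],
               tibble::tibble(n_h = 1L, n_i = 0L, n_t = 1L))

  # no categorised codes -> all zeros
  cnt0 <- suppressMessages(hit_counts(one_article("Humans"), tree))
  expect_equal(unlist(cnt0[, -1]), c(n_h = 0L, n_i = 0L, n_t = 0L))

  # per-descriptor mode collapses same-category multiplicity
  mi <- one_article("Myocardial Ischemia") # two C codes
  expect_equal(hit_counts(mi, tree)$n_h, 2L)
  expect_equal(hit_counts(mi, tree, count_by = "descriptor")$n_h, 1L)
})

test_that("hit_counts is invariant under heading permutation", {
  tree <- example_tree()
  topics <- c("Heart Diseases", "Quality of Life", "Telemedicine",
              "Remote Sensing Technology")
  base <- hit_counts(one_article(topics), tree)
  withr::with_seed(11, {
    for (k in 1:5) {
      perm <- hit_counts(one_article(sample(topics)), tree)
      expect_equal(perm, base)
    }
  })
})

test_that("fractional scores divide counts by the three-category total", {
  expect_equal(
    hit_score(tibble::tibble(n_h = 2L, n_i = 1L, n_t = 0L))[, c("h", "i", "t")],
    tibble::tibble(h = 2 / 3, i = 1 / 3, t = 0))
  expect_equal(
    hit_score(tibble::tibble(n_h = 2L, n_i = 2L, n_t = 6L))[, c("h", "i", "t")],
    tibble::tibble(h = 0.2, i = 0.2, t = 0.6))
  expect_equal(
    hit_score(tibble::tibble(n_h = 5L, n_i = 0L, n_t = 0L))[, c("h", "i", "t")],
    tibble::tibble(h = 1, i = 0, t = 0))
  expect_error(
    hit_score(tibble::tibble(n_h = 0L, n_i = 0L, n_t = 0L), strict = TRUE),
    "unscorable")
  expect_error(hit_score(tibble::tibble(n_h = -1L, n_i = 1L, n_t = 0L)),
               "non-negative")
  soft <- hit_score(tibble::tibble(n_h = c(1L, 0L), n_i = 0L, n_t = 0L))
  expect_true(is.na(soft$h[2]))
})

test_that("scores of scorable articles always sum to one", {
  withr::with_seed(3, {
    counts <- tibble::tibble(n_h = rpois(500, 2), n_i = rpois(500, 1),
                             n_t = rpois(500, 1))
    counts <- counts[counts$n_h + counts$n_i + counts$n_t > 0, ]
    sc <- hit_score(counts)
    expect_true(all(abs(sc$h + sc$i + sc$t - 1) < 1e-12))
  })
})

test_that("mean scores average the fractions and stay on the simplex", {
  two <- tibble::tibble(h = c(1, 0), i = c(0, 1), t = c(0, 0))
  expect_equal(mean_scores(two)[, 1:3],
               tibble::tibble(mean_h = 0.5, mean_i = 0.5, mean_t = 0))
  single <- tibble::tibble(h = 0.2, i = 0.2, t = 0.6)
  expect_equal(unlist(mean_scores(single)[, 1:3]),
               c(mean_h = 0.2, mean_i = 0.2, mean_t = 0.6))
  expect_error(mean_scores(single[0, ]), "no scorable")
  expect_error(mean_scores(tibble::tibble(h = NA_real_, i = NA_real_,
                                          t = NA_real_)), "no scorable")
})

test_that("filter order cannot change final corpus membership", {
  corpus <- example_corpus()
  tree <- example_tree()
  reason <- suppressMessages(exclusion_reason(corpus))
  inc <- suppressMessages(includes_h_and_i(corpus, tree))
  # both are per-record predicates: conjunction is order-free
  members_a <- corpus$pmid[is.na(reason)][inc[is.na(reason)]]
  members_b <- corpus$pmid[inc][is.na(reason[inc])]
  scored <- suppressMessages(score_corpus(corpus, tree))
  expect_setequal(members_a, members_b)
  expect_setequal(scored$pmid[scored$included], members_a)
})

test_that("score_corpus stamps the vocabulary year and reports tallies", {
  tree <- example_tree()
  expect_message(scored <- score_corpus(example_corpus(), tree),
                 class = "hitmapper_tally")
  expect_equal(attr(scored, "mesh_year"), "synthetic-2020-subset")
  # unresolvable major topics are logged, not fatal
  odd <- one_article(c("Not A Real Descriptor", "Heart Diseases",
                       "Telemedicine"))
  expect_message(cnt <- hit_counts(odd, tree), class = "hitmapper_debug")
  expect_equal(cnt$n_h, 1L)
})
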