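excluded_major_topics <- c("Systematic Reviews as Topic",
                           "Meta-Analysis as Topic")
excluded_publication_types <- c("Review", "Retracted Publication")

#' Exclusion filter for secondary-research publications
#'
#' Flags records that should not enter the H-I-T corpus: articles whose
#' major topics include "Systematic Reviews as Topic" or "Meta-Analysis as
#' Topic" (they sit inside the Information Science / Public Health branches
#' yet represent a secondary research approach, not informatics supply or
#' health demand), articles typed Review or Retracted Publication, and
#' articles with "bibliometric" in the title (case-insensitive substring).
#' The first matching reason wins, in that order.
#'
#' @param corpus A corpus tibble.
#' @return Character vector along the corpus rows: one of
#'   `"major_topic"`, `"publication_type"`, `"bibliometric_title"`, or `NA`
#'   for records that pass.
#' @export
exclusion_reason <- function(corpus) {
  validate_corpus(corpus)
  mt <- major_topics(corpus)
  bad_topic_pmids <- unique(
    mt$pmid[mt$descriptor_name %in% excluded_major_topics])
  by_topic <- corpus$pmid %in% bad_topic_pmids
  by_type <- vapply(corpus$publication_types,
                    function(pt) any(pt %in% excluded_publication_types),
                    logical(1))
  by_title <- stringr::str_detect(
    stringr::str_to_lower(corpus$title %||% ""), stringr::fixed("bibliometric"))
  by_title[is.na(by_title)] <- FALSE
  dplyr::case_when(by_topic ~ "major_topic",
                   by_type ~ "publication_type",
                   by_title ~ "bibliometric_title",
                   TRUE ~ NA_character_)
}

# major-topic tree-number codes per article: tibble(pmid, descriptor_name,
# ui, tree_number). Major topics whose names do not resolve in the tree
# (vocabulary drift across MeSH years) are reported once and dropped.
major_topic_codes <- function(corpus, tree) {
  mt <- major_topics(corpus)
  vocab <- tibble(descriptor_name = tree$name, ui = tree$ui,
                  tree_number = tree$tree_number)
  out <- dplyr::left_join(mt, vocab, by = "descriptor_name",
                          relationship = "many-to-many")
  unresolved <- unique(out$descriptor_name[is.na(out$ui)])
  if (length(unresolved) > 0) {
    inform(paste0(length(unresolved), " major-topic name(s) not in the ",
                  "vocabulary, ignored: ",
                  paste(head(unresolved, 5), collapse = "; ")),
           class = "hitmapper_debug")
  }
  out[!is.na(out$ui), , drop = FALSE]
}

#' Does an article link health demand with informatics supply?
#'
#' The corpus-inclusion rule: an article belongs to the medical-informatics
#' corpus iff at least one of its major-topic codes classifies H *and* at
#' least one classifies I.
#'
#' @param corpus A corpus tibble.
#' @param tree A [mesh_tree].
#' @param scheme A [hit_scheme].
#' @return Logical vector along the corpus rows.
#' @export
includes_h_and_i <- function(corpus, tree, scheme = hit_scheme()) {
  cnt <- hit_counts(corpus, tree, scheme)
  cnt$n_h > 0 & cnt$n_i > 0
}

#' Per-article H-I-T code counts
#'
#' Every tree number of every major-topic descriptor is classified; under
#' the default per-code counting a descriptor with k category codes
#' contributes k (three terms can become six codes, and scoring runs on the
#' codes). `count_by = "descriptor"` instead counts each descriptor at most
#' once per category it touches, for sensitivity analysis.
#'
#' @param corpus A corpus tibble.
#' @param tree A [mesh_tree].
#' @param scheme A [hit_scheme].
#' @param count_by `"code"` (default) or `"descriptor"`.
#' @return A tibble `pmid`, `n_h`, `n_i`, `n_t` (zero counts for articles
#'   with no categorised codes), rows aligned with `corpus`.
#' @export
hit_counts <- function(corpus, tree, scheme = hit_scheme(),
                       count_by = c("code", "descriptor")) {
  count_by <- match.arg(count_by)
  stopifnot(all(c("H", "I", "T") %in% names(scheme)))
  codes <- major_topic_codes(corpus, tree)
  codes$category <- classify_code(codes$tree_number, scheme)
  codes <- codes[!is.na(codes$category), , drop = FALSE]
  if (count_by == "descriptor") {
    codes <- distinct(codes, .data$pmid, .data$ui, .data$category)
  }
  tallies <- codes |>
    count(.data$pmid, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (lab in c("H", "I", "T")) {
    if (!lab %in% names(tallies)) tallies[[lab]] <- 0L
  }
  out <- tibble(pmid = corpus$pmid) |>
    left_join(tallies, by = "pmid") |>
    mutate(across(c("H", "I", "T"), ~ ifelse(is.na(.x), 0L, as.integer(.x))))
  tibble(pmid = out$pmid, n_h = out$H, n_i = out$I, n_t = out$T)
}

#' Fractional H-I-T score from category counts
#'
#' Divides each category count by the total over the three categories, so
#' the fractions sum to one. Articles with no categorised codes are
#' unscorable: with `strict = TRUE` (the default for a single article) a
#' zero total is an error; in data-frame use the fractions are `NA` and the
#' caller drops such articles before triangle placement.
#'
#' @param counts A tibble with columns `n_h`, `n_i`, `n_t` (as from
#'   [hit_counts()]).
#' @param strict Error on a zero total instead of returning NA fractions.
#' @return `counts` with added columns `h`, `i`, `t`.
#' @export
hit_score <- function(counts, strict = FALSE) {
  stopifnot(all(c("n_h", "n_i", "n_t") %in% names(counts)))
  if (any(counts$n_h < 0 | counts$n_i < 0 | counts$n_t < 0)) {
    abort("H-I-T counts must be non-negative")
  }
  total <- counts$n_h + counts$n_i + counts$n_t
  if (strict && any(total == 0)) {
    abort("unscorable article: no codes in any H-I-T category")
  }
  total_or_na <- ifelse(total == 0, NA_real_, total)
  counts |>
    mutate(h = .data$n_h / total_or_na,
           i = .data$n_i / total_or_na,
           t = .data$n_t / total_or_na)
}

#' Score a corpus end-to-end
#'
#' Applies the exclusion filter, the H-and-I inclusion rule and the
#' fractional scoring in one pass. Both filters are per-record predicates,
#' so their order cannot change membership.
#'
#' @inheritParams hit_counts
#' @return A tibble `pmid`, `n_h`, `n_i`, `n_t`, `h`, `i`, `t`, `included`,
#'   `exclusion_reason`, carrying the vocabulary year as attribute
#'   `"mesh_year"`. `included` is `TRUE` for records that pass the exclusion
#'   filter and link H with I.
#' @export
score_corpus <- function(corpus, tree, scheme = hit_scheme(),
                         count_by = c("code", "descriptor")) {
  count_by <- match.arg(count_by)
  reason <- exclusion_reason(corpus)
  scored <- hit_score(hit_counts(corpus, tree, scheme, count_by = count_by))
  out <- scored |>
    mutate(included = is.na(reason) & .data$n_h > 0 & .data$n_i > 0,
           exclusion_reason = reason)
  n_excl <- sum(!is.na(reason))
  inform(paste0("scored ", nrow(out), " record(s): ", sum(out$included),
                " included, ", n_excl, " excluded by filters, ",
                sum(is.na(reason) & !out$included),
                " lacking the H-I link"),
         class = "hitmapper_tally")
  attr(out, "mesh_year") <- mesh_year(tree)
  out
}

#' Mean H-I-T scores of a corpus
#'
#' Arithmetic means of the per-article fractions over scorable articles;
#' because each article's fractions sum to one, so do the three means.
#'
#' @param scores A tibble with columns `h`, `i`, `t` (NA rows are
#'   unscorable and rejected).
#' @return A one-row tibble `mean_h`, `mean_i`, `mean_t`, `n_articles`.
#' @export
mean_scores <- function(scores) {
  stopifnot(all(c("h", "i", "t") %in% names(scores)))
  ok <- !is.na(scores$h)
  if (!any(ok)) abort("no scorable articles: cannot take mean scores")
  tibble(mean_h = mean(scores$h[ok]), mean_i = mean(scores$i[ok]),
         mean_t = mean(scores$t[ok]), n_articles = sum(ok))
}
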