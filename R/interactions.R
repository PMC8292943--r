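#' Rollup scheme for interaction profiles
#'
#' Deep topic codes are rolled up to the label of their ancestor at a fixed
#' depth before co-occurrence counting. Defaults follow the interaction
#' profile used for the H-I-T maps: depth 1 for Diseases (`C`) and
#' Techniques (`E`) — the first-level disease and technique classes — and
#' depth 2 for Information Science (`L`), which has a single first-level
#' node so the informative groups (Computing Methodologies, Informatics,
#' Communications Media) live one level deeper. The Health (`N01.400`),
#' Public Health (`N06.850`) and public-health-discipline (`H02.403.720`)
#' subtrees merge into a single "Population Health" label.
#'
#' @param depths Named integer vector of segment depths per category label.
#' @param merges Named character vector: tree-number prefix -> display
#'   label, applied before depth rollup.
#' @return A list of class `rollup_scheme`.
#' @export
rollup_scheme <- function(depths = c(H = 1L, I = 2L, T = 1L),
                          merges = c("N01.400" = "Population Health",
                                     "N06.850" = "Population Health",
                                     "H02.403.720" = "Population Health")) {
  if (any(depths < 1)) abort("rollup depths must be >= 1")
  structure(list(depths = depths, merges = merges), class = "rollup_scheme")
}

code_prefix <- function(code, depth) {
  segs <- strsplit(code, ".", fixed = TRUE)
  depth <- rep_len(depth, length(code))
  purrr::map2_chr(segs, depth,
                  function(s, d) paste(head(s, d), collapse = "."))
}

#' Roll a code up to its display label
#'
#' A code matching a merge prefix takes the merged display label;
#' otherwise the code is truncated to the configured depth for its
#' category and labelled with the name of the descriptor at that position
#' (codes shorter than the depth keep their maximal available depth; a
#' truncated code absent from the vocabulary falls back to the code string
#' itself with a warning).
#'
#' @param code Character vector of tree numbers that classify to a
#'   category.
#' @param tree A [mesh_tree].
#' @param scheme A [hit_scheme].
#' @param rollup A [rollup_scheme].
#' @return Character vector of display labels (NA for codes that classify
#'   to no category).
#' @export
rollup_code <- function(code, tree, scheme = hit_scheme(),
                        rollup = rollup_scheme()) {
  cat_lab <- classify_code(code, scheme)
  out <- rep(NA_character_, length(code))
  for (p in names(rollup$merges)) {
    hit <- under_any(code, p) & is.na(out)
    out[hit] <- rollup$merges[[p]]
  }
  todo <- is.na(out) & !is.na(cat_lab)
  if (any(todo)) {
    depth <- unname(rollup$depths[cat_lab[todo]])
    depth[is.na(depth)] <- 1L
    pref <- code_prefix(code[todo], depth)
    lut <- setNames(tree$name, tree$tree_number)
    lab <- unname(lut[pref])
    if (any(is.na(lab))) {
      warn(paste0("rollup prefix(es) absent from the vocabulary, using the ",
                  "code itself: ",
                  paste(head(unique(pref[is.na(lab)]), 5), collapse = ", ")))
      lab[is.na(lab)] <- pref[is.na(lab)]
    }
    out[todo] <- lab
  }
  out
}

#' Co-occurrence interaction matrix between two H-I-T axes
#'
#' For each (already filtered, included) article, every unordered pair of
#' distinct rolled-up labels across the two chosen categories among its
#' major-topic codes increments the corresponding cell once — pairs are
#' deduplicated within an article, so three cardiovascular codes meeting
#' one telemedicine code add 1, not 3. `count_by = "code"` counts each
#' code pair instead.
#'
#' @param corpus A corpus tibble of included articles.
#' @param tree A [mesh_tree].
#' @param scheme A [hit_scheme].
#' @param rollup A [rollup_scheme].
#' @param axis One of `"HxI"`, `"HxT"`, `"IxT"`.
#' @param count_by `"article"` (default, per-article dedup) or `"code"`.
#' @return A long tibble `row_label`, `col_label`, `n` of class
#'   `hit_interactions` (complete over observed label pairs, zero cells
#'   included), with attributes `axis` and `mesh_year`.
#' @export
cooccurrence_matrix <- function(corpus, tree, scheme = hit_scheme(),
                                rollup = rollup_scheme(),
                                axis = c("HxI", "HxT", "IxT"),
                                count_by = c("article", "code")) {
  axis <- match.arg(axis)
  count_by <- match.arg(count_by)
  cats <- strsplit(axis, "x", fixed = TRUE)[[1]]
  codes <- major_topic_codes(corpus, tree)
  codes$category <- classify_code(codes$tree_number, scheme)
  codes <- codes[!is.na(codes$category) & codes$category %in% cats, ,
                 drop = FALSE]
  codes$label <- rollup_code(codes$tree_number, tree, scheme, rollup)
  pairs <- purrr::map(split(codes, codes$pmid), function(d) {
    a <- d[d$category == cats[1], , drop = FALSE]
    b <- d[d$category == cats[2], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    g <- tidyr::expand_grid(row_label = a$label, col_label = b$label)
    if (count_by == "article") g <- distinct(g)
    g
  })
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    out <- tibble(row_label = character(), col_label = character(),
                  n = integer())
  } else {
    out <- pairs |>
      count(.data$row_label, .data$col_label) |>
      tidyr::complete(.data$row_label, .data$col_label,
                      fill = list(n = 0L)) |>
      arrange(.data$row_label, .data$col_label)
  }
  structure(out, class = c("hit_interactions", class(tibble())),
            axis = axis, mesh_year = mesh_year(tree))
}

#' Widen an interaction tibble to a labelled integer matrix
#'
#' @param x A [cooccurrence_matrix()] result.
#' @return An integer matrix, row/column names from the labels.
#' @export
interaction_matrix <- function(x) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "col_label",
                             values_from = "n", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$row_label
  storage.mode(m) <- "integer"
  m
}

#' Restrict a corpus to a topical subtree
#'
#' Keeps articles carrying at least one major-topic code under the root's
#' subtree — the construction behind AI or EHR sub-corpora ("Artificial
#' Intelligence and all terms beneath it").
#'
#' @param corpus A corpus tibble.
#' @param tree A [mesh_tree].
#' @param root Descriptor name, UI or tree number.
#' @return The corpus rows whose articles touch the subtree.
#' @export
subset_by_subtree <- function(corpus, tree, root) {
  sub <- mesh_descendants(tree, root)
  codes <- major_topic_codes(corpus, tree)
  keep <- unique(codes$pmid[codes$ui %in% unique(sub$ui)])
  corpus[corpus$pmid %in% keep, , drop = FALSE]
}

#' Sankey edge list from an interaction matrix
#'
#' One edge per cell with count at or above the threshold; weights equal
#' the cell counts, so the retained weight total is conserved.
#'
#' @param x A [cooccurrence_matrix()] result.
#' @param min_count Minimum count for an edge to be emitted (default 1).
#' @return A tibble `source`, `target`, `weight`.
#' @export
sankey_edges <- function(x, min_count = 1) {
  out <- as_tibble(x) |>
    filter(.data$n >= min_count) |>
    rename(source = "row_label", target = "col_label", weight = "n")
  out
}

#' Heatmap of an interaction matrix
#'
#' @param object A [cooccurrence_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hit_interactions
#' @export
autoplot.hit_interactions <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$col_label, y = .data$row_label,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "articles") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "axis"),
                                 " co-occurrence interactions")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
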