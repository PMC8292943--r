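#' H-I-T category scheme
#'
#' A category scheme maps labels to sets of tree-number prefixes. The
#' default reproduces the H-I-T model: health demand (H) covers the entire
#' Diseases branch `C` plus the Health `N01.400` and Public Health `N06.850`
#' subtrees — and, because "Public Health" also sits under `H02.403.720` as
#' a medical discipline (Epidemiology, Preventive Medicine and kin), that
#' branch too; informatics supply (I) is the Information Science branch `L`;
#' technological applications (T) is the Analytical, Diagnostic and
#' Therapeutic Techniques, and Equipment branch `E`.
#'
#' Prefix sets must be disjoint across categories (no prefix may lie under a
#' prefix of another category); an overlapping scheme fails to load rather
#' than silently picking a winner.
#'
#' @param categories Named list, label -> character vector of prefixes.
#' @param public_health_discipline Keep the `H02.403.720` branch in H
#'   (default `TRUE`). Ignored when `categories` is supplied explicitly.
#'
#' @return A named list of class `hit_scheme`.
#' @export
hit_scheme <- function(categories = NULL, public_health_discipline = TRUE) {
  if (is.null(categories)) {
    h <- c("C", "N01.400", "N06.850")
    if (public_health_discipline) h <- c(h, "H02.403.720")
    categories <- list(H = h, I = "L", T = "E")
  }
  if (is.null(names(categories)) || any(!nzchar(names(categories))) ||
      anyDuplicated(names(categories))) {
    abort("category labels must be unique and non-empty")
  }
  all_pref <- unlist(categories, use.names = FALSE)
  for (p in all_pref) {
    if (!grepl("^[A-Z]([0-9]+(\\.[0-9]+)*)?$", p)) {
      abort(paste0("invalid category prefix: ", p))
    }
  }
  # cross-category overlap (either direction of nesting) is a hard error
  lab_of <- rep(names(categories), lengths(categories))
  for (a in seq_along(all_pref)) {
    for (b in seq_along(all_pref)) {
      if (a == b || lab_of[a] == lab_of[b]) next
      pa <- all_pref[a]; pb <- all_pref[b]
      overlap <- if (grepl("^[A-Z]$", pb)) startsWith(pa, pb) else is_under(pa, pb)
      if (overlap) {
        abort(paste0("category prefixes overlap across labels: '", pa,
                     "' (", lab_of[a], ") lies under '", pb, "' (",
                     lab_of[b], ")"))
      }
    }
  }
  if (anyDuplicated(all_pref)) abort("a prefix is listed twice in the scheme")
  structure(categories, class = "hit_scheme")
}

#' @export
print.hit_scheme <- function(x, ...) {
  cat("<hit_scheme>\n")
  for (lab in names(x)) {
    cat("  ", lab, ": ", paste(x[[lab]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify tree-number codes into H-I-T categories
#'
#' Each code classifies to the (unique, by scheme disjointness) category one
#' of whose prefixes it lies under, or to `NA` when no category matches
#' (e.g. the Organisms branch `B`).
#'
#' @param code Character vector of tree numbers (NA passes through).
#' @param scheme A [hit_scheme].
#' @return Character vector of category labels, `NA` for uncategorised.
#' @export
classify_code <- function(code, scheme = hit_scheme()) {
  stopifnot(inherits(scheme, "hit_scheme"))
  out <- rep(NA_character_, length(code))
  for (lab in names(scheme)) {
    hit <- under_any(code, scheme[[lab]])
    out[hit & is.na(out)] <- lab
  }
  out
}

#' Classify a descriptor's codes as a category multiset
#'
#' A descriptor may occupy several branches; each of its tree numbers is
#' marked once, so the result is a multiset of labels — one entry per code
#' that classifies, nothing for codes classifying to none.
#'
#' @param tree_numbers Character vector of a descriptor's tree numbers.
#' @param scheme A [hit_scheme].
#' @return Character vector of labels (possibly with repeats), no NAs.
#' @export
classify_descriptor <- function(tree_numbers, scheme = hit_scheme()) {
  tree_numbers <- tree_numbers[!is.na(tree_numbers)]
  labs <- classify_code(tree_numbers, scheme)
  labs[!is.na(labs)]
}

#' Count vocabulary terms per category
#'
#' Counts the vocabulary content of each category under one of two
#' conventions: `"descriptors"` counts unique descriptors owning at least
#' one code in the category; `"tree_positions"` counts codes, so a
#' descriptor with two Diseases-branch codes contributes twice.
#'
#' @param tree A [mesh_tree].
#' @param scheme A [hit_scheme].
#' @param convention `"descriptors"` (default) or `"tree_positions"`.
#' @return A tibble with columns `category` and `n_terms` (one row per
#'   scheme label, zero counts included).
#' @export
count_category_terms <- function(tree, scheme = hit_scheme(),
                                 convention = c("descriptors", "tree_positions")) {
  convention <- match.arg(convention)
  rows <- tibble(ui = tree$ui,
                 category = classify_code(tree$tree_number, scheme))
  rows <- rows[!is.na(rows$category), , drop = FALSE]
  counts <- if (convention == "descriptors") {
    rows |> distinct(.data$ui, .data$category) |> count(.data$category)
  } else {
    rows |> count(.data$category)
  }
  tibble(category = names(scheme)) |>
    left_join(counts, by = "category") |>
    mutate(n_terms = ifelse(is.na(.data$n), 0L, .data$n)) |>
    select("category", "n_terms")
}
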