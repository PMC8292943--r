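#' MeSH vocabulary trees
#'
#' A `mesh_tree` is a tibble holding one row per (descriptor, tree number)
#' pair, with columns `ui` (descriptor unique identifier), `name` (preferred
#' term) and `tree_number` (dot-delimited hierarchical code, e.g.
#' `"C14.907.489"`). Descriptors that occupy several positions in the MeSH
#' hierarchy own several rows; descriptors without any tree number (some
#' publication-type records, for instance) are retained with `tree_number =
#' NA` but can never classify to a category. The vocabulary year travels with
#' the object as the `"mesh_year"` attribute and is stamped on downstream
#' outputs.
#'
#' @param x A data frame with columns `ui`, `name`, `tree_number`.
#' @param year Vocabulary version string, default `"2020"`.
#'
#' @return A tibble of class `mesh_tree`.
#' @export
mesh_tree <- function(x, year = "2020") {
  x <- as_tibble(x)
  required <- c("ui", "name", "tree_number")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("mesh_tree input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x[required]
  x$ui <- as.character(x$ui)
  x$name <- as.character(x$name)
  x$tree_number <- as.character(x$tree_number)
  if (any(is.na(x$name) | x$name == "")) {
    abort("every MeSH descriptor must have a non-empty name")
  }
  codes <- x$tree_number[!is.na(x$tree_number)]
  if (anyDuplicated(codes)) {
    dup <- unique(codes[duplicated(codes)])
    abort(paste0("duplicate tree number(s) in vocabulary: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  bad <- codes[!grepl("^[A-Z][0-9]*(\\.[0-9]+)*$", codes)]
  if (length(bad) > 0) {
    abort(paste0("malformed tree number(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  # one name per ui
  nm <- tapply(x$name, x$ui, function(v) length(unique(v)))
  if (any(nm > 1)) {
    abort(paste0("descriptor ui with conflicting names: ",
                 paste(head(names(nm)[nm > 1], 5), collapse = ", ")))
  }
  unclassifiable <- unique(x$ui[is.na(x$tree_number)])
  unclassifiable <- setdiff(unclassifiable, x$ui[!is.na(x$tree_number)])
  if (length(unclassifiable) > 0) {
    inform(paste0(length(unclassifiable),
                  " descriptor(s) without tree numbers load as unclassifiable"),
           class = "hitmapper_debug")
  }
  structure(x, class = c("mesh_tree", class(tibble())), mesh_year = year)
}

#' @export
print.mesh_tree <- function(x, ...) {
  cat("<mesh_tree> MeSH ", attr(x, "mesh_year"), ": ",
      length(unique(x$ui)), " descriptors, ",
      sum(!is.na(x$tree_number)), " tree positions\n", sep = "")
  NextMethod()
}

#' Vocabulary year of a MeSH tree
#' @param tree A `mesh_tree`.
#' @return The vocabulary version string.
#' @export
mesh_year <- function(tree) attr(tree, "mesh_year") %||% "unknown"

#' Load a MeSH descriptor XML file
#'
#' Reads the NLM `desc` XML format (e.g. `desc2020.xml`): every
#' `DescriptorRecord` becomes one descriptor; its `TreeNumberList` entries
#' become tree-number rows. Records without tree numbers are retained but
#' flagged unclassifiable.
#'
#' @param path Path to a MeSH descriptor XML file.
#' @inheritParams mesh_tree
#' @return A [mesh_tree] tibble.
#' @export
read_mesh_xml <- function(path, year = "2020") {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed MeSH XML: ", conditionMessage(e)))
  )
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  rows <- purrr::map(recs, function(rec) {
    ui <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorUI"))
    name <- xml2::xml_text(
      xml2::xml_find_first(rec, "./DescriptorName/String"))
    tn <- xml2::xml_text(
      xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
    if (length(tn) == 0) tn <- NA_character_
    tibble(ui = ui, name = name, tree_number = tn)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(ui = character(), name = character(),
                  tree_number = character())
  }
  mesh_tree(out, year = year)
}

#' Load a MeSH vocabulary from the tabular fixture dialect
#'
#' Tab-separated lines `ui<TAB>name<TAB>tree numbers joined by |`; an empty
#' third field means the descriptor has no tree numbers. Blank lines are
#' skipped with a warning. Lines starting with `#` are comments. Produces a
#' tree equivalent to [read_mesh_xml()] for the same content.
#'
#' @param path Path to a TSV vocabulary file.
#' @inheritParams mesh_tree
#' @return A [mesh_tree] tibble.
#' @export
read_mesh_table <- function(path, year = "2020") {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines)
  lines <- lines[keep]
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warn(paste0("skipping ", sum(blank), " blank line(s) in ", path))
    lines <- lines[!blank]
  }
  rows <- purrr::imap(lines, function(line, idx) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    n_tabs <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
    if (n_tabs != 2) {
      abort(paste0("line ", idx, ": expected 3 tab-separated columns ",
                   "(ui, name, tree numbers), got ", n_tabs + 1))
    }
    fields <- c(fields, rep("", 3 - length(fields)))
    tn <- strsplit(fields[3], "|", fixed = TRUE)[[1]]
    tn <- tn[nzchar(tn)]
    if (length(tn) == 0) tn <- NA_character_
    tibble(ui = fields[1], name = fields[2], tree_number = tn)
  })
  out <- bind_rows(rows)
  if (length(rows) == 0) {
    out <- tibble(ui = character(), name = character(),
                  tree_number = character())
  }
  mesh_tree(out, year = year)
}

#' Segment-wise tree-number prefix test
#'
#' `is_under(code, prefix)` is `TRUE` iff `code` equals `prefix` or extends
#' it at a dot boundary. Matching is segment-wise — `"C14.907"` is *not*
#' under `"C14.9"` — because tree numbers are positional paths, not flat
#' strings. A bare branch letter (`"C"`, `"L"`, ...) denotes the whole
#' branch and matches any code whose first segment carries that letter.
#'
#' @param code Character vector of tree numbers.
#' @param prefix A single tree number or branch letter.
#' @return Logical vector along `code`.
#' @export
is_under <- function(code, prefix) {
  stopifnot(length(prefix) == 1L)
  if (is.na(prefix) || !grepl("^[A-Z]([0-9]+(\\.[0-9]+)*)?$", prefix)) {
    abort(paste0("malformed tree-number prefix: ", prefix))
  }
  bad <- !is.na(code) & !grepl("^[A-Z][0-9]*(\\.[0-9]+)*$", code)
  if (any(bad)) {
    abort(paste0("malformed tree number(s): ",
                 paste(head(unique(code[bad]), 5), collapse = ", ")))
  }
  out <- rep(FALSE, length(code))
  ok <- !is.na(code)
  if (grepl("^[A-Z]$", prefix)) {
    out[ok] <- startsWith(code[ok], prefix)
  } else {
    out[ok] <- code[ok] == prefix | startsWith(code[ok], paste0(prefix, "."))
  }
  out
}

# Resolve a descriptor reference (name, ui or tree number) to its ui(s).
resolve_descriptor <- function(tree, ref) {
  stopifnot(length(ref) == 1L)
  hit <- tree$ui[!is.na(tree$tree_number) & tree$tree_number == ref]
  if (length(hit) == 0) hit <- unique(tree$ui[tree$ui == ref])
  if (length(hit) == 0) hit <- unique(tree$ui[tree$name == ref])
  if (length(hit) == 0) {
    near <- unique(tree$name[agrepl(ref, tree$name, max.distance = 0.2,
                                    ignore.case = TRUE)])
    msg <- paste0("cannot resolve '", ref, "' in the MeSH tree")
    if (length(near) > 0) {
      msg <- paste0(msg, "; near matches: ",
                    paste(head(near, 5), collapse = ", "))
    }
    abort(msg)
  }
  hit
}

#' Descriptors beneath a subtree root
#'
#' Returns every descriptor owning at least one tree number under any of the
#' root's tree numbers, the root itself included. `root` may be a descriptor
#' name, a descriptor UI, or a tree number.
#'
#' @param tree A [mesh_tree].
#' @param root Descriptor name, UI or tree number resolvable in `tree`.
#' @return A tibble with one row per (descriptor, tree number) of the
#'   matched descriptors.
#' @export
mesh_descendants <- function(tree, root) {
  ui <- resolve_descriptor(tree, root)
  if (!is.na(root) && root %in% tree$tree_number) {
    roots <- root
  } else {
    roots <- tree$tree_number[tree$ui %in% ui & !is.na(tree$tree_number)]
  }
  if (length(roots) == 0) {
    abort(paste0("'", root, "' resolves but owns no tree numbers"))
  }
  under <- Reduce(`|`, lapply(roots, function(r) is_under(tree$tree_number, r)))
  hit_ui <- unique(tree$ui[under])
  out <- tree[tree$ui %in% hit_ui, , drop = FALSE]
  as_tibble(out)
}

#' Write a MeSH tree in the tabular fixture dialect
#'
#' Inverse of [read_mesh_table()]: one line per descriptor, tree numbers
#' pipe-joined, empty third field for unclassifiable descriptors.
#'
#' @param tree A [mesh_tree].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_table <- function(tree, path) {
  per_ui <- split(tree$tree_number, factor(tree$ui, levels = unique(tree$ui)))
  names_per_ui <- tapply(tree$name, factor(tree$ui, levels = unique(tree$ui)),
                         function(v) v[1])
  lines <- vapply(names(per_ui), function(ui) {
    tn <- per_ui[[ui]]
    tn <- tn[!is.na(tn)]
    paste(ui, names_per_ui[[ui]], paste(tn, collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Codes lying beneath any of a set of subtree roots
#'
#' Vectorised membership helper: for each element of `code`, is it under at
#' least one of `roots`?
#'
#' @param code Character vector of tree numbers (NA allowed, never matches).
#' @param roots Character vector of tree-number prefixes.
#' @return Logical vector along `code`.
#' @export
under_any <- function(code, roots) {
  if (length(roots) == 0) return(rep(FALSE, length(code)))
  Reduce(`|`, lapply(roots, function(r) is_under(code, r)))
}
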