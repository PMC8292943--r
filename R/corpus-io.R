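#' Build a MeSH heading row
#'
#' A heading records one descriptor attached to a publication, the
#' descriptor-level major-topic flag (the asterisk PubMed renders on the
#' term), and any subheading qualifiers with their own major flags. A
#' heading counts as a *major topic* when the descriptor flag or any
#' qualifier flag is set, matching how PubMed stars MeSH/Subheading
#' combinations.
#'
#' @param descriptor_name Preferred term (non-empty).
#' @param descriptor_ui Optional descriptor UI.
#' @param major Descriptor-level major-topic flag.
#' @param qualifiers A data frame with columns `name` and `major`
#'   (zero rows for an unqualified heading).
#' @return A one-row tibble usable inside a corpus `headings` list-column.
#' @export
mesh_heading <- function(descriptor_name, descriptor_ui = NA_character_,
                         major = FALSE,
                         qualifiers = tibble(name = character(),
                                             major = logical())) {
  stopifnot(is.character(descriptor_name), nzchar(descriptor_name))
  qualifiers <- as_tibble(qualifiers)
  qualifiers <- if (nrow(qualifiers) == 0) {
    tibble(name = character(), major = logical())
  } else {
    qualifiers[, c("name", "major")]
  }
  tibble(descriptor_name = descriptor_name,
         descriptor_ui = as.character(descriptor_ui),
         major = isTRUE(major),
         qualifiers = list(qualifiers))
}

#' Build a one-article corpus row
#'
#' @param pmid Publication identifier (unique within a corpus).
#' @param title Article title.
#' @param year Publication year (1900-2100).
#' @param language Language code, e.g. `"eng"`.
#' @param country Affiliation country or `NA` when unresolvable.
#' @param publication_types Character vector of publication types.
#' @param headings A headings tibble, usually `dplyr::bind_rows()` of
#'   [mesh_heading()] calls.
#' @return A one-row corpus tibble.
#' @export
article_record <- function(pmid, title = "", year = NA_integer_,
                           language = NA_character_, country = NA_character_,
                           publication_types = character(),
                           headings = mesh_heading("placeholder")[0, ]) {
  tibble(pmid = as.character(pmid), title = as.character(title),
         year = as.integer(year), language = as.character(language),
         country = as.character(country),
         publication_types = list(as.character(publication_types)),
         headings = list(as_tibble(headings)))
}

corpus_columns <- c("pmid", "title", "year", "language", "country",
                    "publication_types", "headings")

validate_corpus <- function(corpus) {
  missing_cols <- setdiff(corpus_columns, names(corpus))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(corpus$pmid)) {
    abort("pmid must be unique within a corpus")
  }
  yr <- corpus$year[!is.na(corpus$year)]
  if (any(yr < 1900 | yr > 2100)) abort("implausible publication year")
  invisible(corpus)
}

#' Read a MEDLINE/PubMed citation XML file
#'
#' One record per `PubmedArticle`/`MedlineCitation`; MeSH headings carry
#' both the descriptor-level and qualifier-level `MajorTopicYN` flags;
#' publication types and language are preserved verbatim. Citations without
#' a PMID are skipped with a warning. The affiliation country of the first
#' author is parsed against a gazetteer of country names; records without a
#' resolvable country keep `country = NA` and are retained.
#'
#' @param path Path to a PubMed/MEDLINE citation XML file.
#' @param gazetteer Named character vector mapping a matchable string to a
#'   canonical country name; see [default_gazetteer()].
#' @return A corpus tibble (one row per citation).
#' @export
read_pubmed_xml <- function(path, gazetteer = default_gazetteer()) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed PubMed XML: ",
                                     conditionMessage(e)))
  )
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  rows <- purrr::imap(cits, function(cit, idx) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warn(paste0("citation ", idx, " has no PMID; skipped"))
      return(NULL)
    }
    art <- xml2::xml_find_first(cit, "./Article")
    title <- xml2::xml_text(xml2::xml_find_first(art, "./ArticleTitle"))
    year <- xml2::xml_text(xml2::xml_find_first(
      art, "./Journal/JournalIssue/PubDate/Year"))
    if (is.na(year)) {
      md <- xml2::xml_text(xml2::xml_find_first(
        art, "./Journal/JournalIssue/PubDate/MedlineDate"))
      year <- if (!is.na(md)) stringr::str_extract(md, "[0-9]{4}") else NA
    }
    language <- xml2::xml_text(xml2::xml_find_first(art, "./Language"))
    ptypes <- xml2::xml_text(xml2::xml_find_all(
      art, "./PublicationTypeList/PublicationType"))
    affil <- xml2::xml_text(xml2::xml_find_first(
      art, "./AuthorList/Author[1]/AffiliationInfo/Affiliation"))
    country <- parse_country(affil, gazetteer)
    heads <- xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading")
    headings <- purrr::map(heads, function(h) {
      d <- xml2::xml_find_first(h, "./DescriptorName")
      quals <- xml2::xml_find_all(h, "./QualifierName")
      mesh_heading(
        descriptor_name = xml2::xml_text(d),
        descriptor_ui = xml2::xml_attr(d, "UI"),
        major = identical(xml2::xml_attr(d, "MajorTopicYN"), "Y"),
        qualifiers = tibble(
          name = xml2::xml_text(quals),
          major = xml2::xml_attr(quals, "MajorTopicYN") == "Y"))
    })
    article_record(pmid = pmid,
                   title = ifelse(is.na(title), "", title),
                   year = suppressWarnings(as.integer(year)),
                   language = language, country = country,
                   publication_types = ptypes,
                   headings = bind_rows(headings))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- article_record("x")[0, ]
  validate_corpus(out)
}

#' Default affiliation-country gazetteer
#'
#' Maps strings searched for in affiliation text (case-insensitively, last
#' match wins — affiliations usually end with the country) to canonical
#' country names. Extend or replace it to change attribution.
#'
#' @return Named character vector.
#' @export
default_gazetteer <- function() {
  c("United States" = "United States", "USA" = "United States",
    "U.S.A" = "United States",
    "United Kingdom" = "United Kingdom", "UK" = "United Kingdom",
    "England" = "United Kingdom", "Scotland" = "United Kingdom",
    "China" = "China", "Taiwan" = "Taiwan",
    "Germany" = "Germany", "Canada" = "Canada", "Australia" = "Australia",
    "Italy" = "Italy", "Japan" = "Japan", "France" = "France",
    "Netherlands" = "The Netherlands", "Spain" = "Spain",
    "South Korea" = "South Korea", "Korea" = "South Korea",
    "India" = "India", "Brazil" = "Brazil", "Sweden" = "Sweden",
    "Switzerland" = "Switzerland", "Denmark" = "Denmark")
}

parse_country <- function(affiliation, gazetteer = default_gazetteer()) {
  if (is.na(affiliation) || !nzchar(affiliation)) return(NA_character_)
  pos <- vapply(names(gazetteer), function(key) {
    m <- gregexpr(key, affiliation, ignore.case = TRUE, fixed = FALSE)[[1]]
    if (m[1] == -1) -1L else max(m)
  }, integer(1))
  if (all(pos < 0)) return(NA_character_)
  unname(gazetteer[which.max(pos)])
}

# canonical JSON for one corpus row: fixed field order, NA -> null
record_to_json <- function(row) {
  h <- row$headings[[1]]
  headings <- purrr::pmap(h, function(descriptor_name, descriptor_ui, major,
                                      qualifiers) {
    list(descriptor_name = descriptor_name,
         descriptor_ui = descriptor_ui,
         major = major,
         qualifiers = purrr::pmap(qualifiers, function(name, major) {
           list(name = name, major = major)
         }))
  })
  jsonlite::toJSON(
    list(pmid = row$pmid, title = row$title, year = row$year,
         language = row$language, country = row$country,
         publication_types = as.list(row$publication_types[[1]]),
         headings = headings),
    auto_unbox = TRUE, null = "null", na = "null", digits = NA)
}

#' Write a corpus as line-delimited JSON
#'
#' One JSON object per line with the corpus record schema (`pmid`, `title`,
#' `year`, `language`, `country`, `publication_types`, `headings`, each
#' heading with `descriptor_name`, `descriptor_ui`, `major`, `qualifiers`).
#' Round-trips bit-exactly with [read_corpus_jsonl()].
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  validate_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)),
                  function(i) as.character(record_to_json(corpus[i, ])),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from line-delimited JSON
#'
#' @param path Path to a JSONL corpus written by [write_corpus_jsonl()] (or
#'   any file following the same schema).
#' @return A corpus tibble.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(line, idx) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) abort(paste0("line ", idx, ": invalid JSON: ",
                                       conditionMessage(e)))
    )
    for (f in corpus_columns) {
      if (!f %in% names(rec)) {
        abort(paste0("line ", idx, ": missing field '", f, "'"))
      }
    }
    headings <- bind_rows(purrr::map(rec$headings, function(h) {
      quals <- purrr::map(h$qualifiers, function(q) {
        tibble(name = q$name, major = isTRUE(q$major))
      })
      mesh_heading(descriptor_name = h$descriptor_name,
                   descriptor_ui = h$descriptor_ui %||% NA_character_,
                   major = isTRUE(h$major),
                   qualifiers = bind_rows(quals))
    }))
    if (nrow(headings) == 0) headings <- mesh_heading("placeholder")[0, ]
    article_record(pmid = rec$pmid, title = rec$title %||% "",
                   year = rec$year %||% NA_integer_,
                   language = rec$language %||% NA_character_,
                   country = rec$country %||% NA_character_,
                   publication_types = unlist(rec$publication_types) %||%
                     character(),
                   headings = headings)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- article_record("x")[0, ]
  validate_corpus(out)
}

#' Major topics of each article
#'
#' A heading is a major topic when its descriptor flag or any of its
#' qualifier flags is set. Names are deduplicated per article with input
#' order preserved (a descriptor starred through two qualifiers appears
#' once).
#'
#' @param corpus A corpus tibble (possibly a single row).
#' @return A tibble with columns `pmid` and `descriptor_name`, one row per
#'   major topic per article.
#' @export
major_topics <- function(corpus) {
  validate_corpus(corpus)
  rows <- purrr::map2(corpus$pmid, corpus$headings, function(pmid, h) {
    if (nrow(h) == 0) return(NULL)
    is_major <- h$major |
      vapply(h$qualifiers, function(q) any(q$major), logical(1))
    nm <- h$descriptor_name[is_major]
    nm <- nm[!duplicated(nm)]
    if (length(nm) == 0) return(NULL)
    tibble(pmid = pmid, descriptor_name = nm)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(pmid = character(), descriptor_name = character())
  }
  out
}
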