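#' Read an ICD-10 to MeSH correspondence table
#'
#' Tab-separated columns `disease`, `icd10`, `matched`, `excluded`;
#' `matched` and `excluded` hold semicolon-separated tree numbers (empty or
#' `NA` for no exclusions). Each row ties one disease (with its ICD-10 code
#' range, e.g. `I10-I15`) to the MeSH subtrees whose publications count
#' towards it, minus excluded subtrees — e.g. Hypertension `C14.907.489`
#' matched for hypertensive heart disease while `C14.907.489.480`
#' (pregnancy-induced hypertension) is carved out.
#'
#' @param path Path to the TSV table.
#' @return A tibble `disease`, `icd10`, `matched`, `excluded` with
#'   list-columns of tree numbers.
#' @export
read_icd_mesh_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  required <- c("disease", "icd10", "matched", "excluded")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("ICD-MeSH table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  split_codes <- function(v) {
    purrr::map(v, function(x) {
      if (is.na(x) || x %in% c("", "N/A", "NA")) return(character())
      trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(disease = df$disease, icd10 = df$icd10,
                matched = split_codes(df$matched),
                excluded = split_codes(df$excluded))
  if (any(lengths(out$matched) == 0)) {
    abort("every disease entry needs at least one matched tree number")
  }
  out
}

#' Map articles to diseases through MeSH subtrees
#'
#' An article maps to a disease when at least one of its major-topic codes
#' lies under one of the disease's matched tree numbers *and* that code
#' lies under none of the excluded ones — exclusion always wins. Matching
#' covers whole subtrees, so an article tagged "Diabetic Nephropathies"
#' reaches a "Kidney Diseases" entry without carrying the parent term. An
#' article may map to several diseases.
#'
#' @param corpus A corpus tibble (already filtered to included articles).
#' @param table An ICD-MeSH tibble from [read_icd_mesh_table()].
#' @param tree A [mesh_tree].
#' @return A tibble `pmid`, `disease`, one row per assignment.
#' @export
assign_diseases <- function(corpus, table, tree) {
  codes <- major_topic_codes(corpus, tree)
  rows <- purrr::pmap(table, function(disease, icd10, matched, excluded) {
    ok <- under_any(codes$tree_number, matched) &
      !under_any(codes$tree_number, excluded)
    pm <- unique(codes$pmid[ok])
    if (length(pm) == 0) return(NULL)
    tibble(pmid = pm, disease = disease)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(pmid = character(), disease = character())
  out
}

#' Publication counts per disease
#'
#' Counts each article once per disease it maps to; diseases attracting no
#' article keep a zero count.
#'
#' @inheritParams assign_diseases
#' @return A tibble `disease`, `n_publications` (one row per table entry).
#' @export
publications_per_disease <- function(corpus, table, tree) {
  asg <- assign_diseases(corpus, table, tree)
  counts <- asg |> distinct(.data$pmid, .data$disease) |>
    count(.data$disease, name = "n_publications")
  tibble(disease = table$disease) |>
    left_join(counts, by = "disease") |>
    mutate(n_publications = ifelse(is.na(.data$n_publications), 0L,
                                   as.integer(.data$n_publications)))
}

#' Through-origin regression of research effort on disease burden
#'
#' Fits publications ~ DALYs with zero intercept: the slope is
#' \eqn{\sum xy / \sum x^2}. By default the fit quality uses the uncentered
#' total sum of squares, \eqn{R^2 = 1 - \sum(y-\hat y)^2/\sum y^2} — the
#' standard convention for zero-intercept fits (and what an R no-intercept
#' `lm` summary reports); `centered = TRUE` switches to the centered
#' convention for comparison.
#'
#' @param dalys Numeric vector of DALYs (not all zero).
#' @param publications Numeric vector of non-negative publication counts,
#'   same length as `dalys` (length >= 2).
#' @param centered Use the centered total sum of squares for R^2.
#' @return An object of class `hit_origin_fit` with elements `slope`,
#'   `r_squared`, `data`, `centered` and the underlying `lm` fit.
#' @export
fit_through_origin <- function(dalys, publications, centered = FALSE) {
  if (length(dalys) != length(publications) || length(dalys) < 2) {
    abort("dalys and publications must be equal-length vectors, length >= 2")
  }
  if (any(is.na(dalys)) || any(is.na(publications))) {
    abort("missing values are not allowed in the regression inputs")
  }
  if (any(dalys < 0)) abort("DALYs must be non-negative")
  if (any(publications < 0)) {
    abort("publication counts must be non-negative")
  }
  if (all(dalys == 0)) abort("all-zero DALYs: slope is undefined")
  data <- tibble(dalys = as.numeric(dalys),
                 publications = as.numeric(publications))
  fit <- stats::lm(publications ~ 0 + dalys, data = data)
  tss <- if (centered) {
    sum((data$publications - mean(data$publications))^2)
  } else {
    sum(data$publications^2)
  }
  r2 <- 1 - sum(stats::resid(fit)^2) / tss
  structure(list(slope = unname(coef(fit)[["dalys"]]), r_squared = r2,
                 data = data, centered = centered, lm = fit),
            class = "hit_origin_fit")
}

#' @export
print.hit_origin_fit <- function(x, ...) {
  cat("<hit_origin_fit> y = ", format(x$slope, digits = 4), " x,  R^2 = ",
      format(x$r_squared, digits = 4),
      if (x$centered) " (centered)" else " (uncentered)", "\n", sep = "")
  invisible(x)
}

#' @method tidy hit_origin_fit
#' @export
tidy.hit_origin_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = "dalys", estimate = x$slope,
         std.error = s[1, "Std. Error"], statistic = s[1, "t value"],
         p.value = s[1, "Pr(>|t|)"])
}

#' @method glance hit_origin_fit
#' @export
glance.hit_origin_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         n = nrow(x$data), centered = x$centered)
}

#' Burden-versus-effort scatter with the fitted line
#'
#' @param object A [fit_through_origin()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hit_origin_fit
#' @export
autoplot.hit_origin_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dalys, y = .data$publications)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "DALYs", y = "informatics publications",
                  subtitle = sprintf("y = %.4gx,  R² = %.4g",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}
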