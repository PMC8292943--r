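#' Default ternary layout
#'
#' Vertex placement for the H-I-T triangle: H at the lower-left, I at the
#' lower-right (so the H-I edge — the T-free edge — is the base) and T at
#' the apex of an equilateral triangle of unit side.
#'
#' @return A 3x2 numeric matrix with rows `H`, `I`, `T`.
#' @export
ternary_layout <- function() {
  matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2, byrow = TRUE,
         dimnames = list(c("H", "I", "T"), c("x", "y")))
}

check_simplex <- function(h, i, t, tol = 1e-9) {
  bad <- is.na(h) | is.na(i) | is.na(t) |
    h < -tol | i < -tol | t < -tol | abs(h + i + t - 1) > tol
  if (any(bad)) {
    abort(paste0(sum(bad), " point(s) are not normalised barycentric ",
                 "coordinates (h+i+t must be 1, each in [0,1])"))
  }
}

#' Barycentric to Cartesian coordinates
#'
#' Affine interpolation of the three vertex positions: a vertex score maps
#' to that vertex, the centroid to the mean of the vertices, the 50/50 H-I
#' score to the midpoint of the base edge.
#'
#' @param scores A data frame with columns `h`, `i`, `t` summing to one per
#'   row (e.g. from [hit_score()] after dropping unscorable rows).
#' @param layout A 3x2 vertex matrix as from [ternary_layout()].
#' @return `scores` with added columns `x`, `y`.
#' @export
ternary_xy <- function(scores, layout = ternary_layout()) {
  stopifnot(all(c("h", "i", "t") %in% names(scores)))
  layout <- as.matrix(layout)
  stopifnot(identical(dim(layout), c(3L, 2L)))
  area2 <- (layout[2, 1] - layout[1, 1]) * (layout[3, 2] - layout[1, 2]) -
    (layout[3, 1] - layout[1, 1]) * (layout[2, 2] - layout[1, 2])
  if (abs(area2) < 1e-12) abort("degenerate layout: vertices are collinear")
  check_simplex(scores$h, scores$i, scores$t)
  b <- cbind(scores$h, scores$i, scores$t)
  xy <- b %*% layout
  scores |> mutate(x = xy[, 1], y = xy[, 2])
}

# floor of v with near-integer snapping: values within tol of an integer
# are treated as exactly that integer.
snap_floor <- function(v, tol = 1e-9) {
  r <- round(v)
  ifelse(abs(v - r) < tol, r, floor(v))
}

#' Assign points to tribin cells
#'
#' The simplex is cut into N equal parts in the three coordinate
#' directions, yielding N^2 congruent sub-triangles (tribins): upward cells
#' whose coordinate floors sum to N-1 and downward cells summing to N-2.
#' Cells are indexed by `row` (1 = the strip along the T-free H-I edge, N =
#' the strip at the T vertex), `position` (left-to-right within the row,
#' from the H side to the I side; odd positions are upward cells) and
#' `orientation` (`"up"`/`"down"`).
#'
#' Fractional scores with small denominators often land exactly on lattice
#' lines; such values are snapped before flooring, and a point falling on a
#' lattice *vertex* (all three coordinates on lines) is resolved by nudging
#' its T coordinate down first, then I, then H — a deterministic rule that
#' always yields an upward cell containing the point. Triangle vertices
#' belong to their corner cells.
#'
#' @param scores A data frame with columns `h`, `i`, `t`.
#' @param n Subdivision count per edge (n >= 1).
#' @return `scores` with added columns `row`, `position`, `orientation`.
#' @export
tribin_index <- function(scores, n) {
  stopifnot(all(c("h", "i", "t") %in% names(scores)),
            length(n) == 1L, n >= 1, n == as.integer(n))
  check_simplex(scores$h, scores$i, scores$t)
  fh <- snap_floor(scores$h * n)
  fi <- snap_floor(scores$i * n)
  ft <- snap_floor(scores$t * n)
  s <- fh + fi + ft
  # lattice-vertex points: all three coordinates exact, floors sum to n.
  # Nudge T first, then I, then H (only a coordinate with a positive floor
  # can move down); at least one floor is positive since they sum to n >= 1.
  at_vertex <- s == n
  take_t <- at_vertex & ft >= 1
  take_i <- at_vertex & !take_t & fi >= 1
  take_h <- at_vertex & !take_t & !take_i
  ft <- ft - as.integer(take_t)
  fi <- fi - as.integer(take_i)
  fh <- fh - as.integer(take_h)
  s <- fh + fi + ft
  if (!all(s %in% c(n - 1, n - 2))) {
    abort("internal error: tribin floors out of range") # nocov
  }
  up <- s == n - 1
  scores |>
    mutate(row = as.integer(ft + 1),
           position = as.integer(ifelse(up, 2 * fi + 1, 2 * fi + 2)),
           orientation = ifelse(up, "up", "down"))
}

#' All tribin cells of an N-subdivision
#'
#' @param n Subdivision count per edge.
#' @return A tibble `row`, `position`, `orientation` with exactly `n^2`
#'   rows.
#' @export
tribin_cells <- function(n) {
  rows <- purrr::map(seq_len(n), function(r) {
    n_pos <- 2 * (n - r) + 1
    tibble(row = r, position = seq_len(n_pos),
           orientation = ifelse(seq_len(n_pos) %% 2 == 1, "up", "down"))
  })
  bind_rows(rows) |> mutate(row = as.integer(.data$row))
}

#' Barycentric vertices of one tribin cell
#'
#' @param row,position Cell index as produced by [tribin_index()].
#' @param n Subdivision count.
#' @return A 3x3 matrix; rows are the cell's vertices, columns `h`, `i`,
#'   `t`.
#' @export
tribin_vertices <- function(row, position, n) {
  c_idx <- row - 1
  up <- position %% 2 == 1
  b <- if (up) (position - 1) / 2 else position / 2 - 1
  if (up) {
    a <- n - 1 - c_idx - b
    v <- rbind(c(a + 1, b, c_idx), c(a, b + 1, c_idx), c(a, b, c_idx + 1))
  } else {
    a <- n - 2 - c_idx - b
    v <- rbind(c(a + 1, b + 1, c_idx), c(a + 1, b, c_idx + 1),
               c(a, b + 1, c_idx + 1))
  }
  colnames(v) <- c("h", "i", "t")
  v / n
}

#' Bin a corpus of scores into a tribin grid
#'
#' Counts points per cell over the full N^2-cell grid (zero-count cells
#' included), conserving the number of binned points. Unscorable articles
#' (NA fractions) must be dropped by the caller beforehand.
#'
#' @param scores A data frame with columns `h`, `i`, `t`.
#' @param n Subdivision count per edge (default 10).
#' @param mesh_year Vocabulary version string stamped on the grid.
#' @return A tibble `row`, `position`, `orientation`, `count` of class
#'   `tribin_grid`, with attributes `n`, `n_points` and `mesh_year`.
#' @export
tribin_grid <- function(scores, n = 10, mesh_year = NULL) {
  idx <- tribin_index(scores, n)
  counts <- idx |> count(.data$row, .data$position, name = "count")
  out <- tribin_cells(n) |>
    left_join(counts, by = c("row", "position")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count)))
  structure(out, class = c("tribin_grid", class(tibble())),
            n = as.integer(n), n_points = nrow(idx),
            mesh_year = mesh_year %||% attr(scores, "mesh_year"))
}

#' @export
print.tribin_grid <- function(x, ...) {
  cat("<tribin_grid> n = ", attr(x, "n"), ", ", attr(x, "n_points"),
      " points in ", nrow(x), " cells\n", sep = "")
  NextMethod()
}

#' Plot a tribin grid
#'
#' Draws the subdivided H-I-T triangle with cells shaded by count, the
#' display the tribin binning exists for: each small triangle is coloured
#' by how many articles fall in it.
#'
#' @param object A [tribin_grid()].
#' @param layout Vertex placement, see [ternary_layout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tribin_grid
#' @export
autoplot.tribin_grid <- function(object, layout = ternary_layout(), ...) {
  n <- attr(object, "n")
  polys <- purrr::pmap(
    list(object$row, object$position, object$count),
    function(row, position, count) {
      v <- tribin_vertices(row, position, n) %*% as.matrix(layout)
      tibble(x = v[, 1], y = v[, 2],
             cell = paste(row, position, sep = "-"), count = count)
    }) |> bind_rows()
  lab <- tibble(x = layout[, 1] + c(-0.04, 0.04, 0),
                y = layout[, 2] + c(-0.03, -0.03, 0.04),
                text = rownames(layout) %||% c("H", "I", "T"))
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$cell,
                                      fill = .data$count)) +
    ggplot2::geom_polygon(colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$text),
                       inherit.aes = FALSE) +
    ggplot2::scale_fill_viridis_c(name = "articles") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Write a tribin grid as TSV
#'
#' Columns `row`, `position`, `orientation`, `count`; a header comment
#' carries the subdivision and vocabulary version so grids serialise
#' stably.
#'
#' @param grid A [tribin_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tribin_tsv <- function(grid, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# tribin grid: n=", attr(grid, "n"),
                    " points=", attr(grid, "n_points"),
                    " mesh_year=", attr(grid, "mesh_year") %||% "unknown"),
             con)
  utils::write.table(as.data.frame(grid), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
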