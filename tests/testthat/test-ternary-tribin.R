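test_that("barycentric placement hits vertices, edge midpoints and centroid", {
  pts <- tibble::tibble(h = c(1, 0, 0, 0.5, 1 / 3),
                        i = c(0, 1, 0, 0.5, 1 / 3),
                        t = c(0, 0, 1, 0, 1 / 3))
  xy <- ternary_xy(pts)
  layout <- ternary_layout()
  expect_equal(unlist(xy[1, c("x", "y")]), layout["H", ],
               ignore_attr = TRUE)
  expect_equal(unlist(xy[2, c("x", "y")]), layout["I", ],
               ignore_attr = TRUE)
  expect_equal(unlist(xy[3, c("x", "y")]), layout["T", ],
               ignore_attr = TRUE)
  expect_equal(unlist(xy[4, c("x", "y")]), colMeans(layout[1:2, ]),
               ignore_attr = TRUE)
  expect_equal(unlist(xy[5, c("x", "y")]), colMeans(layout),
               ignore_attr = TRUE)
})

test_that("cartesian projection inverts back to barycentric coordinates", {
  layout <- ternary_layout()
  withr::with_seed(5, {
    pts <- as.data.frame(runif_simplex(50))
    names(pts) <- c("h", "i", "t")
    xy <- ternary_xy(pts, layout)
    # invert the affine map: [x y 1] = b %*% [layout | 1]
    m <- cbind(layout, 1)
    back <- as.matrix(cbind(xy$x, xy$y, 1)) %*% solve(m)
    expect_equal(back[, 1], pts$h, tolerance = 1e-10)
    expect_equal(back[, 2], pts$i, tolerance = 1e-10)
  })
  bad <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_error(ternary_xy(tibble::tibble(h = 1, i = 0, t = 0), bad),
               "collinear")
  expect_error(ternary_xy(tibble::tibble(h = 0.7, i = 0.7, t = -0.4)),
               "normalised")
})

test_that("special points land in their documented cells", {
  # any point, n = 1: the single cell
  one <- tribin_index(tibble::tibble(h = 0.2, i = 0.5, t = 0.3), 1)
  expect_equal(one$row, 1L)
  expect_equal(one$position, 1L)
  expect_equal(one$orientation, "up")

  # H vertex, n = 4: apex corner cell on the base row, H side
  hv <- tribin_index(tibble::tibble(h = 1, i = 0, t = 0), 4)
  expect_equal(unlist(hv[, c("row", "position")]),
               c(row = 1L, position = 1L))
  # T vertex: top row
  tv <- tribin_index(tibble::tibble(h = 0, i = 0, t = 1), 4)
  expect_equal(tv$row, 4L)

  # centroid, n = 3: the central cell of the base row, and the geometric
  # containment oracle agrees the point lies in the assigned cell
  ce <- tribin_index(tibble::tibble(h = 1 / 3, i = 1 / 3, t = 1 / 3), 3)
  expect_equal(unlist(ce[, c("row", "position")]),
               c(row = 1L, position = 3L))
  containing <- oracle_containing_cells(1 / 3, 1 / 3, 1 / 3, 3)
  expect_true(any(containing$row == ce$row &
                    containing$position == ce$position))
})

test_that("assigned cells always contain their points (oracle agreement)", {
  withr::with_seed(17, {
    pts <- runif_simplex(250)
    # add rational points that sit exactly on lattice lines and vertices
    exact <- rbind(c(1 / 2, 1 / 2, 0), c(1 / 3, 1 / 3, 1 / 3),
                   c(0.4, 0.4, 0.2), c(0.25, 0.5, 0.25),
                   c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(0.2, 0.4, 0.4), c(0.6, 0.2, 0.2))
    pts <- rbind(pts, exact)
    df <- tibble::tibble(h = pts[, 1], i = pts[, 2], t = pts[, 3])
    for (n in c(2, 3, 5, 8)) {
      idx <- tribin_index(df, n)
      solvers <- oracle_cell_solvers(n)
      for (k in seq_len(nrow(df))) {
        containing <- oracle_containing_cells(df$h[k], df$i[k], df$t[k], n,
                                              solvers)
        expect_true(
          any(containing$row == idx$row[k] &
                containing$position == idx$position[k]),
          info = sprintf("n=%d point=(%.6f,%.6f,%.6f) cell=(%d,%d)",
                         n, df$h[k], df$i[k], df$t[k], idx$row[k],
                         idx$position[k]))
      }
    }
  })
})

test_that("grids conserve counts over exactly n^2 cells", {
  withr::with_seed(23, {
    pts <- runif_simplex(400)
    df <- tibble::tibble(h = pts[, 1], i = pts[, 2], t = pts[, 3])
    for (n in 1:12) {
      grid <- tribin_grid(df, n)
      expect_equal(nrow(grid), n^2)
      expect_equal(sum(grid$count), nrow(df))
      expect_true(all(grid$orientation %in% c("up", "down")))
      expect_equal(sum(grid$orientation == "down"), n * (n - 1) / 2)
    }
  })
  # n = 5 reports 25 cells including empty ones
  g5 <- tribin_grid(tibble::tibble(h = 1, i = 0, t = 0), 5)
  expect_equal(nrow(g5), 25)
  expect_equal(sum(g5$count == 0), 24)
})

test_that("repeated centroids pile into a single cell", {
  df <- tibble::tibble(h = rep(1 / 3, 3), i = rep(1 / 3, 3),
                       t = rep(1 / 3, 3))
  grid <- tribin_grid(df, 3)
  expect_equal(sum(grid$count), 3)
  expect_equal(max(grid$count), 3)
  expect_equal(sum(grid$count > 0), 1)
})

test_that("tribins have equal measure under uniform sampling", {
  withr::with_seed(29, {
    pts <- runif_simplex(10000)
    grid <- tribin_grid(tibble::tibble(h = pts[, 1], i = pts[, 2],
                                       t = pts[, 3]), 10)
    expect_equal(sum(grid$count), 10000)
    # each congruent cell expects 100 points; allow 5 sd of binomial noise
    sd <- sqrt(10000 * (1 / 100) * (99 / 100))
    expect_true(all(abs(grid$count - 100) <= 5 * sd))
    chi <- suppressWarnings(stats::chisq.test(grid$count))
    expect_gt(chi$p.value, 0.001)
  })
})

test_that("grid serialisation and plotting adapters work", {
  withr::with_seed(31, {
    pts <- runif_simplex(50)
    grid <- tribin_grid(tibble::tibble(h = pts[, 1], i = pts[, 2],
                                       t = pts[, 3]), 4,
                        mesh_year = "synthetic")
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tribin_tsv(grid, path)
  lines <- readLines(path)
  expect_match(lines[1], "n=4")
  expect_match(lines[1], "mesh_year=synthetic")
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(back), 16)
  expect_equal(sum(back$count), 50)
  p <- ggplot2::autoplot(grid)
  expect_s3_class(p, "ggplot")
})
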