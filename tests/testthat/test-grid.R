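test_that("grid cells have equal area derived from the edge length", {
  g <- build_grid(10, 10, 24.125)
  expect_equal(g$cell_area_km2, 24.125^2, tolerance = 1e-9)
  expect_equal(round(g$cell_area_km2, 2), 582.02)
  expect_equal(build_grid(1, 1, 1.0)$cell_area_km2, 1.0)
  g2 <- build_grid(3, 4, 2.0)
  expect_length(g2$cell_ids, 12L)
  expect_equal(g2$cell_area_km2, 4.0)
  expect_false(anyDuplicated(g2$cell_ids) > 0)
})

test_that("invalid grid dimensions are rejected", {
  expect_error(build_grid(0, 5), "positive")
  expect_error(build_grid(3, 3, -1), "positive")
  expect_error(build_grid(2.5, 3), "positive integers")
})

test_that("cell_rowcol inverts row-major numbering", {
  g <- build_grid(3, 4)
  rc <- cell_rowcol(g)
  expect_equal(rc$row[rc$cell_id == 5], 2L)
  expect_equal(rc$col[rc$cell_id == 5], 1L)
  expect_equal((rc$row - 1L) * g$n_cols + rc$col, rc$cell_id)
})

test_that("small ranges keep every touched cell regardless of overlap", {
  g <- build_grid(5, 5)  # cell area 582.02 km2
  ov <- list(species_id = "s", polygon_area_km2 = 100,
             cell_overlaps = c(`1` = 0.03, `2` = 0.02))
  expect_equal(rasterize_range(ov, g), c(1L, 2L))
  # invariant to the threshold
  expect_equal(rasterize_range(ov, g, min_overlap = 0.5), c(1L, 2L))
})

test_that("large ranges drop cells below the 10% overlap threshold, keeping ties", {
  g <- build_grid(5, 5)
  ov <- list(species_id = "s", polygon_area_km2 = 5000,
             cell_overlaps = c(`1` = 0.50, `2` = 0.05))
  expect_equal(rasterize_range(ov, g), 1L)
  # a cell exactly at the threshold is kept (exclusion is strictly below)
  ov2 <- list(species_id = "s", polygon_area_km2 = 5000,
              cell_overlaps = c(`3` = 0.10))
  expect_equal(rasterize_range(ov2, g), 3L)
})

test_that("a large range with no qualifying cell keeps its best cell, with a warning", {
  g <- build_grid(5, 5)
  ov <- list(species_id = "s", polygon_area_km2 = 5000,
             cell_overlaps = c(`1` = 0.04, `2` = 0.08, `3` = 0.02))
  expect_warning(kept <- rasterize_range(ov, g), "best-covered")
  expect_equal(kept, 2L)
})

test_that("empty or malformed overlap maps are rejected", {
  g <- build_grid(3, 3)
  expect_error(rasterize_range(list(species_id = "s", polygon_area_km2 = 10,
                                    cell_overlaps = numeric()), g),
               "empty range")
  expect_error(rasterize_range(list(species_id = "s", polygon_area_km2 = 10,
                                    cell_overlaps = c(`1` = 1.2)), g),
               "\\[0, 1\\]")
  expect_error(rasterize_range(list(species_id = "s", polygon_area_km2 = 10,
                                    cell_overlaps = c(`99` = 0.5)), g),
               "cell ids")
})

test_that("rasterization equals a brute-force filter and shrinks monotonically", {
  g <- build_grid(10, 10)
  set.seed(91)
  for (rep in 1:30) {
    n <- sample(3:15, 1)
    cells <- sample(g$cell_ids, n)
    fr <- stats::setNames(round(stats::runif(n), 3), cells)
    area <- stats::runif(1, 0.5, 10) * g$cell_area_km2
    ov <- list(species_id = "s", cell_overlaps = fr, polygon_area_km2 = area)
    got <- suppressWarnings(rasterize_range(ov, g, 0.1))
    expected <- if (area < g$cell_area_km2) {
      sort(as.integer(names(fr)[fr > 0]))
    } else if (any(fr >= 0.1)) {
      sort(as.integer(names(fr)[fr >= 0.1]))
    } else {
      as.integer(names(fr)[which.max(fr)])
    }
    expect_equal(got, expected)
    if (area >= g$cell_area_km2 && any(fr >= 0.3)) {
      lo <- rasterize_range(ov, g, 0.1)
      hi <- rasterize_range(ov, g, 0.3)
      expect_true(all(hi %in% lo))
    }
  }
})

test_that("species and overlap tables round-trip through CSV", {
  sp <- tibble::tibble(
    species_id = c("a", "b"), taxon = c("bird", "reptile"),
    redlist = c("LC", "EN"),
    habitat_classes = list(c("forest", "managed"), "non_forest"),
    polygon_area_km2 = c(1000, 350.5)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp, f)
  back <- read_species_table(f)
  expect_equal(back$habitat_classes, sp$habitat_classes)
  expect_equal(back$polygon_area_km2, sp$polygon_area_km2)

  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species_id = c("a", "a", "b"),
                              cell_id = c(1, 2, 9),
                              overlap_fraction = c(0.5, 0.2, 0.9)),
                   f2, row.names = FALSE)
  ov <- read_range_overlaps(f2)
  expect_equal(ov$a, c(`1` = 0.5, `2` = 0.2))
  expect_equal(ov$b, c(`9` = 0.9))
})
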