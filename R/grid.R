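#' Build an equal-area analysis grid
#'
#' Defines the square equal-area lattice on which all stages operate. The
#' default cell edge of 24.125 km gives the 582.02 km2 cell used for global
#' analyses in a Behrmann equal-area projection; synthetic worlds treat the
#' grid as an abstract lattice, so no coordinate reference system is attached
#' and per-cell range overlap fractions are consumed directly.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_edge_km Cell edge length in km (default 24.125).
#' @return An object of class `ea_grid`: a list with `n_rows`, `n_cols`,
#'   `cell_edge_km`, `cell_area_km2` (edge squared) and integer `cell_ids`
#'   numbered row-major from 1.
#' @export
#' @examples
#' g <- build_grid(10, 10)
#' g$cell_area_km2  # 582.015625
build_grid <- function(n_rows, n_cols, cell_edge_km = 24.125) {
  if (length(n_rows) != 1L || length(n_cols) != 1L || length(cell_edge_km) != 1L)
    stop("grid dimensions must be scalars", call. = FALSE)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1 ||
      n_rows != floor(n_rows) || n_cols != floor(n_cols))
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  if (!is.finite(cell_edge_km) || cell_edge_km <= 0)
    stop("cell_edge_km must be positive", call. = FALSE)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  structure(
    list(
      n_rows = n_rows,
      n_cols = n_cols,
      cell_edge_km = cell_edge_km,
      cell_area_km2 = cell_edge_km^2,
      cell_ids = seq_len(n_rows * n_cols)
    ),
    class = "ea_grid"
  )
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf("<ea_grid> %d x %d cells, edge %.3f km, cell area %.2f km2\n",
              x$n_rows, x$n_cols, x$cell_edge_km, x$cell_area_km2))
  invisible(x)
}

#' Row and column of grid cells
#'
#' @param grid An `ea_grid`.
#' @param cell_ids Integer cell ids (default all).
#' @return Tibble with `cell_id`, `row`, `col` (row-major numbering).
#' @export
cell_rowcol <- function(grid, cell_ids = grid$cell_ids) {
  tibble::tibble(
    cell_id = as.integer(cell_ids),
    row = ((as.integer(cell_ids) - 1L) %/% grid$n_cols) + 1L,
    col = ((as.integer(cell_ids) - 1L) %% grid$n_cols) + 1L
  )
}

#' Rasterize a species range from per-cell overlap fractions
#'
#' Applies the two range-map gridding rules: a species whose whole polygonal
#' range is smaller than one grid cell keeps every cell its polygon touches;
#' a larger-ranged species keeps only cells where the polygon covers at least
#' `min_overlap` of the cell (strictly-below-threshold cells are excluded, so
#' a cell exactly at the threshold is kept). A large-ranged species none of
#' whose cells reach the threshold keeps its single best-covered cell, with a
#' warning, so that every species remains analysable.
#'
#' @param overlap A list (or one-row data frame) with `species_id`,
#'   `cell_overlaps` (named numeric vector, names = cell ids, values =
#'   overlap fractions in \[0,1\]) and `polygon_area_km2`.
#' @param grid An `ea_grid`.
#' @param min_overlap Minimum overlap fraction for large ranges (default 0.1).
#' @return Sorted integer vector of retained cell ids.
#' @export
#' @examples
#' g <- build_grid(5, 5)
#' ov <- list(species_id = "sp1", polygon_area_km2 = 100,
#'            cell_overlaps = c(`1` = 0.03, `2` = 0.02))
#' rasterize_range(ov, g)  # small range: both cells kept
rasterize_range <- function(overlap, grid, min_overlap = 0.1) {
  if (min_overlap < 0 || min_overlap > 1)
    stop("min_overlap must be in [0, 1]", call. = FALSE)
  fr <- overlap$cell_overlaps
  if (is.null(fr) || length(fr) == 0L)
    stop("empty range: species '", overlap$species_id,
         "' has no overlapping cells", call. = FALSE)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("overlap fractions must be finite and in [0, 1]", call. = FALSE)
  cells <- as.integer(names(fr))
  if (anyNA(cells) || !all(cells %in% grid$cell_ids))
    stop("cell_overlaps names must be cell ids of the grid", call. = FALSE)

  if (overlap$polygon_area_km2 < grid$cell_area_km2) {
    keep <- cells[fr > 0]
  } else {
    keep <- cells[fr >= min_overlap]
    if (length(keep) == 0L) {
      keep <- cells[which.max(fr)]
      warning("species '", overlap$species_id,
              "': no cell reaches the overlap threshold; keeping the ",
              "single best-covered cell", call. = FALSE)
    }
  }
  sort(unique(keep))
}

#' Read a species table from CSV
#'
#' Expects columns `species_id`, `taxon`, `redlist`, `habitat_classes`
#' (pipe-delimited class names) and `polygon_area_km2`.
#'
#' @param path CSV file path.
#' @return Tibble with `habitat_classes` parsed into a list-column.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "taxon", "redlist", "habitat_classes", "polygon_area_km2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("species table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$habitat_classes <- strsplit(df$habitat_classes, "|", fixed = TRUE)
  tibble::as_tibble(df)
}

#' Write a species table to CSV
#'
#' @param species Tibble as returned by [read_species_table()] (the
#'   `habitat_classes` list-column is collapsed with `|`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path) {
  out <- species
  out$habitat_classes <- vapply(out$habitat_classes, paste, "", collapse = "|")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read range overlaps from CSV
#'
#' Long format: columns `species_id`, `cell_id`, `overlap_fraction`.
#'
#' @param path CSV file path.
#' @return Named list of named numeric overlap vectors, one per species.
#' @export
read_range_overlaps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "cell_id", "overlap_fraction")
  if (!all(need %in% names(df)))
    stop("range overlap table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  split(stats::setNames(df$overlap_fraction, df$cell_id), df$species_id)
}
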